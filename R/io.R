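# Series readers/writers: NIfTI volume + JSON sidecar. The sidecar carries
# the acquisition metadata (offset list, M0 flags, saturation scheme) that no
# standard image header stores; its schema is versioned.

SIDECAR_SCHEMA <- "cestr-sidecar-1"

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a CEST series (NIfTI + JSON sidecar)
#'
#' @param series `cest_series`.
#' @param path output `.nii` / `.nii.gz` path; the sidecar is written next to
#'   it with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "cest_series"))
  write_nifti(series$signal, series$geometry, path)
  sc <- list(schema = SIDECAR_SCHEMA,
             offsets_ppm = series$grid$offsets_ppm,
             m0_flags = series$grid$m0_flags,
             repetition_index = series$grid$repetition_index,
             scheme = unclass(series$scheme),
             mask_rle = rle_encode(series$mask),
             recovery_times_s = series$recovery_times_s)
  jsonlite::write_json(sc, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a CEST series (NIfTI + JSON sidecar)
#'
#' @param path `.nii` / `.nii.gz` path written by [write_series()].
#' @return `cest_series`.
#' @export
read_series <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for ", path, " (expected ", sp, ")")
  sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(sc$schema) || !identical(sc$schema, SIDECAR_SCHEMA))
    stop(sp, ": unsupported sidecar schema")
  vol <- read_nifti(path)
  if (dim(vol$data)[4] != length(sc$offsets_ppm))
    stop(sprintf("%s: sidecar lists %d offsets but the volume has %d frames",
                 path, length(sc$offsets_ppm), dim(vol$data)[4]))
  grid <- offset_grid(sc$offsets_ppm, as.logical(sc$m0_flags),
                      sc$repetition_index)
  scheme <- do.call(saturation_scheme, as.list(sc$scheme))
  mask <- if (!is.null(sc$mask_rle)) rle_decode(sc$mask_rle, dim(vol$data)[1:3])
  rec <- sc$recovery_times_s
  if (length(rec) == 0) rec <- NULL
  cest_series(vol$data, vol$geometry, grid, scheme, mask = mask,
              recovery_times_s = rec)
}

# compact logical-mask run-length coding for the sidecar
rle_encode <- function(mask) {
  r <- rle(as.logical(mask))
  list(first = r$values[1], lengths = r$lengths)
}

rle_decode <- function(enc, dims) {
  n <- length(enc$lengths)
  vals <- rep(c(enc$first, !enc$first), length.out = n)
  array(inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                   values = vals), class = "rle")), dims)
}

#' Write field maps as NIfTI volumes
#'
#' Writes `b0_ppm.nii.gz`, `rel_b1.nii.gz`, `t1_s.nii.gz` (whichever are
#' present) into a directory.
#'
#' @param maps `cest_fieldmaps`.
#' @param geometry `cest_geometry`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_maps <- function(maps, geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("b0_ppm", "rel_b1", "t1_s")) {
    m <- maps[[nm]]
    if (!is.null(m)) {
      m[!is.finite(m)] <- 0
      write_nifti(m, geometry, file.path(dir, paste0(nm, ".nii.gz")))
    }
  }
  invisible(dir)
}
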