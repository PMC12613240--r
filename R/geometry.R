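#' Volume geometry
#'
#' Describes the sampling grid of a 3D volume: matrix dimensions, voxel size
#' and the world-space position (mm) of the centre of voxel (0,0,0). Voxel
#' indices are 0-based and world coordinates follow an axis-aligned RAS+
#' convention (the affine is diagonal: world = origin + index * voxel size).
#'
#' @param matrix_dims integer vector of length 3, all >= 1.
#' @param voxel_size_mm numeric vector of length 3, all > 0.
#' @param origin_offset_mm numeric vector of length 3 (defaults to 0,0,0).
#' @return An object of class `cest_geometry`.
#' @export
volume_geometry <- function(matrix_dims = c(128L, 104L, 16L),
                            voxel_size_mm = c(1.7, 1.7, 3),
                            origin_offset_mm = c(0, 0, 0)) {
  matrix_dims <- as.integer(matrix_dims)
  stopifnot(length(matrix_dims) == 3, length(voxel_size_mm) == 3,
            length(origin_offset_mm) == 3)
  if (any(matrix_dims < 1L)) stop("all matrix dimensions must be >= 1")
  if (any(voxel_size_mm <= 0)) stop("all voxel sizes must be > 0")
  structure(list(matrix_dims = matrix_dims,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_offset_mm = as.numeric(origin_offset_mm)),
            class = "cest_geometry")
}

#' @export
print.cest_geometry <- function(x, ...) {
  cat(sprintf("<cest_geometry> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$matrix_dims[1], x$matrix_dims[2], x$matrix_dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-9) {
  identical(a$matrix_dims, b$matrix_dims) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$origin_offset_mm - b$origin_offset_mm)) < tol
}

# world coordinates (mm) of all voxel centres along one axis
axis_world <- function(geom, axis) {
  geom$origin_offset_mm[axis] +
    (seq_len(geom$matrix_dims[axis]) - 1) * geom$voxel_size_mm[axis]
}

#' Resample a label volume onto a target geometry
#'
#' Nearest-neighbour assignment in world coordinates, used to map atlas ROIs
#' onto the contrast-map grid. The label set of the output is a subset of the
#' input's; target voxels whose world position falls outside the source field
#' of view raise an error when the geometries do not overlap at all and are
#' otherwise assigned the nearest edge voxel (half-voxel tolerance).
#'
#' @param labels 3D integer array.
#' @param geometry `cest_geometry` of `labels`.
#' @param target `cest_geometry` to resample onto.
#' @return 3D integer array with `target$matrix_dims` dimensions.
#' @export
resample_labels <- function(labels, geometry, target) {
  stopifnot(inherits(geometry, "cest_geometry"), inherits(target, "cest_geometry"))
  if (!identical(dim(labels), as.integer(geometry$matrix_dims)))
    stop("label array dimensions do not match the stated geometry")
  if (geometry_equal(geometry, target)) return(labels)
  idx <- vector("list", 3)
  for (ax in 1:3) {
    src <- axis_world(geometry, ax)
    tgt <- axis_world(target, ax)
    half <- geometry$voxel_size_mm[ax] / 2
    if (max(tgt) < min(src) - half || min(tgt) > max(src) + half)
      stop("source and target geometries do not overlap on axis ", ax)
    if (min(tgt) < min(src) - half || max(tgt) > max(src) + half)
      stop("source geometry does not cover the target field of view on axis ", ax)
    # nearest source voxel centre for every target centre
    idx[[ax]] <- pmin(pmax(round((tgt - src[1]) / geometry$voxel_size_mm[ax]) + 1, 1),
                      geometry$matrix_dims[ax])
  }
  out <- labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- target$matrix_dims
  storage.mode(out) <- "integer"
  out
}
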