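# Pipeline orchestration: field mapping -> preprocessing -> four-pool
# fitting -> contrasts -> ROI statistics, per subject and at group level.

# Z_lab / Z_ref maps for one pool from fitted parameter maps (vectorized
# over voxels).
pool_zmaps <- function(fitmaps, pool) {
  m <- fitmaps$maps
  k <- match(pool, POOLS)
  center <- if (pool == "DS") m$d_DS else POOL_CENTERS[[pool]]
  total <- m$z0 - m$plateau
  amps <- list(m$A_DS, m$A_amide, m$A_rNOE, m$A_ssMT)
  wids <- list(m$G_DS, m$G_amide, m$G_rNOE, m$G_ssMT)
  cens <- list(m$d_DS, POOL_CENTERS[["amide"]], POOL_CENTERS[["rNOE"]],
               POOL_CENTERS[["ssMT"]])
  z_lab <- total
  z_ref <- total
  for (j in 1:4) {
    g <- wids[[j]] / 2
    lj <- g^2 / (g^2 + (center - cens[[j]])^2)
    z_lab <- z_lab - amps[[j]] * lj
    if (j != k) z_ref <- z_ref - amps[[j]] * lj
  }
  list(z_lab = z_lab, z_ref = z_ref)
}

# MTR_Rex / LD / AREX maps at one acquisition from fitted maps
series_contrasts <- function(fitmaps, t1_s = NULL) {
  out <- list()
  for (pool in c("amide", "rNOE", "ssMT")) {
    zz <- pool_zmaps(fitmaps, pool)
    bad <- !is.na(zz$z_lab) & zz$z_lab <= 0
    mt <- mtr_rex(zz$z_lab, zz$z_ref)
    mt[bad] <- NA_real_
    out[[paste0("MTRRex_", pool)]] <- mt
    out[[paste0("LD_", pool)]] <- ld(zz$z_lab, zz$z_ref)
    if (!is.null(t1_s))
      out[[paste0("AREX_", pool)]] <- arex(mt, t1_s)
  }
  out
}

#' Process one subject through the full pipeline
#'
#' Stages: WASABI B0/relative-B1 fit, saturation-recovery T1 fit,
#' normalization, B0 correction, optional PCA denoising, four-pool fitting
#' of both low-power series, MTR_Rex/LD/AREX computation with two-point B1
#' correction to `target_uT`, and APTw (plus fluid-suppressed APTw) from the
#' high-power series.
#'
#' @param subject `cest_phantom_subject` (or any list with the same
#'   `series`, `labels`, `config` fields).
#' @param denoise apply PCA denoising to the low-power series.
#' @param config four-pool fit configuration.
#' @param target_uT B1 reconstruction target (default 0.7).
#' @param mask optional 3D logical processing mask (default: the series
#'   mask).
#' @param progress print stage messages.
#' @return list of class `cest_subject_result`: fitted `field_maps`,
#'   `contrasts` (named `cest_contrast` list incl. `T1`), and the fit maps.
#' @export
process_subject <- function(subject, denoise = TRUE, config = fit_config(),
                            target_uT = 0.7, mask = NULL, progress = FALSE) {
  ser <- subject$series
  need <- c("lowpower_06", "lowpower_09")
  if (is.null(ser$wasabi))
    stop("WASABI series missing: B0 correction and the two-point MTR_Rex ",
         "B1 correction need the rel. B1 / B0 maps")
  if (is.null(ser$t1rec))
    stop("T1 saturation-recovery series missing: AREX needs a quantitative T1 map")
  if (any(vapply(ser[need], is.null, logical(1))))
    stop("both low-power series (0.6 and 0.9 uT) are required")
  say <- function(...) if (progress) message(...)
  restrict <- function(s) {
    if (!is.null(mask)) s$mask <- s$mask & mask
    s
  }
  say("  WASABI field mapping")
  fm_w <- fit_wasabi(restrict(ser$wasabi))
  say("  T1 saturation-recovery fit")
  fm_t1 <- fit_t1_satrec(restrict(ser$t1rec))
  geom <- ser$lowpower_06$geometry
  fits <- list()
  for (nm in need) {
    say("  fitting ", nm)
    zs <- normalize_series(restrict(ser[[nm]]))
    zs <- correct_b0(zs, fm_w$b0_ppm)
    if (denoise) zs <- denoise_pca(zs)
    fits[[nm]] <- fit_four_pool(zs, config)
  }
  con_low <- series_contrasts(fits$lowpower_06, fm_t1$t1_s)
  con_high <- series_contrasts(fits$lowpower_09, fm_t1$t1_s)
  msk <- fits$lowpower_06$mask
  contrasts <- list()
  for (nm in names(con_low)) {
    lo <- contrast_volume(nm, con_low[[nm]], msk, 0.6, geom)
    hi <- contrast_volume(nm, con_high[[nm]], msk, 0.9, geom)
    contrasts[[nm]] <- b1_correct_two_point(lo, hi, fm_w$rel_b1,
                                            target_uT = target_uT)
  }
  say("  APTw evaluation")
  zs_apt <- normalize_series(restrict(ser$aptw))
  apt <- aptw_contrast(zs_apt, fm_w$b0_ppm)
  contrasts$APTw <- apt
  contrasts$APTw_fs <- fluid_suppress(apt)
  field_maps <- field_maps(b0_ppm = fm_w$b0_ppm, rel_b1 = fm_w$rel_b1,
                           t1_s = fm_t1$t1_s)
  field_maps$quality <- fm_w$quality & fm_t1$quality
  structure(list(field_maps = field_maps, contrasts = contrasts,
                 fits = fits, labels = subject$labels,
                 subject_index = subject$subject_index, geometry = geom),
            class = "cest_subject_result")
}

# value map for summary purposes: contrasts plus the fitted T1
result_value_maps <- function(result) {
  vals <- lapply(result$contrasts, function(cv) {
    v <- cv$values
    v[!cv$mask] <- NA_real_
    v
  })
  vals$T1 <- result$field_maps$t1_s
  vals
}

#' Per-subject ROI summary table
#'
#' One row per (tissue, region, contrast): n, mean, SD and median over the
#' ROI voxels, for all contrasts and the fitted T1 map.
#'
#' @param result `cest_subject_result`.
#' @return data.frame (the single-subject reference-table analog).
#' @export
summarize_subject <- function(result) {
  defs <- roi_definitions(result$labels)
  vals <- result_value_maps(result)
  rows <- list()
  for (cn in names(vals)) {
    for (r in seq_len(nrow(defs))) {
      s <- summarize_roi(vals[[cn]], result$labels, defs$label_codes[[r]])
      rows[[length(rows) + 1]] <-
        cbind(data.frame(subject = result$subject_index,
                         tissue = defs$tissue[r], region = defs$region[r],
                         contrast = cn), s)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise ROI tests for one contrast
#'
#' Within each tissue, every region is compared with every other region;
#' the combined GM and WM groups are also contrasted. Works on voxel values
#' of a single subject (`mode = "voxel"`) or on per-subject medians
#' (`mode = "group"`, pass the per-subject summary table).
#'
#' @param values named list of value groups, e.g. from
#'   [roi_value_groups()].
#' @inheritParams pairwise_mann_whitney
#' @return data.frame of test results.
#' @export
roi_tests <- function(values, alpha = 0.05, adjust = "none") {
  gm <- values[grep("^GM", names(values))]
  wm <- values[grep("^WM", names(values))]
  gm <- gm[!grepl("Combined", names(gm))]
  wm <- wm[!grepl("Combined", names(wm))]
  res <- rbind(pairwise_mann_whitney(gm, alpha, adjust),
               pairwise_mann_whitney(wm, alpha, adjust))
  if (all(c("GM-Combined", "WM-Combined") %in% names(values)))
    res <- rbind(res, pairwise_mann_whitney(values[c("GM-Combined",
                                                     "WM-Combined")],
                                            alpha, adjust))
  res
}

#' Extract ROI value groups for one contrast
#'
#' @param result `cest_subject_result` (voxel mode) or a per-subject summary
#'   data.frame as built by [summarize_subject()] rows bound over subjects
#'   (group-median mode).
#' @param contrast contrast name (`"T1"` for the T1 map).
#' @return named list `"<tissue>-<region>"` of numeric vectors.
#' @export
roi_value_groups <- function(result, contrast) {
  if (inherits(result, "cest_subject_result")) {
    defs <- roi_definitions(result$labels)
    vals <- result_value_maps(result)[[contrast]]
    out <- lapply(seq_len(nrow(defs)), function(r)
      roi_values(vals, result$labels, defs$label_codes[[r]]))
    names(out) <- paste(defs$tissue, defs$region, sep = "-")
    return(out)
  }
  d <- result[result$contrast == contrast, ]
  key <- paste(d$tissue, d$region, sep = "-")
  split(d$median, key)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Simulates the cohort, processes every subject, and assembles the group
#' median table, pairwise tests and coefficients of variation. When
#' `out_dir` is given, tables, the serialized run configuration and a
#' checksum manifest are written there (and per-subject volumes when
#' `write_volumes`).
#'
#' @param config `cest_phantom_config`.
#' @param out_dir optional output directory.
#' @param denoise apply PCA denoising.
#' @param write_volumes also write per-subject phantom series and contrast
#'   maps as NIfTI.
#' @param progress print stage messages.
#' @param mask_fn optional `function(subject) -> 3D logical` restricting the
#'   processed voxels (e.g. for quick desk-scale runs); ROI summaries then
#'   cover only the retained voxels.
#' @return list of class `cest_run`: `results` (per subject),
#'   `per_subject` (summary rows), `group_table`, `group_tests`, `cvs`,
#'   `manifest` (or `NULL`), `config`.
#' @export
run_pipeline <- function(config = phantom_config(), out_dir = NULL,
                         denoise = TRUE, write_volumes = FALSE,
                         progress = FALSE, mask_fn = NULL) {
  say <- function(...) if (progress) message(...)
  say("simulating ", config$n_subjects, "-subject phantom cohort")
  cohort <- simulate_cohort(config)
  results <- vector("list", length(cohort))
  per_subject <- list()
  for (k in seq_along(cohort)) {
    say("processing subject ", k)
    msk <- if (!is.null(mask_fn)) mask_fn(cohort[[k]])
    results[[k]] <- process_subject(cohort[[k]], denoise = denoise,
                                    progress = progress, mask = msk)
    per_subject[[k]] <- summarize_subject(results[[k]])
  }
  per_subject <- do.call(rbind, per_subject)
  group_table <- build_group_table(per_subject)
  contrasts <- unique(per_subject$contrast)
  tests <- lapply(contrasts, function(cn)
    cbind(contrast = cn, roi_tests(roi_value_groups(per_subject, cn))))
  group_tests <- do.call(rbind, tests)
  cv_rows <- list()
  for (cn in setdiff(contrasts, c("APTw", "APTw_fs"))) {
    d <- per_subject[per_subject$contrast == cn, ]
    for (key in split(d, paste(d$tissue, d$region))) {
      cv_rows[[length(cv_rows) + 1]] <-
        data.frame(tissue = key$tissue[1], region = key$region[1],
                   contrast = cn,
                   cv_percent = coefficient_of_variation(key$median, cn))
    }
  }
  cvs <- do.call(rbind, cv_rows)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_subject, file.path(out_dir, "table1_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(group_table, file.path(out_dir, "table2_group.csv"),
                     row.names = FALSE)
    utils::write.csv(group_tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
    utils::write.csv(cvs, file.path(out_dir, "cv.csv"), row.names = FALSE)
    cfg <- config
    cfg$geometry <- unclass(cfg$geometry)
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (write_volumes) {
      for (k in seq_along(cohort)) {
        sdir <- file.path(out_dir, sprintf("subject%02d", k))
        write_phantom_subject(cohort[[k]], sdir)
        for (nm in names(results[[k]]$contrasts)) {
          v <- results[[k]]$contrasts[[nm]]$values
          v[!is.finite(v)] <- 0
          write_nifti(v, results[[k]]$geometry,
                      file.path(sdir, paste0(nm, ".nii.gz")))
        }
      }
    }
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, per_subject = per_subject,
                 group_table = group_table, group_tests = group_tests,
                 cvs = cvs, manifest = manifest, config = config),
            class = "cest_run")
}
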