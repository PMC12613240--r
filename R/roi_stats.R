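# Atlas-ROI statistics: per-ROI summaries, Mann-Whitney comparisons with
# exact small-sample p-values, normality screening, coefficients of
# variation, and the voxel-wise contrast-vs-B1 regression check.

#' ROI definitions for a label volume
#'
#' Eight named (tissue, region) ROIs plus the combined GM and WM unions.
#'
#' @param labels 3D integer label array (codes of [roi_table()]).
#' @param min_voxels voxel floor enforced for the four named regions.
#' @return data.frame with `tissue`, `region` (incl. `"Combined"`),
#'   `label_codes` (list column), `voxel_count`.
#' @export
roi_definitions <- function(labels, min_voxels = 100L) {
  tab <- roi_table()
  counts <- tabulate(labels, nbins = 8L)
  if (any(counts < min_voxels)) {
    bad <- which(counts < min_voxels)[1]
    stop(sprintf("ROI %s-%s has %d voxels (< %d)", tab$tissue[bad],
                 tab$region[bad], counts[bad], min_voxels))
  }
  defs <- rbind(data.frame(tissue = tab$tissue, region = tab$region),
                data.frame(tissue = TISSUES, region = "Combined"))
  defs$label_codes <- c(as.list(tab$code),
                        list(tab$code[tab$tissue == "GM"],
                             tab$code[tab$tissue == "WM"]))
  defs$voxel_count <- vapply(defs$label_codes,
                             function(cc) sum(counts[cc]), numeric(1))
  defs
}

roi_values <- function(values, labels, codes) {
  v <- values[labels %in% codes]
  v[is.finite(v)]
}

#' Summarize a contrast over one ROI
#'
#' Mean, SD (n-1 denominator) and median over the ROI's masked, valid
#' voxels.
#'
#' @param contrast `cest_contrast` or a 3D numeric array.
#' @param labels 3D integer label array.
#' @param codes label code(s) of the ROI.
#' @return one-row data.frame with `n`, `mean`, `sd`, `median`.
#' @export
summarize_roi <- function(contrast, labels, codes) {
  vals <- if (inherits(contrast, "cest_contrast")) {
    v <- contrast$values
    v[!contrast$mask] <- NA_real_
    v
  } else contrast
  v <- roi_values(vals, labels, codes)
  if (!length(v)) stop("ROI has no valid voxels for this contrast")
  data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
             median = stats::median(v))
}

# Exact two-sided Mann-Whitney p by enumeration of all group-A/B rank
# assignments (midranks under ties); used for small samples.
mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  rs <- colSums(matrix(r[combos], nrow = na))
  us <- rs - na * (na + 1) / 2
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-corrected normal approximation (two-sided, continuity corrected).
mw_normal_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - na * nb / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-z))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for `length(a) + length(b) <= exact_max` (handles
#' ties via midranks), tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric value groups (each n >= 3).
#' @param exact_max sample-size bound for exact enumeration (default 20).
#' @return list with `u_statistic`, `p_value`, `exact`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  exact <- length(a) + length(b) <= exact_max
  p <- if (exact) mw_exact_p(a, b) else mw_normal_p(a, b)
  list(u_statistic = u, p_value = p, exact = exact)
}

#' All pairwise Mann-Whitney comparisons of labeled groups
#'
#' Compares every group with every other group (the within-tissue region
#' pairs and the combined GM-vs-WM contrast in the ROI analysis). Groups
#' with fewer than 3 values are skipped with a warning. Shapiro-Wilk
#' normality p-values are reported per group but never switch the test.
#' Raw p-values are reported by default; `adjust = "holm"` applies a Holm
#' correction.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `u_statistic`, `p_value`, `significant`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
pairwise_mann_whitney <- function(groups, alpha = 0.05,
                                  adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  ok <- vapply(groups, length, integer(1)) >= 3L
  if (any(!ok))
    warning("skipping groups with < 3 values: ",
            paste(names(groups)[!ok], collapse = ", "))
  groups <- groups[ok]
  if (length(groups) < 2L)
    return(data.frame(group_a = character(), group_b = character(),
                      u_statistic = numeric(), p_value = numeric(),
                      shapiro_p_a = numeric(), shapiro_p_b = numeric(),
                      significant = logical()))
  nm <- names(groups)
  shapiro_p <- vapply(groups, function(v) {
    if (length(unique(v)) < 3 || length(v) > 5000) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    mw <- mann_whitney_u(groups[[i1]], groups[[i2]])
    data.frame(group_a = nm[i1], group_b = nm[i2],
               u_statistic = mw$u_statistic, p_value = mw$p_value,
               shapiro_p_a = shapiro_p[i1], shapiro_p_b = shapiro_p[i2])
  })
  res <- do.call(rbind, res)
  if (adjust == "holm") res$p_value <- stats::p.adjust(res$p_value, "holm")
  res$significant <- res$p_value < alpha
  res
}

#' Coefficient of variation of subject medians (%)
#'
#' `100 * sd / mean`. Refused for the APTw family, which is defined on an
#' interval scale (its zero is arbitrary, so a ratio CV is meaningless).
#'
#' @param subject_medians numeric vector.
#' @param contrast_name contrast these medians belong to.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(subject_medians, contrast_name = "") {
  if (grepl("^APTw", contrast_name))
    stop("CV is not defined for the interval-scaled APTw contrasts")
  m <- mean(subject_medians)
  if (m == 0) stop("CV undefined: mean of medians is zero")
  100 * stats::sd(subject_medians) / m
}

#' Group table of per-subject ROI medians
#'
#' For each (tissue, region, contrast): the mean and SD of the per-subject
#' medians -- the group reference-table analog.
#'
#' @param per_subject data.frame with columns `subject`, `tissue`, `region`,
#'   `contrast`, `median` (rows from [summarize_roi()] per subject).
#' @return data.frame with `tissue`, `region`, `contrast`, `n_subjects`,
#'   `mean_median`, `sd_median`.
#' @export
build_group_table <- function(per_subject) {
  req <- c("subject", "tissue", "region", "contrast", "median")
  stopifnot(all(req %in% names(per_subject)))
  if (length(unique(per_subject$subject)) < 2L)
    stop("group table needs at least 2 subjects")
  key <- interaction(per_subject$tissue, per_subject$region,
                     per_subject$contrast, drop = TRUE)
  rows <- lapply(split(per_subject, key), function(d) {
    data.frame(tissue = d$tissue[1], region = d$region[1],
               contrast = d$contrast[1], n_subjects = nrow(d),
               mean_median = mean(d$median), sd_median = stats::sd(d$median))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Voxel-wise contrast-vs-B1 regression check
#'
#' Ordinary least squares of the contrast on relative B1 over an ROI's
#' voxels; a successfully B1-corrected contrast should show a slope and
#' coefficient of determination near zero.
#'
#' @param contrast `cest_contrast` or 3D array (may also be a plain vector
#'   paired with a `rel_b1` vector).
#' @param rel_b1 3D numeric array (or vector).
#' @param labels optional label array with `codes` selecting the ROI.
#' @param codes label codes of the ROI.
#' @return list with `slope`, `r_squared`, `n`.
#' @export
b1_correlation_check <- function(contrast, rel_b1, labels = NULL, codes = NULL) {
  vals <- if (inherits(contrast, "cest_contrast")) contrast$values else contrast
  if (!is.null(labels)) {
    sel <- labels %in% codes
    vals <- vals[sel]; rel_b1 <- rel_b1[sel]
  }
  keep <- is.finite(vals) & is.finite(rel_b1)
  vals <- vals[keep]; rel_b1 <- rel_b1[keep]
  if (length(vals) < 3) stop("too few voxels for regression")
  if (stats::sd(rel_b1) == 0)
    return(list(slope = NA_real_, r_squared = NA_real_, n = length(vals),
                flag = "constant rel_b1: R^2 undefined"))
  fit <- stats::lm.fit(cbind(1, rel_b1), vals)
  ssr <- sum(fit$residuals^2)
  sst <- sum((vals - mean(vals))^2)
  list(slope = unname(fit$coefficients[2]),
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
       n = length(vals))
}
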