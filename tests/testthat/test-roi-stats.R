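# independent Mann-Whitney oracle: U from pairwise comparisons, two-sided p
# from exhaustive enumeration of group assignments of the pooled values
mw_oracle <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mu <- length(a) * length(b) / 2
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

test_that("ROI summary statistics", {
  lab <- array(c(1, 1, 1, 1, 2, 2), c(6, 1, 1))
  vals <- array(c(1, 2, 3, 4, 9, 9), c(6, 1, 1))
  s <- summarize_roi(vals, lab, 1)
  expect_equal(s$n, 4)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  expect_equal(round(s$sd, 4), 1.291)
  expect_equal(s$median, 2.5)

  const <- array(0.3, c(6, 1, 1))
  sc <- summarize_roi(const, lab, 1:2)
  expect_equal(c(sc$mean, sc$sd, sc$median), c(0.3, 0, 0.3))
  expect_error(summarize_roi(array(NA_real_, c(6, 1, 1)), lab, 1), "valid")
})

test_that("Mann-Whitney U: textbook case and identical groups", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 0.1)          # 2/20 assignments as extreme
  expect_true(mw$exact)
  same <- mann_whitney_u(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$p_value, 1)
})

test_that("exact p-values match the enumeration oracle (property)", {
  set.seed(12)
  for (i in 1:12) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    vals <- if (i %% 2) rnorm(na + nb) else sample(1:4, na + nb, TRUE)  # ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    mw <- mann_whitney_u(a, b)
    or <- mw_oracle(a, b)
    expect_equal(mw$u_statistic, or$u, tolerance = 1e-12)
    expect_equal(mw$p_value, or$p, tolerance = 1e-12)
  }
})

test_that("p-values are symmetric in group order and the approximation is sane", {
  set.seed(13)
  a <- rnorm(30); b <- rnorm(35, 0.2)
  p1 <- mann_whitney_u(a, b); p2 <- mann_whitney_u(b, a)
  expect_false(p1$exact)
  expect_equal(p1$p_value, p2$p_value, tolerance = 1e-12)
  # large-sample approximation close to the exact wilcox.test reference
  expect_equal(p1$p_value,
               stats::wilcox.test(a, b, correct = TRUE)$p.value,
               tolerance = 0.02)
})

test_that("pairwise_mann_whitney covers all pairs and skips tiny groups", {
  set.seed(14)
  groups <- list(A = rnorm(8), B = rnorm(8, 2), C = rnorm(8), tiny = 1:2)
  expect_warning(res <- pairwise_mann_whitney(groups), "tiny")
  expect_equal(nrow(res), 3)
  expect_true(res$significant[res$group_a == "A" & res$group_b == "B"])
  expect_true(all(c("shapiro_p_a", "shapiro_p_b") %in% names(res)))
})

test_that("coefficient of variation", {
  expect_equal(coefficient_of_variation(c(0.19, 0.20, 0.21)),
               100 * sd(c(0.19, 0.20, 0.21)) / 0.2)
  expect_equal(coefficient_of_variation(rep(0.37, 6)), 0)
  x <- c(1, 2, 3)
  expect_equal(coefficient_of_variation(10 * x),
               coefficient_of_variation(x))      # scale invariance
  expect_error(coefficient_of_variation(c(1, 2), "APTw"), "interval")
  expect_error(coefficient_of_variation(c(1, 2), "APTw_fs"), "interval")
})

test_that("group table aggregates per-subject medians", {
  ps <- data.frame(subject = rep(1:2, each = 2),
                   tissue = "GM", region = rep(c("FL", "OC"), 2),
                   contrast = "MTRRex_amide",
                   median = c(0.19, 0.30, 0.21, 0.32))
  gt <- build_group_table(ps)
  fl <- gt[gt$region == "FL", ]
  expect_equal(fl$mean_median, 0.20)
  expect_equal(round(fl$sd_median, 4), 0.0141)
  expect_equal(fl$n_subjects, 2)
  expect_error(build_group_table(ps[ps$subject == 1, ]), "2 subjects")
})

test_that("B1 correlation check", {
  set.seed(15)
  rb <- runif(5000, 0.74, 1.05)
  lin <- 0.1 + 0.2 * rb
  ck <- b1_correlation_check(lin, rb)
  expect_equal(ck$r_squared, 1, tolerance = 1e-12)
  expect_equal(ck$slope, 0.2, tolerance = 1e-9)
  indep <- rnorm(5000)
  ck2 <- b1_correlation_check(indep, rb)
  expect_lt(ck2$r_squared, 0.002)
  ck3 <- b1_correlation_check(rnorm(100), rep(1, 100))
  expect_true(is.na(ck3$r_squared))
})
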