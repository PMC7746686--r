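test_that("paired t-test matches hand computation and guards degeneracy", {
  # alternating differences: mean 0, t = 0, p = 1
  tt <- paired_t_test(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  expect_equal(tt$df, 3)
  # identical visits: flagged, p = 1
  same <- paired_t_test(c(3, 4, 5), c(3, 4, 5))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # constant non-zero difference: flagged degenerate with undefined p
  const <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))
  expect_error(paired_t_test(c(1, 2), c(1, 2)), "3")
})

test_that("ICC(2,1) matches the from-definitions ANOVA oracle", {
  set.seed(41)
  for (i in 1:300) {
    n <- sample(3:20, 1)
    X <- cbind(stats::rnorm(n, 10, 3), stats::rnorm(n, 10, 3))
    fit <- icc_two_way(X[, 1], X[, 2])
    expect_lt(abs(fit$icc - icc_oracle(X)), 1e-10)
  }
})

test_that("a constant shift between visits lowers absolute-agreement ICC", {
  # v2 = v1 + 2 on 4 subjects: MSR = 10/3, MSC = 8, MSE = 0
  # ICC = (10/3) / (10/3 + (2/4) * 8) = 5/11
  fit <- icc_two_way(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(fit$icc, 5 / 11, tolerance = 1e-10)
  expect_lt(fit$icc, 1)
})

test_that("ICC degenerate conventions and banding are as documented", {
  ident <- icc_two_way(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(ident$icc, 1)
  expect_equal(ident$ci, c(1, 1))
  expect_identical(ident$band, "excellent")
  allsame <- icc_two_way(c(2, 2, 2), c(2, 2, 2))
  expect_identical(allsame$icc, 1)
  expect_true(allsame$degenerate)
  # band boundaries: 0.90 is good, just above is excellent
  expect_identical(glance(icc_two_way(c(1, 2, 3, 4), c(3, 4, 5, 6)))$band,
                   "poor")
  b <- function(x) octarepeat:::icc_band(x)
  expect_identical(b(0.49), "poor")
  expect_identical(b(0.50), "moderate")
  expect_identical(b(0.75), "good")
  expect_identical(b(0.90), "good")
  expect_identical(b(0.91), "excellent")
})

test_that("ICC is invariant under a common affine map of both visits", {
  set.seed(43)
  v1 <- stats::rnorm(12, 30, 4); v2 <- v1 + stats::rnorm(12, 0, 1)
  base <- icc_two_way(v1, v2)$icc
  mapped <- icc_two_way(3 * v1 + 7, 3 * v2 + 7)$icc
  expect_equal(mapped, base, tolerance = 1e-10)
})

test_that("tidy and glance summarize an ICC fit", {
  fit <- icc_two_way(c(7, 8, 9, 10), c(7.1, 8.2, 8.8, 10.3))
  td <- tidy(fit)
  expect_equal(td$estimate, fit$icc)
  expect_true(td$conf.low <= fit$icc && td$conf.high >= fit$icc)
  gl <- glance(fit)
  expect_true(all(c("icc", "msr", "msc", "mse", "band") %in% names(gl)))
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD", {
  # d = (-1, 1): mean 0, SD sqrt(2), loa = +/- 2.772
  ba <- bland_altman(c(0, 1), c(1, 0))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_hi, 1.96 * sqrt(2), tolerance = 1e-6)
  expect_equal(ba$loa_lo, -1.96 * sqrt(2), tolerance = 1e-6)
  # identical visits collapse to (0, 0, 0)
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(z$mean_diff, z$loa_lo, z$loa_hi), c(0, 0, 0))
  # translation equivariance: shifting visit2 by c shifts everything by -c
  v1 <- c(10, 12, 14, 16); v2 <- c(10.5, 11.5, 14.5, 15.5)
  a <- bland_altman(v1, v2); bshift <- bland_altman(v1, v2 + 2)
  expect_equal(bshift$mean_diff, a$mean_diff - 2)
  expect_equal(bshift$loa_lo, a$loa_lo - 2)
  expect_equal(bshift$loa_hi, a$loa_hi - 2)
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(44)
  v1 <- stats::rnorm(2000, 50, 5)
  v2 <- v1 + stats::rnorm(2000, 0, 1)
  ba <- bland_altman(v1, v2)
  inside <- mean(ba$points$diff >= ba$loa_lo & ba$points$diff <= ba$loa_hi)
  expect_gte(inside, 0.93)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_ci(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  expect_error(pearson_with_ci(rep(1, 5), x), "variance")
  expect_error(pearson_with_ci(x[1:3], x[1:3]), "4")
  out <- pearson_with_ci(c(1, 3, 2, 5, 4, 6), c(2, 3, 4, 4, 6, 5))
  expect_true(out$conf.low <= out$r && out$r <= out$conf.high)
})

test_that("build_report emits one row per metric-region-variant", {
  set.seed(45)
  grid <- tidyr::expand_grid(subject = 1:6, visit = 1:2,
                             metric = c("pd_scp", "fv_area"),
                             region = c("macula", "periphery"),
                             variant = c("none", "hessian"))
  grid$value <- stats::rnorm(nrow(grid), 30, 2)
  rep <- build_report(grid, reference = c(pd_scp = "none", fv_area = "none"))
  expect_equal(nrow(rep), 2 * 2 * 2)
  expect_true(all(is.na(rep$pearson_r[rep$variant == "none"])))
  expect_true(all(!is.na(rep$pearson_r[rep$variant == "hessian"])))
  expect_true(all(rep$icc_lo <= rep$icc & rep$icc <= rep$icc_hi))
  expect_true(all(rep$loa_lo <= rep$mean_diff & rep$mean_diff <= rep$loa_hi))
  expect_error(build_report(grid, reference = c(pd_scp = "absent")),
               "reference")
  expect_error(build_report(grid[, -6]), "value")
})

test_that("an identical-visit cohort reports ICC 1 and flagged t-tests", {
  one_visit <- tidyr::expand_grid(subject = 1:8, metric = "pd_scp",
                                  region = "macula", variant = "none")
  set.seed(46)
  one_visit$value <- stats::rnorm(8, 35, 1)[one_visit$subject]
  d <- dplyr::bind_rows(dplyr::mutate(one_visit, visit = 1),
                        dplyr::mutate(one_visit, visit = 2))
  rep <- build_report(d)
  expect_identical(rep$icc, 1)
  expect_true(rep$t_degenerate)
  expect_equal(c(rep$mean_diff, rep$loa_lo, rep$loa_hi), c(0, 0, 0))
})
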