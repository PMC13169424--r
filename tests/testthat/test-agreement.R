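# Agreement statistics: paired differences, robust bias, percentile
# precision, bootstrap CIs, Bland-Altman, RMS, Spearman, RCV.

test_that("paired differences follow the sign convention and pair-mean denominator", {
  ds <- diff_set(ref = c(4.0, 3.0, 2.0), comp = c(4.2, 3.0, 1.8))
  expect_equal(ds$d, c(0.2, 0, -0.2))
  expect_equal(ds$x, c(4.1, 3.0, 1.9))
  expect_equal(ds$r[1], 100 * 0.2 / 4.1, tolerance = 1e-12)  # ~4.878%
  expect_equal(ds$r[2], 0)
  expect_lt(ds$d[3], 0)  # comparator lower -> negative
})

test_that("pairs with nonpositive pair means are excluded from the relative scale", {
  ds <- diff_set(ref = c(4, -3), comp = c(5, 1))  # second pair mean = -1
  expect_equal(ds$n_excluded_relative, 1L)
  expect_equal(length(diffs_on_scale(ds, "relative")), 1L)
  expect_equal(length(diffs_on_scale(ds, "nominal")), 2L)
})

test_that("paired_differences joins readers through the table and errors on no overlap", {
  df <- rbind(make_measurement_df(c("S1", "S2"), "TRV", "CL1", c(4.0, 3.0),
                                  quality_score = c(4L, 2L)),
              make_measurement_df(c("S1", "S2", "S3"), "TRV", "DL", c(4.2, 2.8, 9)))
  tab <- measurement_table(df)
  ds <- paired_differences(tab, "TRV", "CL1", "DL")
  expect_equal(ds$n, 2L)
  expect_equal(sort(ds$d), c(-0.2, 0.2))
  expect_equal(as.character(sort(ds$quality)), c("good", "low"))
  expect_error(paired_differences(tab, "TAPSE", "CL1", "DL"), "TAPSE")
})

test_that("robust bias is the interpolated median and resists outliers", {
  mk <- function(d) diff_set(ref = rep(0, length(d)), comp = d)
  expect_equal(robust_bias(mk(c(-1, 0, 1)), "nominal"), 0)
  expect_equal(robust_bias(mk(c(1, 2, 3, 4)), "nominal"), 2.5)
  expect_equal(robust_bias(mk(c(1, 2, 3, 4, 100)), "nominal"), 3)
  # replacing one value by something huge moves the median at most to the
  # adjacent order statistic, while the Bland-Altman mean is unbounded
  base <- c(1, 2, 3, 4, 5)
  pert <- c(1, 2, 3, 4, 1e6)
  expect_equal(robust_bias(mk(pert), "nominal"), 3)
  expect_gt(bland_altman_loa(mk(pert), "nominal")$mean_bias, 1e5)
})

test_that("percentile precision uses the (k-1)/(n-1) interpolation rule and sqrt(2) scaling", {
  mk <- function(d) diff_set(ref = rep(0, length(d)), comp = d)
  ds <- mk(0:100)
  expect_equal(percentile_precision(ds, "nominal", scaled = FALSE), 34)
  expect_equal(percentile_precision(ds, "nominal", scaled = TRUE), 34 / sqrt(2))
  expect_equal(34 / sqrt(2), 24.042, tolerance = 1e-4)
  expect_equal(percentile_precision(mk(rep(2, 10)), "nominal"), 0)
  expect_error(percentile_precision(mk(1), "nominal"), "at least 2")
  # exact scaling identity on arbitrary data
  set.seed(1)
  ds2 <- mk(rt(97, df = 3))
  expect_equal(percentile_precision(ds2, "nominal", scaled = TRUE) * sqrt(2),
               percentile_precision(ds2, "nominal", scaled = FALSE),
               tolerance = 1e-12)
})

test_that("scaled precision of standard-normal differences approaches qnorm(0.84)/sqrt(2)", {
  set.seed(202)
  ds <- diff_set(ref = rep(0, 1e6), comp = rnorm(1e6))
  expect_equal(percentile_precision(ds, "nominal", scaled = TRUE),
               qnorm(0.84) / sqrt(2), tolerance = 0.01)
  expect_equal(qnorm(0.84) / sqrt(2), 0.7032, tolerance = 1e-3)
})

test_that("bootstrap CIs are seed-deterministic and degenerate data give zero width", {
  ds <- diff_set(ref = rep(0, 50), comp = rnorm(50, 1, 2))
  a <- bootstrap_ci("bias", ds, "nominal", B = 500, seed = 7)
  b <- bootstrap_ci("bias", ds, "nominal", B = 500, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  c_ <- bootstrap_ci("bias", ds, "nominal", B = 500, seed = 8)
  expect_false(identical(as.numeric(a), as.numeric(c_)))

  const <- diff_set(ref = rep(0, 20), comp = rep(3.5, 20))
  ci <- bootstrap_ci("bias", const, "nominal", B = 100, seed = 1)
  expect_equal(as.numeric(ci), c(3.5, 3.5))
  # precision on an all-equal resample is 0, never fatal
  ci_p <- bootstrap_ci("precision", const, "nominal", B = 100, seed = 1)
  expect_equal(as.numeric(ci_p), c(0, 0))
})

test_that("Bland-Altman limits use the n-1 SD and 1.96 multiplier", {
  mk <- function(d) diff_set(ref = rep(0, length(d)), comp = d)
  loa <- bland_altman_loa(mk(c(-1, 1)), "nominal")
  expect_equal(loa$mean_bias, 0)
  expect_equal(loa$upper, 1.96 * sqrt(2), tolerance = 1e-12)  # ~2.772
  expect_equal(loa$lower, -1.96 * sqrt(2), tolerance = 1e-12)
  const <- bland_altman_loa(mk(rep(4, 5)), "nominal")
  expect_equal(c(const$mean_bias, const$lower, const$upper), c(4, 4, 4))
  set.seed(33)
  big <- bland_altman_loa(mk(rnorm(2e5, 0, 3)), "nominal")
  expect_equal((big$upper - big$lower) / 2, 1.96 * 3, tolerance = 0.02)
})

test_that("RMS identity: RMS^2 = mean bias^2 + population variance, on any data", {
  mk <- function(d) diff_set(ref = rep(0, length(d)), comp = d)
  expect_equal(rms_error(mk(c(3, 4)), "nominal"), sqrt(12.5))
  expect_equal(rms_error(mk(rep(0, 7)), "nominal"), 0)
  set.seed(77)
  for (n in c(2, 5, 31, 200)) {
    d <- rnorm(n, 1, 2) + rexp(n)
    pop_var <- mean((d - mean(d))^2)
    expect_equal(rms_error(mk(d), "nominal")^2, mean(d)^2 + pop_var,
                 tolerance = 1e-12)
    # with nonzero mean bias the RMS always exceeds the dispersion alone
    if (abs(mean(d)) > 1e-8) expect_gt(rms_error(mk(d), "nominal"), sqrt(pop_var))
  }
})

test_that("Spearman correlation equals Pearson on midranks and handles ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_correlation(x, exp(x)), 1)
  expect_equal(spearman_correlation(x, -x^3), -1)
  # tied example: hand-assigned midranks
  x2 <- c(1, 2, 2, 4)   # midranks 1, 2.5, 2.5, 4
  y2 <- c(10, 20, 30, 30)  # midranks 1, 2, 3.5, 3.5
  expect_equal(spearman_correlation(x2, y2),
               cor(c(1, 2.5, 2.5, 4), c(1, 2, 3.5, 3.5)))
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "rank variance")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("reference change value follows the quadrature RCV formula", {
  r <- reference_change_value(10, 5, 1.96)
  expect_equal(r$cv_total, sqrt(125))
  expect_equal(r$rcv_pct, sqrt(2) * 1.96 * sqrt(125))
  expect_equal(r$rcv_pct, 30.99, tolerance = 0.01)
  expect_equal(reference_change_value(10, 0, 1.96)$rcv_pct, sqrt(2) * 1.96 * 10)
  expect_equal(reference_change_value(10, 0, 1.96)$rcv_pct, 27.72, tolerance = 0.01)
  expect_equal(reference_change_value(0, 0, 1.96)$rcv_pct, 0)
  expect_error(reference_change_value(-1, 5), ">= 0")
  # rcv >= sqrt(2) z max(cv) always
  for (cvs in list(c(3, 4), c(0, 7), c(12, 1))) {
    r <- reference_change_value(cvs[1], cvs[2], 2.33)
    expect_gte(r$rcv_pct, sqrt(2) * 2.33 * max(cvs))
  }
})

test_that("the agreement fit bundles bias/precision with reproducible CIs", {
  set.seed(5)
  ds <- diff_set(ref = runif(120, 3, 5), comp = runif(120, 3, 5) * 1.02)
  f1 <- agreement(ds, scale = "relative", B = 300, seed = 9)
  f2 <- agreement(ds, scale = "relative", B = 300, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(confint(f1), confint(f2))
  expect_equal(unname(coef(f1)["bias"]), robust_bias(ds, "relative"))
  expect_equal(f1$precision * sqrt(2), f1$precision_unscaled)
  expect_true(f1$ci_bias[1] <= f1$bias && f1$bias <= f1$ci_bias[2])
  df <- as.data.frame(f1)
  expect_equal(df$precision, f1$precision)
})

test_that("yield arithmetic matches counts and errors without reference reads", {
  tab <- presence_table("TRV", "CL1", "DL", n_ref = 10, n_comp = 9, n_common = 8)
  y <- compute_yield(tab, "TRV", "CL1", "DL")
  expect_equal(c(y$n_ref, y$n_comp, y$n_common), c(10L, 9L, 8L))
  expect_equal(y$relative_yield_pct, 80)
  all_read <- presence_table("TAPSE", "CL1", "DL", 12, 12, 12)
  expect_equal(compute_yield(all_read, "TAPSE", "CL1", "DL")$relative_yield_pct, 100)
  expect_error(compute_yield(tab, "TRV", "CL2", "DL"), "undefined")
})
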