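# Robust bias, scaled percentile precision, bootstrap CIs, and the
# classical companions (Bland-Altman limits, RMS, Spearman, RCV).
#
# Percentile convention, used everywhere: linear interpolation between
# order statistics with the k-th of n points at probability (k-1)/(n-1)
# (R's type-7 quantile).

#' Robust bias: median paired difference
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} (\%) or \code{"nominal"}.
#' @return the sample median (linear interpolation at even n).
#' @export
robust_bias <- function(ds, scale = c("relative", "nominal")) {
  v <- diffs_on_scale(ds, scale)
  if (length(v) < 1L) stop("need at least 1 difference")
  median(v)
}

#' Percentile precision: half the 16th-84th percentile spread
#'
#' Precision is half the difference between the 84th and 16th percentiles
#' of the paired differences; the 16th/84th percentiles correspond to -1/+1
#' SD in a normal distribution, so this is a robust dispersion estimate.
#' Dividing by sqrt(2) (the default) converts difference-scale dispersion
#' into per-measurement dispersion, since a difference of two equally
#' imprecise reads has sqrt(2) times the per-read SD.
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @param scaled divide by sqrt(2)?  Default \code{TRUE}.
#' @return nonnegative precision estimate.
#' @export
percentile_precision <- function(ds, scale = c("relative", "nominal"),
                                 scaled = TRUE) {
  v <- diffs_on_scale(ds, scale)
  if (length(v) < 2L) stop("need at least 2 differences for percentile precision")
  q <- quantile(v, c(0.16, 0.84), names = FALSE, type = 7)
  p <- (q[2] - q[1]) / 2
  if (scaled) p / sqrt(2) else p
}

#' Percentile-bootstrap confidence interval for bias or precision
#'
#' Resamples the paired differences (the subject is the resampling unit,
#' preserving pairing) with replacement B times, recomputes the statistic,
#' and returns the 2.5th/97.5th percentiles of the bootstrap distribution.
#' Deterministic given \code{seed}; the caller's RNG state is untouched.
#'
#' @param statistic \code{"bias"} or \code{"precision"}.
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param scaled for \code{statistic = "precision"}, divide by sqrt(2).
#' @return numeric length-2 vector \code{c(lower, upper)} with attribute
#'   \code{"boot"} holding the bootstrap replicates.
#' @export
bootstrap_ci <- function(statistic = c("bias", "precision"), ds,
                         scale = c("relative", "nominal"),
                         B = 1000L, seed = NULL, conf = 0.95, scaled = TRUE) {
  statistic <- match.arg(statistic)
  v <- diffs_on_scale(ds, scale)
  n <- length(v)
  if (n < 2L) stop("need at least 2 differences")
  if (B < 1L) stop("B must be >= 1")
  stat_fun <- if (statistic == "bias") {
    median
  } else {
    function(u) {
      q <- quantile(u, c(0.16, 0.84), names = FALSE, type = 7)
      p <- (q[2] - q[1]) / 2
      if (scaled) p / sqrt(2) else p
    }
  }
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vapply(seq_len(B), function(b) stat_fun(v[idx[b, ]]), numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  attr(ci, "boot") <- boot
  ci
}

#' Bland-Altman limits of agreement
#'
#' Mean difference plus/minus 1.96 times the sample SD (n - 1 denominator).
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @return list with \code{mean_bias}, \code{lower}, \code{upper}, \code{sd}.
#' @export
bland_altman_loa <- function(ds, scale = c("relative", "nominal")) {
  v <- diffs_on_scale(ds, scale)
  if (length(v) < 2L) stop("need at least 2 differences")
  m <- mean(v); s <- sd(v)
  list(mean_bias = m, lower = m - 1.96 * s, upper = m + 1.96 * s, sd = s)
}

#' Root-mean-square error of the paired differences
#'
#' A global measure combining precision and bias: sqrt(mean(d^2)).  In the
#' presence of systematic bias it always exceeds the dispersion alone
#' (RMS^2 = mean bias^2 + population variance).
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @return nonnegative RMS.
#' @export
rms_error <- function(ds, scale = c("relative", "nominal")) {
  v <- diffs_on_scale(ds, scale)
  if (length(v) < 1L) stop("need at least 1 difference")
  sqrt(mean(v^2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("zero rank variance: Spearman correlation undefined")
  cor(x, y, method = "spearman")
}

#' Reference change value
#'
#' The smallest serial change exceeding combined analytic and
#' within-subject biological variation at confidence level given by z:
#' RCV = sqrt(2) * z * CV_total, with CV_total the quadrature sum
#' sqrt(cv_analytic^2 + cv_biological^2).
#'
#' @param cv_analytic analytic (measurement) coefficient of variation, %.
#' @param cv_biological within-subject biological CV, %.
#' @param z z score for the chosen confidence (1.96 for two-sided 5\%).
#' @return list of class \code{rcv_result}: the two CVs, \code{z},
#'   \code{cv_total}, and \code{rcv_pct}.
#' @export
#' @examples
#' reference_change_value(10, 5, 1.96)  # ~31%
reference_change_value <- function(cv_analytic, cv_biological = 0, z = 1.96) {
  if (cv_analytic < 0 || cv_biological < 0) stop("CVs must be >= 0")
  if (z <= 0) stop("z must be > 0")
  cv_total <- sqrt(cv_analytic^2 + cv_biological^2)
  structure(list(cv_analytic = cv_analytic, cv_biological = cv_biological,
                 z = z, cv_total = cv_total,
                 rcv_pct = sqrt(2) * z * cv_total),
            class = "rcv_result")
}

#' @export
print.rcv_result <- function(x, ...) {
  cat(sprintf("RCV = sqrt(2) x %.3g x CV_total(%.3g%%) = %.1f%%\n",
              x$z, x$cv_total, x$rcv_pct))
  cat(sprintf("  (analytic CV %.3g%%, biological CV %.3g%%)\n",
              x$cv_analytic, x$cv_biological))
  invisible(x)
}

# The agreement fit object ----------------------------------------------------

#' Fit a duplicate-measurement agreement summary
#'
#' The core estimator: robust bias (median paired difference) and scaled
#' percentile precision, each with a percentile-bootstrap confidence
#' interval, on the chosen difference scale.
#'
#' @param ds a \code{\link{diff_set}} (from \code{\link{paired_differences}}).
#' @param scale \code{"relative"} (\%, default) or \code{"nominal"}.
#' @param B bootstrap resamples for the CIs (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{echo_agreement} with components
#'   \code{bias}, \code{precision}, \code{precision_unscaled},
#'   \code{ci_bias}, \code{ci_precision}, \code{yield-like} counts, plus
#'   Bland-Altman and RMS companions.  Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{confint}, \code{as.data.frame}.
#' @export
#' @examples
#' cc <- generate_case_control_cohort(cohort_config(n_healthy = 60, n_case = 60), seed = 3)
#' ds <- paired_differences(cc$measurements, "TRV", "CL1", "DL")
#' agreement(ds, B = 200, seed = 1)
agreement <- function(ds, scale = c("relative", "nominal"),
                      B = 1000L, seed = NULL, conf = 0.95) {
  scale <- match.arg(scale)
  v <- diffs_on_scale(ds, scale)
  if (length(v) < 2L) stop("need at least 2 differences")
  pu <- percentile_precision(ds, scale, scaled = FALSE)
  fit <- list(parameter = ds$parameter,
              ref_reader = ds$ref_reader, comp_reader = ds$comp_reader,
              scale = scale, n = length(v),
              n_excluded_relative = if (scale == "relative") ds$n_excluded_relative else 0L,
              bias = robust_bias(ds, scale),
              precision_unscaled = pu,
              precision = pu / sqrt(2),
              ci_bias = bootstrap_ci("bias", ds, scale, B = B,
                                     seed = if (is.null(seed)) NULL else child_seed(seed, 1),
                                     conf = conf),
              ci_precision = bootstrap_ci("precision", ds, scale, B = B,
                                          seed = if (is.null(seed)) NULL else child_seed(seed, 2),
                                          conf = conf),
              loa = bland_altman_loa(ds, scale),
              rms = rms_error(ds, scale),
              B = B, seed = seed, conf = conf)
  class(fit) <- "echo_agreement"
  fit
}

#' @export
print.echo_agreement <- function(x, ...) {
  unit <- if (x$scale == "relative") "%" else ""
  cat(sprintf("Agreement: %s, %s vs %s (%s scale, n = %d)\n",
              x$parameter, x$comp_reader, x$ref_reader, x$scale, x$n))
  cat(sprintf("  bias (median diff):       %7.3f%s  [%.3f, %.3f]\n",
              x$bias, unit, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  precision (scaled):       %7.3f%s  [%.3f, %.3f]\n",
              x$precision, unit, x$ci_precision[1], x$ci_precision[2]))
  invisible(x)
}

#' @export
summary.echo_agreement <- function(object, ...) {
  print(object)
  unit <- if (object$scale == "relative") "%" else ""
  cat(sprintf("  precision (unscaled):     %7.3f%s\n", object$precision_unscaled, unit))
  cat(sprintf("  Bland-Altman LoA:         %7.3f [%.3f, %.3f]\n",
              object$loa$mean_bias, object$loa$lower, object$loa$upper))
  cat(sprintf("  RMS error:                %7.3f%s\n", object$rms, unit))
  cat(sprintf("  bootstrap: B = %d, conf = %.2f\n", object$B, object$conf))
  if (object$n_excluded_relative > 0)
    cat(sprintf("  %d pair(s) excluded from the relative scale\n",
                object$n_excluded_relative))
  invisible(object)
}

#' @export
coef.echo_agreement <- function(object, ...) {
  c(bias = object$bias, precision = object$precision)
}

#' @export
confint.echo_agreement <- function(object, parm = c("bias", "precision"),
                                   level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  out <- rbind(bias = as.numeric(object$ci_bias),
               precision = as.numeric(object$ci_precision))[parm, , drop = FALSE]
  colnames(out) <- sprintf("%.1f %%", c((1 - object$conf) / 2,
                                        1 - (1 - object$conf) / 2) * 100)
  out
}

#' @export
as.data.frame.echo_agreement <- function(x, ...) {
  data.frame(parameter = x$parameter, ref_reader = x$ref_reader,
             comp_reader = x$comp_reader, scale = x$scale, n = x$n,
             bias = x$bias, bias_lo = x$ci_bias[1], bias_hi = x$ci_bias[2],
             precision = x$precision,
             precision_lo = x$ci_precision[1], precision_hi = x$ci_precision[2],
             precision_unscaled = x$precision_unscaled,
             loa_lower = x$loa$lower, loa_upper = x$loa$upper,
             rms = x$rms, B = x$B, stringsAsFactors = FALSE)
}
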