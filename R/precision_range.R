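# Precision-range modelling: exact linear quantile regression at
# tau = 0.16 / 0.50 / 0.84 and the derived precision-vs-range curve.
#
# The pinball (check) loss rho_tau(u) = u * (tau - 1{u < 0}) is piecewise
# linear in (intercept, slope), so the minimum of the L1-type objective is
# attained at a vertex of the feasible polyhedron -- a line through two
# data points (when the x values are not all equal).  The fit enumerates
# all such candidate lines and evaluates the loss exactly, which is both
# the global optimum and directly testable against a brute-force oracle.

pinball_loss <- function(u, tau) sum(u * (tau - (u < 0)))

# Intercept-only pinball minimiser: the tau-quantile set of d.  When the
# optimum is a whole interval (n * tau integer) the midpoint is returned,
# so that tau = 0.5 always yields the sample median.
.pinball_intercept <- function(d, tau) {
  n <- length(d)
  v <- sort(d)
  k <- n * tau
  if (abs(k - round(k)) < 1e-9 && round(k) >= 1 && round(k) < n) {
    (v[round(k)] + v[round(k) + 1]) / 2
  } else {
    v[min(n, max(1L, ceiling(k)))]
  }
}

#' Exact linear quantile regression fit
#'
#' Finds (intercept, slope) minimizing the pinball loss
#' sum(rho_tau(d - a - b x)) exactly, by enumerating candidate lines
#' through pairs of data points (an optimal vertex of the underlying
#' linear program always passes through two data points).  Ties among
#' optima are broken by smallest slope magnitude, then smallest intercept.
#'
#' @param x numeric predictor (measurement-range axis, typically the pair
#'   mean).
#' @param d numeric response (differences), same length as \code{x}.
#' @param tau quantile level in (0, 1).
#' @param intercept_only force slope = 0 and fit the tau-quantile of
#'   \code{d} alone.
#' @return object of class \code{quantile_line}: \code{tau},
#'   \code{intercept}, \code{slope}, \code{pinball_loss}, \code{n}.
#' @export
#' @examples
#' quantile_line_fit(1:10, 2 * (1:10) + 1, tau = 0.5)  # recovers (1, 2)
quantile_line_fit <- function(x, d, tau, intercept_only = FALSE) {
  stopifnot(length(x) == length(d))
  keep <- complete.cases(x, d)
  x <- x[keep]; d <- d[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for a quantile line")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")

  if (!intercept_only && length(unique(x)) < 2L) {
    warning("all x identical: slope unidentifiable, fitting intercept only")
    intercept_only <- TRUE
  }
  if (intercept_only) {
    a <- .pinball_intercept(d, tau)
    return(structure(list(tau = tau, intercept = a, slope = 0,
                          pinball_loss = pinball_loss(d - a, tau), n = n),
                     class = "quantile_line"))
  }

  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  ok <- abs(dx) > 0
  b <- (d[ij[2, ]][ok] - d[ij[1, ]][ok]) / dx[ok]
  a <- d[ij[1, ]][ok] - b * x[ij[1, ]][ok]

  # Evaluate the loss of all candidate lines in memory-bounded chunks.
  K <- length(a)
  best <- NULL
  chunk <- max(1L, min(K, as.integer(2e6 / n)))
  tau_m <- tau
  for (s in seq(1L, K, by = chunk)) {
    e <- min(K, s + chunk - 1L)
    res <- outer(d, rep(1, e - s + 1L)) -
      outer(rep(1, n), a[s:e]) - outer(x, b[s:e])
    loss <- colSums(res * (tau_m - (res < 0)))
    cand <- data.frame(a = a[s:e], b = b[s:e], loss = loss)
    best <- rbind(best, cand[which.min(cand$loss), ])
    # keep near-ties for the final tie-break
    tol <- 1e-9 * (1 + abs(min(cand$loss)))
    best <- rbind(best, cand[cand$loss <= min(cand$loss) + tol, ])
  }
  tol <- 1e-9 * (1 + abs(min(best$loss)))
  opt <- best[best$loss <= min(best$loss) + tol, , drop = FALSE]
  opt <- opt[order(abs(opt$b), opt$a), , drop = FALSE]
  structure(list(tau = tau, intercept = opt$a[1], slope = opt$b[1],
                 pinball_loss = pinball_loss(d - opt$a[1] - opt$b[1] * x, tau),
                 n = n),
            class = "quantile_line")
}

#' @export
print.quantile_line <- function(x, ...) {
  cat(sprintf("tau = %.2f quantile line: q(x) = %.4g + %.4g x  (pinball loss %.4g, n = %d)\n",
              x$tau, x$intercept, x$slope, x$pinball_loss, x$n))
  invisible(x)
}

#' Fit a precision-range model
#'
#' Fits independent quantile lines at tau = 0.16, 0.50 and 0.84 of the
#' paired differences against the measurement-range axis (pair mean); the
#' precision-range curve is then p(x) = (q84(x) - q16(x)) / 2, divided by
#' sqrt(2) when \code{scaled = TRUE} (same per-measurement scaling as
#' \code{\link{percentile_precision}}).
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"} differences.
#' @param taus the three quantile levels (low, median, high).
#' @param scaled apply the sqrt(2) per-measurement scaling to the curve.
#' @return object of class \code{precision_range} holding the three
#'   \code{quantile_line}s.  Methods: \code{print}, \code{predict} (returns
#'   per-x quantiles and precision), \code{coef}, \code{plot}.
#' @export
#' @examples
#' cc <- generate_case_control_cohort(cohort_config(n_healthy = 40, n_case = 40), seed = 4)
#' ds <- paired_differences(cc$measurements, "TRV", "CL1", "DL")
#' pr <- precision_range(ds)
#' predict(pr, newdata = c(2.5, 4.0))
precision_range <- function(ds, scale = c("relative", "nominal"),
                            taus = c(0.16, 0.5, 0.84), scaled = TRUE) {
  scale <- match.arg(scale)
  stopifnot(length(taus) == 3L, all(diff(taus) > 0))
  v <- if (scale == "nominal") ds$d else ds$r
  keep <- !is.na(v)
  x <- ds$x[keep]; v <- v[keep]
  lines <- lapply(taus, function(tau) quantile_line_fit(x, v, tau))
  names(lines) <- sprintf("tau_%g", taus)
  structure(list(lines = lines, taus = taus, scaled = scaled, scale = scale,
                 parameter = ds$parameter, ref_reader = ds$ref_reader,
                 comp_reader = ds$comp_reader, x = x, d = v, n = length(v)),
            class = "precision_range")
}

#' @export
print.precision_range <- function(x, ...) {
  cat(sprintf("Precision-range model: %s, %s vs %s (%s scale, n = %d, %s)\n",
              x$parameter, x$comp_reader, x$ref_reader, x$scale, x$n,
              if (x$scaled) "scaled by 1/sqrt(2)" else "unscaled"))
  for (l in x$lines) print(l)
  invisible(x)
}

#' @export
coef.precision_range <- function(object, ...) {
  t(vapply(object$lines, function(l) c(intercept = l$intercept, slope = l$slope),
           numeric(2)))
}

#' Evaluate a precision-range model
#'
#' @param object a \code{\link{precision_range}} fit.
#' @param newdata numeric vector of measurement-range values.
#' @param ... unused.
#' @return data frame with the three quantile lines evaluated at
#'   \code{newdata} and the precision curve \code{precision}.  A negative
#'   precision (crossing quantile lines) triggers a warning and is
#'   returned as-is, never clipped.
#' @export
predict.precision_range <- function(object, newdata, ...) {
  q <- vapply(object$lines, function(l) l$intercept + l$slope * newdata,
              numeric(length(newdata)))
  q <- matrix(q, nrow = length(newdata),
              dimnames = list(NULL, names(object$lines)))
  p <- (q[, 3] - q[, 1]) / 2
  if (object$scaled) p <- p / sqrt(2)
  if (any(p < 0))
    warning("quantile lines cross: negative precision at ",
            sum(p < 0), " evaluation point(s)")
  data.frame(x = newdata, q, precision = p, check.names = FALSE)
}

#' Precision across the measurement range
#'
#' Convenience wrapper: p(x) = (q84(x) - q16(x)) / 2 at each supplied x,
#' divided by sqrt(2) if the model was fitted with \code{scaled = TRUE}.
#'
#' @param model a \code{\link{precision_range}} fit.
#' @param x_values numeric evaluation points (e.g. representative lower and
#'   higher measurement values).
#' @return numeric vector of precision values (negative where the quantile
#'   lines cross, with a warning).
#' @export
precision_range_curve <- function(model, x_values) {
  stopifnot(inherits(model, "precision_range"))
  predict(model, x_values)$precision
}

#' @export
plot.precision_range <- function(x, ...) {
  plot(x$x, x$d,
       xlab = sprintf("pair mean (%s)", x$parameter),
       ylab = if (x$scale == "relative") "relative difference (%)" else "difference",
       main = sprintf("Quantile lines: %s, %s vs %s",
                      x$parameter, x$comp_reader, x$ref_reader), ...)
  xs <- range(x$x)
  for (i in seq_along(x$lines)) {
    l <- x$lines[[i]]
    lines(xs, l$intercept + l$slope * xs, lty = c(2, 1, 2)[i])
  }
  invisible(x)
}
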