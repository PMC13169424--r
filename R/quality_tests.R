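# Image-quality stratified tests: Kruskal-Wallis for median differences,
# Levene (Brown-Forsythe) for equality of variance.

.as_group_list <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  groups
}

#' Kruskal-Wallis test across difference groups
#'
#' Rank-based test of equal group medians (midranks with tie correction;
#' chi-square reference with k - 1 df).  The degenerate case where every
#' value in every group is identical returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors (one per group, e.g. per quality
#'   category).
#' @return object of class \code{group_test}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{group_sizes}, \code{method}.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(values) < 3L) stop("need at least 3 observations in total")
  if (length(unique(values)) == 1L) {
    stat <- 0; p <- 1
  } else {
    kt <- kruskal.test(values, g)
    stat <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic = stat, df = length(groups) - 1L,
                 p_value = p,
                 group_sizes = vapply(groups, length, 1L),
                 method = "Kruskal-Wallis"),
            class = "group_test")
}

#' Levene test for equality of variance (Brown-Forsythe by default)
#'
#' One-way ANOVA F on absolute deviations from the group centre.  The
#' default centre is the group median (the Brown-Forsythe variant, robust
#' to non-normal differences); \code{center = "mean"} gives the classical
#' Levene test.  If all deviations are zero the statistic is 0 with p = 1.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return object of class \code{group_test} with \code{statistic} (F),
#'   \code{df} = c(k - 1, N - k), \code{p_value}, \code{group_sizes}.
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- .as_group_list(groups)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  cfun <- if (center == "median") median else mean
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  k <- length(z); N <- sum(sizes)
  zbar_j <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(sizes * (zbar_j - zbar)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(j) sum((z[[j]] - zbar_j[j])^2), numeric(1)))
  if (ss_within <= 0) {
    if (ss_between <= 0) { stat <- 0; p <- 1 } else { stat <- Inf; p <- 0 }
  } else {
    stat <- (ss_between / (k - 1)) / (ss_within / (N - k))
    p <- pf(stat, k - 1, N - k, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = c(k - 1L, N - k),
                 p_value = p, group_sizes = sizes,
                 method = sprintf("Levene (%s-centred)", center)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %s, p = %.4g (group sizes: %s)\n",
              x$method, x$statistic, paste(x$df, collapse = "/"),
              x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Image-quality impact on bias and dispersion
#'
#' Splits the paired differences of a \code{\link{diff_set}} by the shared
#' image-quality category and runs the Kruskal-Wallis test (location /
#' bias) and the Levene test (dispersion / precision) across categories.
#'
#' @param ds a \code{\link{diff_set}} carrying quality categories.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @param center Levene centring, see \code{\link{levene_test}}.
#' @return list with \code{kruskal}, \code{levene}, and the per-category
#'   difference counts.
#' @export
quality_impact <- function(ds, scale = c("relative", "nominal"),
                           center = "median") {
  scale <- match.arg(scale)
  if (is.null(ds$quality)) stop("difference set carries no quality categories")
  v <- if (scale == "nominal") ds$d else ds$r
  keep <- !is.na(v) & !is.na(ds$quality)
  groups <- split(v[keep], droplevels(ds$quality[keep]))
  list(kruskal = kruskal_wallis(groups),
       levene = levene_test(groups, center = center),
       n_by_category = vapply(groups, length, 1L))
}
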