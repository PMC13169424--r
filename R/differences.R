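# Paired differences between two readers, and relative yield accounting.

#' Relative yield of a comparator reader
#'
#' The relative yield is the proportion of reference-reader reads for which
#' the comparator also produced a value: 100 * n_common / n_ref.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param parameter parameter name.
#' @param ref_reader,comp_reader reader ids.
#' @return list of class \code{yield_result}: \code{parameter},
#'   \code{n_ref}, \code{n_comp}, \code{n_common},
#'   \code{relative_yield_pct} (full precision; round only for display).
#' @export
#' @examples
#' cc <- generate_case_control_cohort(cohort_config(n_healthy = 30, n_case = 30), seed = 2)
#' compute_yield(cc$measurements, "TRV", "CL1", "DL")
compute_yield <- function(table, parameter, ref_reader, comp_reader) {
  stopifnot(inherits(table, "measurement_table"))
  sub <- table[table$parameter == parameter, , drop = FALSE]
  ref_ids <- sub$subject_id[sub$reader == ref_reader]
  comp_ids <- sub$subject_id[sub$reader == comp_reader]
  n_ref <- length(ref_ids)
  if (n_ref == 0L)
    stop("no reference reads for ", parameter, " by ", ref_reader,
         ": relative yield undefined")
  n_common <- length(intersect(ref_ids, comp_ids))
  structure(list(parameter = parameter, ref_reader = ref_reader,
                 comp_reader = comp_reader,
                 n_ref = n_ref, n_comp = length(comp_ids),
                 n_common = n_common,
                 relative_yield_pct = 100 * n_common / n_ref),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("%s: %s yield relative to %s = %.1f%% (%d/%d; %s reads %d)\n",
              x$parameter, x$comp_reader, x$ref_reader,
              x$relative_yield_pct, x$n_common, x$n_ref,
              x$comp_reader, x$n_comp))
  invisible(x)
}

#' Paired differences between two readers for one parameter
#'
#' For each subject read by both readers, forms the nominal difference
#' d = comp - ref (positive when the comparator reads higher), the relative
#' difference r = 100 * d / pair mean, and the measurement-range axis
#' x = pair mean.  Pairs with nonpositive pair means are excluded from the
#' relative scale (relative difference undefined) and counted.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param parameter parameter name.
#' @param ref_reader,comp_reader reader ids.
#' @return object of class \code{diff_set} with elements \code{ref},
#'   \code{comp}, \code{d} (nominal), \code{r} (relative, %), \code{x}
#'   (pair means), \code{quality} (shared image-quality category where
#'   recorded), \code{subject_id}, \code{n}, \code{n_excluded_relative}.
#' @export
paired_differences <- function(table, parameter, ref_reader, comp_reader) {
  stopifnot(inherits(table, "measurement_table"))
  sub <- as.data.frame(table[table$parameter == parameter, , drop = FALSE])
  a <- sub[sub$reader == ref_reader, c("subject_id", "value", "quality_score")]
  b <- sub[sub$reader == comp_reader, c("subject_id", "value")]
  m <- merge(a, b, by = "subject_id", suffixes = c("_ref", "_comp"))
  if (nrow(m) == 0L)
    stop("no common reads for ", parameter, " between ",
         ref_reader, " and ", comp_reader)
  diff_set(ref = m$value_ref, comp = m$value_comp,
           parameter = parameter, ref_reader = ref_reader,
           comp_reader = comp_reader, subject_id = m$subject_id,
           quality = quality_category(m$quality_score))
}

#' Build a difference set from raw paired values
#'
#' Lower-level constructor used by \code{\link{paired_differences}};
#' useful when paired reads come from outside a measurement table.
#'
#' @param ref,comp numeric vectors of equal length (reference and
#'   comparator reads on the same subjects).
#' @param parameter,ref_reader,comp_reader labels carried along.
#' @param subject_id optional ids.
#' @param quality optional quality categories (factor good/moderate/low).
#' @return a \code{diff_set}.
#' @export
diff_set <- function(ref, comp, parameter = "value", ref_reader = "ref",
                     comp_reader = "comp", subject_id = NULL, quality = NULL) {
  stopifnot(length(ref) == length(comp), length(ref) >= 1)
  d <- comp - ref
  x <- (ref + comp) / 2
  bad_rel <- x <= 0
  r <- ifelse(bad_rel, NA_real_, 100 * d / x)
  structure(list(parameter = parameter, ref_reader = ref_reader,
                 comp_reader = comp_reader,
                 subject_id = if (is.null(subject_id)) as.character(seq_along(d)) else as.character(subject_id),
                 ref = ref, comp = comp, d = d, r = r, x = x,
                 quality = quality,
                 n = length(d),
                 n_excluded_relative = sum(bad_rel)),
            class = "diff_set")
}

#' Extract the differences of a diff_set on one scale
#'
#' Returns the nominal or relative differences with undefined
#' (nonpositive-pair-mean) relative entries removed.  Every downstream
#' statistic consumes differences through this accessor.
#'
#' @param ds a \code{\link{diff_set}}.
#' @param scale \code{"relative"} or \code{"nominal"}.
#' @return numeric vector of differences.
#' @export
diffs_on_scale <- function(ds, scale = c("relative", "nominal")) {
  scale <- match.arg(scale)
  v <- if (scale == "nominal") ds$d else ds$r
  v[!is.na(v)]
}

#' @export
print.diff_set <- function(x, ...) {
  cat(sprintf("Paired differences: %s, %s vs %s (n = %d)\n",
              x$parameter, x$comp_reader, x$ref_reader, x$n))
  if (x$n_excluded_relative > 0)
    cat(sprintf("  %d pair(s) with nonpositive pair mean excluded from the relative scale\n",
                x$n_excluded_relative))
  cat(sprintf("  nominal: median %.4g, IQR [%.4g, %.4g]\n",
              median(x$d), quantile(x$d, .25, type = 7), quantile(x$d, .75, type = 7)))
  invisible(x)
}

#' Bland-Altman plot of a difference set
#'
#' @param x a \code{diff_set}.
#' @param scale \code{"relative"} (\%) or \code{"nominal"}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the limits of agreement.
#' @export
plot.diff_set <- function(x, scale = c("relative", "nominal"), ...) {
  scale <- match.arg(scale)
  v <- if (scale == "nominal") x$d else x$r
  keep <- !is.na(v)
  loa <- bland_altman_loa(x, scale = scale)
  plot(x$x[keep], v[keep],
       xlab = sprintf("pair mean (%s)", x$parameter),
       ylab = if (scale == "relative") "relative difference (%)" else "difference",
       main = sprintf("%s: %s vs %s", x$parameter, x$comp_reader, x$ref_reader),
       ...)
  abline(h = loa$mean_bias, lty = 1)
  abline(h = c(loa$lower, loa$upper), lty = 2)
  invisible(loa)
}
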