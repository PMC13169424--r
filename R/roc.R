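# Discrimination: midrank AUC, DeLong paired comparison, PH labelling,
# case-control matching, and the guideline supporting-criteria category.

# DeLong structural components via midranks.
# V10[i] = P(marker_pos_i > neg) + 0.5 P(=), one entry per positive;
# V01[j] analogous per negative.  mean(V10) = mean(V01) = AUC.
.delong_components <- function(marker, labels) {
  pos <- marker[labels == 1]
  neg <- marker[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m < 1L || n < 1L) stop("need at least one positive and one negative")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  V10 <- (r_all[seq_len(m)] - r_pos) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(V10 = V10, V01 = V01, auc = mean(V10), m = m, n = n)
}

.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2L)
    stop("need both classes present to compute an AUC")
  labels
}

#' AUC of a diagnostic marker (midrank / Mann-Whitney estimator)
#'
#' AUC is the mean over all positive/negative pairs of 1 if the positive
#' subject's marker exceeds the negative's, 1/2 if tied.  The confidence
#' interval uses the DeLong structural-component variance with a normal
#' approximation.
#'
#' @param marker numeric marker values.
#' @param labels binary labels (1 = disease).
#' @param direction \code{"higher"} if larger marker values indicate
#'   disease (default), \code{"lower"} to flip the marker (e.g. TAPSE,
#'   RVFAC); \code{"auto"} looks the parameter up in
#'   \code{\link{echo_marker_orientation}} via \code{parameter}.
#' @param parameter parameter name, used only by \code{direction = "auto"}.
#' @param conf confidence level for the CI.
#' @return object of class \code{roc_result}: \code{auc}, \code{var},
#'   \code{ci}, \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(marker, labels, direction = c("higher", "lower", "auto"),
                    parameter = NULL, conf = 0.95) {
  direction <- match.arg(direction)
  labels <- .check_labels(labels)
  keep <- !is.na(marker)
  marker <- marker[keep]; labels <- labels[keep]
  if (direction == "auto") {
    if (is.null(parameter)) stop("direction = 'auto' needs a parameter name")
    o <- echo_marker_orientation()[[parameter]]
    if (is.null(o)) stop("unknown parameter: ", parameter)
    if (o < 0) marker <- -marker
  } else if (direction == "lower") {
    marker <- -marker
  }
  cm <- .delong_components(marker, labels)
  v <- var(cm$V10) / cm$m + var(cm$V01) / cm$n
  zq <- qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, cm$auc - zq * sqrt(v)), min(1, cm$auc + zq * sqrt(v)))
  structure(list(auc = cm$auc, var = v, ci = ci,
                 n_pos = cm$m, n_neg = cm$n, conf = conf),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f; %d positives, %d negatives)\n",
              x$auc, 100 * x$conf, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired AUC comparison by the DeLong method
#'
#' Both markers must be observed on the same subjects with the same
#' labels.  Variances and the covariance of the two AUCs are estimated
#' from the structural components (midranks throughout); the test is a
#' two-sided z test on the AUC difference.
#'
#' @param marker1,marker2 numeric marker vectors on the same subjects.
#' @param labels binary labels (1 = disease).
#' @return object of class \code{delong_comparison}: \code{auc1},
#'   \code{auc2}, \code{var1}, \code{var2}, \code{covariance}, \code{z},
#'   \code{p_value}.  Comparing a marker with itself yields z = 0, p = 1;
#'   a degenerate zero-variance difference with unequal AUCs is reported
#'   as non-computable (NA with a warning).
#' @export
delong_compare <- function(marker1, marker2, labels) {
  stopifnot(length(marker1) == length(marker2))
  labels <- .check_labels(labels)
  keep <- !is.na(marker1) & !is.na(marker2)
  c1 <- .delong_components(marker1[keep], labels[keep])
  c2 <- .delong_components(marker2[keep], labels[keep])
  m <- c1$m; n <- c1$n
  v1 <- var(c1$V10) / m + var(c1$V01) / n
  v2 <- var(c2$V10) / m + var(c2$V01) / n
  cv <- cov(c1$V10, c2$V10) / m + cov(c1$V01, c2$V01) / n
  denom2 <- v1 + v2 - 2 * cv
  dauc <- c1$auc - c2$auc
  if (denom2 <= .Machine$double.eps) {
    if (abs(dauc) <= sqrt(.Machine$double.eps)) {
      z <- 0; p <- 1
    } else {
      warning("zero variance of the AUC difference with unequal AUCs: ",
              "test non-computable")
      z <- NA_real_; p <- NA_real_
    }
  } else {
    z <- dauc / sqrt(denom2)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc1 = c1$auc, auc2 = c2$auc, var1 = v1, var2 = v2,
                 covariance = cv, z = z, p_value = p,
                 n_pos = m, n_neg = n),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc1, x$auc2, x$z, x$p_value))
  invisible(x)
}

#' Classify pulmonary hypertension from mean pulmonary artery pressure
#'
#' PH is defined by a strict MPAP > 20 mm Hg; exactly 20 is no_PH.
#'
#' @param mpap_mmhg positive MPAP values (mm Hg).
#' @return factor with levels \code{no_PH, PH}.
#' @export
#' @examples
#' classify_ph(c(20, 21, 36))
classify_ph <- function(mpap_mmhg) {
  if (any(is.na(mpap_mmhg)) || any(mpap_mmhg <= 0))
    stop("MPAP must be present and > 0")
  factor(ifelse(mpap_mmhg > 20, "PH", "no_PH"), levels = c("no_PH", "PH"))
}

#' Referral eligibility: mild-PH band
#'
#' Subjects with MPAP > 35 mm Hg fall outside the mild-PH referral band.
#'
#' @param mpap_mmhg positive MPAP values (mm Hg).
#' @return logical: \code{TRUE} iff MPAP <= 35.
#' @export
referral_eligible <- function(mpap_mmhg) {
  if (any(is.na(mpap_mmhg)) || any(mpap_mmhg <= 0))
    stop("MPAP must be present and > 0")
  mpap_mmhg <= 35
}

#' Greedy age- and sex-matched case-control construction
#'
#' 1:1 matching within exact sex, nearest age.  Cases are processed in
#' order of increasing match difficulty (fewest eligible controls first,
#' ties by case id); each takes the nearest-age unused control of the same
#' sex (ties by lexicographic control id).  Pairs whose age gap exceeds
#' the caliper are rejected.
#'
#' @param cases,controls data frames with columns \code{id}, \code{age},
#'   \code{sex}.
#' @param caliper_years maximum allowed age gap (default \code{Inf}).
#' @return object of class \code{matched_cohort}: \code{pairs} (data frame
#'   case_id / control_id / age_gap), \code{unmatched_cases},
#'   \code{unmatched_controls}, \code{caliper_years}.
#' @export
match_case_control <- function(cases, controls, caliper_years = Inf) {
  need <- c("id", "age", "sex")
  stopifnot(all(need %in% names(cases)), all(need %in% names(controls)),
            nrow(cases) > 0, nrow(controls) > 0)
  cases$id <- as.character(cases$id)
  controls$id <- as.character(controls$id)

  eligible_count <- vapply(seq_len(nrow(cases)), function(i) {
    sum(controls$sex == cases$sex[i] &
          abs(controls$age - cases$age[i]) <= caliper_years)
  }, numeric(1))
  ord <- order(eligible_count, cases$id)

  used <- rep(FALSE, nrow(controls))
  pairs <- list()
  for (i in ord) {
    cand <- which(!used & controls$sex == cases$sex[i] &
                    abs(controls$age - cases$age[i]) <= caliper_years)
    if (!length(cand)) next
    gap <- abs(controls$age[cand] - cases$age[i])
    cand <- cand[order(gap, controls$id[cand])]
    j <- cand[1]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cases$id[i], control_id = controls$id[j],
      age_gap = abs(controls$age[j] - cases$age[i]),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(), control_id = character(),
               age_gap = numeric(), stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_cases = setdiff(cases$id, pairs$case_id),
                 unmatched_controls = setdiff(controls$id, pairs$control_id),
                 caliper_years = caliper_years),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d pairs (caliper %s y); %d case(s), %d control(s) unmatched\n",
              nrow(x$pairs),
              if (is.finite(x$caliper_years)) format(x$caliper_years) else "none",
              length(x$unmatched_cases), length(x$unmatched_controls)))
  invisible(x)
}

#' Guideline TRV probability bands (editable constant)
#'
#' Echocardiographic probability of PH from peak TRV, per the European
#' guideline convention: TRV <= 2.8 m/s low, 2.9-3.4 intermediate,
#' > 3.4 high.  Kept as a constant table (not hard-wired logic) because
#' the thresholds originate in external guidelines.
#'
#' @return list with \code{low_max} and \code{intermediate_max} (m/s).
#' @export
trv_probability_bands <- function() {
  list(low_max = 2.8, intermediate_max = 3.4)
}

#' Guideline supporting-criteria probability category
#'
#' Base category from peak TRV via \code{\link{trv_probability_bands}};
#' two or more supporting signs (from other echocardiographic criteria)
#' raise the category one level, capped at high.  A missing TRV with >= 2
#' signs maps to intermediate, otherwise low.
#'
#' @param trv_ms peak TRV in m/s, or \code{NA}.
#' @param n_supporting_signs nonnegative integer count of supporting signs.
#' @param bands threshold table, default \code{\link{trv_probability_bands}}.
#' @return factor level among \code{low, intermediate, high}.
#' @export
#' @examples
#' supporting_criteria_score(3.0, 2)  # upgraded to high
supporting_criteria_score <- function(trv_ms, n_supporting_signs = 0,
                                      bands = trv_probability_bands()) {
  stopifnot(length(trv_ms) == 1L, length(n_supporting_signs) == 1L)
  if (is.na(n_supporting_signs) || n_supporting_signs < 0)
    stop("n_supporting_signs must be a nonnegative integer")
  lv <- c("low", "intermediate", "high")
  if (is.na(trv_ms)) {
    base <- if (n_supporting_signs >= 2) "intermediate" else "low"
    return(factor(base, levels = lv))
  }
  base <- if (trv_ms <= bands$low_max) 1L
          else if (trv_ms <= bands$intermediate_max) 2L
          else 3L
  if (n_supporting_signs >= 2) base <- min(base + 1L, 3L)
  factor(lv[base], levels = lv)
}
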