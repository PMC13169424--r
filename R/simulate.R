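# Synthetic cohort generators with known ground truth.
#
# Generative model (case-control): each subject carries a latent severity
# z ~ N(0,1); the true value of parameter p is
#   theta_p = mu[g,p] + sigma[g,p] * (lambda_p * z + sqrt(1-lambda_p^2) * eps_p)
# truncated to physiologic bounds.  Image quality is a property of the
# acquired image (one draw per subject x parameter, shared by all readers).
# Each reader returns theta_p * (1 + delta) with delta ~ N(bias/100,
# (sd * quality multiplier / 100)^2), and returns anything at all with the
# reader's per-parameter yield probability.

# Draw a truncated shifted/scaled normal: mu + sigma * w with the latent
# severity part fixed, rejecting only the independent component.
.draw_truth <- function(mu, sigma, lambda, z, lo, hi, max_tries = 200L) {
  resid <- sqrt(1 - lambda^2)
  for (i in seq_len(max_tries)) {
    theta <- mu + sigma * (lambda * z + resid * rnorm(1))
    if (theta > lo && theta < hi) return(theta)
  }
  min(max(theta, lo + 1e-6), hi - 1e-6)
}

# Multiplicative reader error; rejects draws that would push the read out
# of its admissible range (positive; (0,100) for RVFAC).
.apply_reader_error <- function(theta, parameter, mean_delta, sd_delta,
                                max_tries = 200L) {
  hi <- if (parameter == "RVFAC") 100 else Inf
  for (i in seq_len(max_tries)) {
    read <- theta * (1 + rnorm(1, mean_delta, sd_delta))
    if (read > 0 && read < hi) return(read)
  }
  min(max(read, 1e-6), hi - 1e-6)
}

.quality_levels <- c("good", "moderate", "low")

# One subject's reads across all parameters and readers.  Returns flat
# vectors (no data frames: this runs once per subject).  Uses whatever RNG
# stream is active; callers wrap it in the subject's child stream.
.simulate_subject <- function(subject_id, cohort, group, age, sex, z,
                              dists, readers, quality_probs, contamination,
                              theta_override = NULL, mpap = NA_real_,
                              interp_w = NA_real_) {
  npar <- nrow(dists)
  reader_ids <- names(readers)
  nr <- length(reader_ids)

  theta <- numeric(npar)
  qcat <- character(npar)
  qscore <- integer(npar)
  val <- numeric(npar * nr); par_out <- character(npar * nr)
  rdr_out <- character(npar * nr); qs_out <- integer(npar * nr)
  present <- matrix(FALSE, npar, nr, dimnames = list(dists$parameter, reader_ids))
  k <- 0L
  for (j in seq_len(npar)) {
    p <- dists$parameter[j]
    if (!is.null(theta_override) && !is.na(theta_override[j])) {
      theta[j] <- theta_override[j]
    } else {
      if (!is.na(interp_w)) {
        mu <- dists$mean_healthy[j] + (dists$mean_case[j] - dists$mean_healthy[j]) * interp_w
        sg <- dists$sd_healthy[j] + (dists$sd_case[j] - dists$sd_healthy[j]) * interp_w
      } else if (group == "healthy") {
        mu <- dists$mean_healthy[j]; sg <- dists$sd_healthy[j]
      } else {
        mu <- dists$mean_case[j]; sg <- dists$sd_case[j]
      }
      theta[j] <- .draw_truth(mu, sg, dists$severity_loading[j], z,
                              dists$lower_bound[j], dists$upper_bound[j])
    }
    u <- runif(1)
    qcat[j] <- if (u < quality_probs[[1]]) "good"
               else if (u < quality_probs[[1]] + quality_probs[[2]]) "moderate"
               else "low"
    qscore[j] <- switch(qcat[j],
                        good = if (runif(1) < 0.5) 4L else 5L,
                        moderate = 3L,
                        low = if (runif(1) < 0.5) 1L else 2L)

    for (ri in seq_len(nr)) {
      rm <- readers[[ri]]
      if (runif(1) > rm$yield_prob[[p]]) next
      present[j, ri] <- TRUE
      sd_delta <- rm$sd_pct[[p]] * rm$quality_sd_multiplier[[qcat[j]]] / 100
      if (contamination > 0 && runif(1) < contamination) sd_delta <- sd_delta * 5
      mean_delta <- (rm$bias_pct[[p]] + rm$quality_bias_offset[[qcat[j]]]) / 100
      k <- k + 1L
      val[k] <- .apply_reader_error(theta[j], p, mean_delta, sd_delta)
      par_out[k] <- p
      rdr_out[k] <- reader_ids[ri]
      qs_out[k] <- qscore[j]
    }
  }
  idx <- seq_len(k)
  list(subject_id = subject_id, cohort = cohort, group = group,
       age = age, sex = sex, z = z, mpap = mpap,
       parameter = par_out[idx], reader = rdr_out[idx], value = val[idx],
       quality_score = qs_out[idx],
       truth_parameter = dists$parameter, theta = theta, present = present)
}

# Assemble the per-subject results into (measurement_table, truth).
.assemble_cohort <- function(sims, reader_ids) {
  counts <- vapply(sims, function(s) length(s$value), 1L)
  if (sum(counts) == 0L) stop("generator produced no reads; check yield_prob")
  meas <- data.frame(
    subject_id = rep(vapply(sims, `[[`, "", "subject_id"), counts),
    cohort = rep(vapply(sims, `[[`, "", "cohort"), counts),
    group = rep(vapply(sims, `[[`, "", "group"), counts),
    parameter = unlist(lapply(sims, `[[`, "parameter")),
    reader = unlist(lapply(sims, `[[`, "reader")),
    value = unlist(lapply(sims, `[[`, "value")),
    quality_score = unlist(lapply(sims, `[[`, "quality_score")),
    age_years = rep(vapply(sims, `[[`, 0, "age"), counts),
    sex = rep(vapply(sims, `[[`, "", "sex"), counts),
    stringsAsFactors = FALSE)
  meas$units <- unname(echo_parameter_units()[meas$parameter])

  npar <- length(sims[[1]]$truth_parameter)
  truth <- data.frame(
    subject_id = rep(vapply(sims, `[[`, "", "subject_id"), each = npar),
    parameter = rep(sims[[1]]$truth_parameter, length(sims)),
    theta = unlist(lapply(sims, `[[`, "theta")),
    severity = rep(vapply(sims, `[[`, 0, "z"), each = npar),
    group = rep(vapply(sims, `[[`, "", "group"), each = npar),
    mpap_mmhg = rep(vapply(sims, `[[`, 0, "mpap"), each = npar),
    stringsAsFactors = FALSE)
  for (ri in seq_along(reader_ids)) {
    truth[[paste0("present_", reader_ids[ri])]] <-
      unlist(lapply(sims, function(s) s$present[, ri]))
  }
  list(measurements = measurement_table(meas), truth = truth)
}

#' Generate a synthetic case-control cohort
#'
#' Draws a healthy and a case (PAH-like) group with per-parameter normal
#' distributions tied together by a shared latent severity factor, then
#' produces per-reader reads under each reader's multiplicative bias,
#' imprecision, quality-dependent error inflation, and yield.  Fully
#' reproducible: each subject has a child RNG stream derived from the root
#' seed, so the table is identical for identical (config, seed).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer root seed.
#' @return list with \code{measurements} (a
#'   \code{\link{measurement_table}}) and \code{truth} (data frame of true
#'   values, latent severity, group, and per-reader inclusion indicators).
#' @export
#' @examples
#' cc <- generate_case_control_cohort(cohort_config(n_healthy = 20, n_case = 20), seed = 1)
#' head(cc$truth)
generate_case_control_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_healthy + config$n_case
  groups <- rep(c("healthy", "PAH"), c(config$n_healthy, config$n_case))
  gkey <- ifelse(groups == "healthy", "healthy", "case")
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    sims[[i]] <- with_seed(child_seed(seed, i), {
      z <- rnorm(1)
      age <- max(18, rnorm(1, config$age_mean[[gkey[i]]], config$age_sd[[gkey[i]]]))
      sex <- if (runif(1) < config$prop_female[[gkey[i]]]) "F" else "M"
      .simulate_subject(sprintf("S%04d", i), "case_control", groups[i],
                        round(age, 1), sex, z,
                        config$distributions, config$readers,
                        config$quality_probs, config$contamination)
    })
  }
  .assemble_cohort(sims, names(config$readers))
}

# CDF of the two-piece uniform MPAP mixture.
.mpap_percentile <- function(m, lo, hi, p_below) {
  ifelse(m < 20,
         p_below * (m - lo) / (20 - lo),
         p_below + (1 - p_below) * (m - 20) / max(hi - 20, .Machine$double.eps))
}

#' Generate a synthetic referral cohort with hemodynamics
#'
#' Subjects referred for right heart catheterization with continuous MPAP
#' on the mild band (support within 10-35 mm Hg; mass below vs above the
#' 20 mm Hg PH threshold set by \code{prob_below_20}).  Systolic pulmonary
#' pressure follows the configured linear coupling sPAP = a * MPAP + b, and
#' the true peak TRV follows the simplified Bernoulli relation
#' TRV = sqrt((sPAP - RAP)/4).  Other parameters are tied to the subject's
#' MPAP percentile, interpolating between the healthy and case
#' distributions.  Reader reads are produced as in the case-control
#' generator.
#'
#' @param config a \code{\link{cohort_config}} with a \code{referral} block.
#' @param seed integer root seed.
#' @return list with \code{measurements}, \code{hemodynamics} (subject_id,
#'   mpap_mmhg, days_echo_to_rhc), and \code{truth}.
#' @export
generate_referral_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  ref <- config$referral
  if (is.null(ref)) stop("config has no referral block")
  n <- ref$n_subjects
  lo <- ref$mpap_range[1]; hi <- ref$mpap_range[2]
  readers <- config$readers[intersect(names(config$readers), ref$readers)]
  for (r in setdiff(ref$readers, names(readers))) {
    # Clinical-report reads: treated as an expert reader with core-lab
    # error structure and the core-lab attempt rates.
    proto <- config$readers[["CL1"]]
    readers[[r]] <- reader_error_model(r, bias_pct = 0, sd_pct = proto$sd_pct,
                                       yield_prob = proto$yield_prob)
  }
  trv_row <- which(config$distributions$parameter == "TRV")
  sims <- vector("list", n)
  hemo <- data.frame(subject_id = sprintf("R%04d", seq_len(n)),
                     mpap_mmhg = numeric(n),
                     days_echo_to_rhc = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- with_seed(child_seed(seed, 10^6 + i), {
      mpap <- if (runif(1) < ref$prob_below_20) runif(1, lo, min(20, hi))
              else runif(1, max(20, lo), hi)
      spap <- ref$spap_a * mpap + ref$spap_b
      if (spap <= ref$rap_mmhg) stop("sPAP <= RAP: TRV undefined; check coupling")
      pct <- .mpap_percentile(mpap, lo, hi, ref$prob_below_20)
      pct <- min(max(pct, 1e-6), 1 - 1e-6)
      z <- qnorm(pct)
      theta_override <- rep(NA_real_, nrow(config$distributions))
      if (length(trv_row)) theta_override[trv_row] <- sqrt((spap - ref$rap_mmhg) / 4)
      age <- max(18, rnorm(1, 62, 16))
      sex <- if (runif(1) < 0.53) "F" else "M"
      days <- max(0L, as.integer(round(rlnorm(1, log(23), 1.1))))
      s <- .simulate_subject(hemo$subject_id[i], "referral", "unknown",
                             round(age, 1), sex, z,
                             config$distributions, readers,
                             config$quality_probs, config$contamination,
                             theta_override = theta_override, mpap = mpap,
                             interp_w = pct)
      list(sim = s, mpap = mpap, days = days)
    })
    sims[[i]] <- res$sim
    hemo$mpap_mmhg[i] <- res$mpap
    hemo$days_echo_to_rhc[i] <- res$days
  }
  out <- .assemble_cohort(sims, names(readers))
  list(measurements = out$measurements, hemodynamics = hemo,
       truth = out$truth)
}
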