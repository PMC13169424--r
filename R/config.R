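# Cohort configuration: parameter distributions, reader error models,
# quality structure, and the referral (hemodynamics) block.

#' Default per-parameter distributions for healthy and PAH groups
#'
#' Means and SDs are the reported right-heart reference values for a healthy
#' adult cohort and a PAH cohort (TRV in m/s, diameters in mm, areas in
#' cm^2, RVFAC in %).  Truncation bounds are loose physiologic limits;
#' \code{severity_loading} is the weight of a shared latent severity factor
#' inducing cross-parameter correlation within subject.
#'
#' @param severity_loading shared-factor loading in [-1, 1], applied to all
#'   parameters.
#' @return data frame, one row per parameter.
#' @export
default_parameter_distributions <- function(severity_loading = 0.7) {
  d <- data.frame(
    parameter    = c("TRV", "RV_basal_diameter", "TAPSE", "RA_area",
                     "RVEDA", "RVESA", "RVFAC"),
    mean_healthy = c(2.1, 37.8, 25.1, 15.9, 22.2, 13.3, 39.9),
    sd_healthy   = c(0.5,  8.3,  3.6,  4.1,  5.5,  3.4,  3.6),
    mean_case    = c(4.1, 54.8, 16.1, 23.3, 37.4, 30.5, 19.7),
    sd_case      = c(0.7, 10.2,  4.8,  9.3, 11.6, 11.2,  6.5),
    lower_bound  = c(0.5, 10,    2,    4,    5,    2,    2),
    upper_bound  = c(7,   100,  50,   80,  100,   90,   75),
    stringsAsFactors = FALSE
  )
  # Higher severity means worse disease: larger TRV/diameter/areas, smaller
  # TAPSE/RVFAC.  The sign of the loading encodes the direction.
  d$severity_loading <- severity_loading * unname(echo_marker_orientation()[d$parameter])
  d
}

#' Reader error model
#'
#' Each reader applies a multiplicative error to the true value:
#' read = truth * (1 + delta), delta ~ N(bias_pct/100,
#' (sd_pct * quality_multiplier / 100)^2), and produces a read at all with
#' probability \code{yield_prob[parameter]}.
#'
#' @param reader reader id (e.g. "DL", "CL1", "CL2", "CLINICAL").
#' @param bias_pct systematic relative difference from truth, in %.  Either
#'   a single value or a named vector by parameter.
#' @param sd_pct per-read relative SD, in %; single value or named by parameter.
#' @param yield_prob probability a read is produced; single value or named
#'   by parameter.
#' @param quality_sd_multiplier named multipliers for
#'   \code{c(good, moderate, low)} image quality; \code{good} must be 1.
#' @param quality_bias_offset optional additive bias offsets (in %) per
#'   quality category, default all 0.
#' @return an object of class \code{reader_error_model}.
#' @export
reader_error_model <- function(reader,
                               bias_pct = 0,
                               sd_pct = 5,
                               yield_prob = 1,
                               quality_sd_multiplier = c(good = 1, moderate = 1.3, low = 1.6),
                               quality_bias_offset = c(good = 0, moderate = 0, low = 0)) {
  pars <- .valid_parameters()
  expand <- function(x, what, default = NULL) {
    if (length(x) == 1L && is.null(names(x))) return(setNames(rep(as.numeric(x), length(pars)), pars))
    out <- setNames(rep(if (is.null(default)) NA_real_ else default, length(pars)), pars)
    out[names(x)] <- as.numeric(x)
    if (anyNA(out)) stop(what, " must cover every parameter or be a single value")
    out
  }
  bias_pct <- expand(bias_pct, "bias_pct")
  sd_pct <- expand(sd_pct, "sd_pct")
  yield_prob <- expand(yield_prob, "yield_prob")
  if (any(sd_pct < 0)) stop("sd_pct must be >= 0")
  if (any(yield_prob < 0 | yield_prob > 1)) stop("yield_prob must lie in [0, 1]")
  qm <- quality_sd_multiplier[c("good", "moderate", "low")]
  if (anyNA(qm) || any(qm < 1)) stop("quality_sd_multiplier needs good/moderate/low entries >= 1")
  if (qm[["good"]] != 1) stop("quality_sd_multiplier['good'] must be 1")
  qb <- quality_bias_offset[c("good", "moderate", "low")]
  if (anyNA(qb)) stop("quality_bias_offset needs good/moderate/low entries")
  structure(list(reader = as.character(reader), bias_pct = bias_pct,
                 sd_pct = sd_pct, yield_prob = yield_prob,
                 quality_sd_multiplier = qm, quality_bias_offset = qb),
            class = "reader_error_model")
}

# Per-reader defaults calibrated so the pairwise comparisons vs CL1
# reproduce the reported relative bias and scaled percentile precision:
# the two core-lab readers are assumed exchangeable (s_CL1 = s_CL2 =
# pairwise precision of CL2 vs CL1), and the automated reader's SD solves
# sqrt((s_CL1^2 + s_DL^2)/2) = pairwise precision of DL vs CL1.
# Per-reader yields are the observed read counts out of 434 studies.
.default_readers <- function() {
  pars <- .valid_parameters()
  prec_dl  <- setNames(c(6.70, 10.13, 11.49, 10.17, 9.24, 12.35, 17.34), pars)
  prec_cl2 <- setNames(c(5.35,  7.24,  6.15,  9.85, 7.46,  9.14, 10.01), pars)
  bias_dl  <- setNames(c(0.90, -6.35,  1.28,  1.71, -11.0, -14.29, 11.46), pars)
  bias_cl2 <- setNames(c(-6.02, -0.36, 0.00,  4.67, -6.89, -8.18,  2.70), pars)
  sd_cl    <- prec_cl2
  sd_dl    <- sqrt(pmax(2 * prec_dl^2 - prec_cl2^2, 0))
  yield_cl1 <- setNames(c(396, 422, 316, 426, 408, 408, 413) / 434, pars)
  yield_dl  <- setNames(c(403, 357, 319, 376, 351, 351, 329) / 434, pars)
  list(
    CL1 = reader_error_model("CL1", bias_pct = 0, sd_pct = sd_cl, yield_prob = yield_cl1),
    DL  = reader_error_model("DL", bias_pct = bias_dl, sd_pct = sd_dl, yield_prob = yield_dl),
    CL2 = reader_error_model("CL2", bias_pct = bias_cl2, sd_pct = sd_cl, yield_prob = yield_cl1)
  )
}

#' Cohort generator configuration
#'
#' Bundles everything the synthetic generators need: group sizes,
#' per-parameter distributions, reader error models, the image-quality
#' distribution, age/sex marginals, and the referral (hemodynamics) block.
#'
#' @param n_healthy,n_case case-control group sizes.
#' @param distributions data frame as from
#'   \code{\link{default_parameter_distributions}}.
#' @param readers named list of \code{\link{reader_error_model}}s.
#' @param quality_probs probabilities of \code{good, moderate, low} image
#'   quality (must sum to 1); quality is a property of the acquired image,
#'   shared by all readers of that image.
#' @param age_mean,age_sd,prop_female named (healthy/case) age and sex
#'   marginals.
#' @param referral list with \code{n_subjects}, \code{prob_below_20} (mass
#'   of the MPAP mixture below 20 mm Hg), \code{mpap_range} (support,
#'   within 10-35 mm Hg), \code{rap_mmhg}, and sPAP = \code{spap_a} * MPAP +
#'   \code{spap_b} coupling coefficients.
#' @param contamination probability that a read is replaced by a gross
#'   outlier (error SD inflated 5x); default 0 (off).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_healthy = 213, n_case = 221,
                          distributions = default_parameter_distributions(),
                          readers = .default_readers(),
                          quality_probs = c(good = 0.60, moderate = 0.25, low = 0.15),
                          age_mean = c(healthy = 55, case = 48),
                          age_sd = c(healthy = 17, case = 14),
                          prop_female = c(healthy = 0.46, case = 0.78),
                          referral = list(n_subjects = 196,
                                          prob_below_20 = 89 / 196,
                                          mpap_range = c(10, 35),
                                          rap_mmhg = 5,
                                          spap_a = 1.5, spap_b = 0,
                                          readers = c("CLINICAL", "DL")),
                          contamination = 0) {
  stopifnot(n_healthy > 0, n_case > 0)
  if (abs(sum(quality_probs) - 1) > 1e-8) stop("quality_probs must sum to 1")
  if (any(abs(distributions$severity_loading) > 1))
    stop("severity_loading must lie in [-1, 1]")
  if (any(distributions$sd_healthy <= 0) || any(distributions$sd_case <= 0))
    stop("distribution SDs must be > 0")
  if (any(distributions$lower_bound >= distributions$upper_bound))
    stop("lower_bound must be < upper_bound")
  if (!is.null(referral)) {
    if (referral$mpap_range[1] < 10 - 1e-9 || referral$mpap_range[2] > 35 + 1e-9)
      stop("referral MPAP support must lie within (10, 35) mm Hg")
    lo_spap <- referral$spap_a * referral$mpap_range[1] + referral$spap_b
    if (lo_spap <= referral$rap_mmhg)
      stop("sPAP <= RAP at the lower MPAP bound: TRV undefined")
  }
  structure(list(n_healthy = n_healthy, n_case = n_case,
                 distributions = distributions, readers = readers,
                 quality_probs = quality_probs,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female,
                 referral = referral, contamination = contamination),
            class = "cohort_config")
}

#' Read a cohort/analysis configuration from YAML
#'
#' Recognised top-level keys: \code{n_healthy}, \code{n_case},
#' \code{quality_probs}, \code{contamination}, \code{referral} (a mapping
#' with the fields of the \code{referral} argument of
#' \code{\link{cohort_config}}), \code{readers} (a mapping reader ->
#' \code{bias_pct}/\code{sd_pct}/\code{yield_prob}), plus analysis settings
#' \code{bootstrap_B}, \code{seed}, \code{taus} returned as attributes.
#' Unspecified fields keep package defaults.
#'
#' @param path YAML file path.
#' @return a \code{cohort_config} with attributes \code{bootstrap_B},
#'   \code{seed}, \code{taus} when present in the file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_healthy", "n_case", "contamination")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$quality_probs)) args$quality_probs <- unlist(y$quality_probs)
  if (!is.null(y$referral)) {
    ref <- formals(cohort_config)$referral
    ref <- eval(ref)
    ref[names(y$referral)] <- y$referral
    args$referral <- ref
  }
  if (!is.null(y$readers)) {
    readers <- .default_readers()
    for (nm in names(y$readers)) {
      spec <- y$readers[[nm]]
      readers[[nm]] <- reader_error_model(
        nm,
        bias_pct = if (is.null(spec$bias_pct)) 0 else unlist(spec$bias_pct),
        sd_pct = if (is.null(spec$sd_pct)) 5 else unlist(spec$sd_pct),
        yield_prob = if (is.null(spec$yield_prob)) 1 else unlist(spec$yield_prob))
    }
    args$readers <- readers
  }
  cfg <- do.call(cohort_config, args)
  attr(cfg, "bootstrap_B") <- if (is.null(y$bootstrap_B)) 1000L else as.integer(y$bootstrap_B)
  attr(cfg, "seed") <- y$seed
  attr(cfg, "taus") <- if (is.null(y$taus)) c(0.16, 0.5, 0.84) else as.numeric(unlist(y$taus))
  cfg
}
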