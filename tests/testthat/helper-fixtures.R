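# Shared fixtures: tiny measurement tables and lean generator configs.

make_measurement_df <- function(subject_id, parameter, reader, value,
                                quality_score = NA_integer_,
                                group = "healthy", age_years = 50, sex = "F") {
  data.frame(subject_id = subject_id, cohort = "case_control", group = group,
             parameter = parameter, reader = reader, value = value,
             units = unname(echo_parameter_units()[parameter]),
             quality_score = quality_score, age_years = age_years, sex = sex,
             stringsAsFactors = FALSE)
}

# A measurement table with prescribed presence pattern for one parameter:
# n_ref reference reads, n_comp comparator reads, n_common shared subjects.
presence_table <- function(parameter, ref_reader, comp_reader,
                           n_ref, n_comp, n_common) {
  stopifnot(n_common <= min(n_ref, n_comp))
  ids <- sprintf("P%04d", seq_len(n_ref + n_comp - n_common))
  ref_ids <- ids[seq_len(n_ref)]
  comp_ids <- c(ids[seq_len(n_common)],
                ids[n_ref + seq_len(n_comp - n_common)])
  df <- rbind(
    make_measurement_df(ref_ids, parameter, ref_reader, value = 2.5),
    make_measurement_df(comp_ids, parameter, comp_reader, value = 2.5))
  measurement_table(df)
}

# TRV-only two-reader config used by the recovery experiments.
trv_pair_config <- function(n_pairs = 400, sd_pct = 6.7 / sqrt(2),
                            bias_pct = 0.9) {
  cohort_config(
    n_healthy = ceiling(n_pairs / 2), n_case = floor(n_pairs / 2),
    distributions = default_parameter_distributions()[
      default_parameter_distributions()$parameter == "TRV", ],
    readers = list(
      CL1 = reader_error_model("CL1", bias_pct = 0, sd_pct = sd_pct, yield_prob = 1),
      DL = reader_error_model("DL", bias_pct = bias_pct, sd_pct = sd_pct, yield_prob = 1)),
    quality_probs = c(good = 1, moderate = 0, low = 0))
}

# Independent pinball-loss oracle (deliberately naive).
oracle_pinball <- function(x, d, a, b, tau) {
  u <- d - a - b * x
  sum(u * (tau - as.numeric(u < 0)))
}

# Brute-force AUC by exhaustive pair counting.
oracle_auc <- function(marker, labels) {
  pos <- marker[labels == 1]; neg <- marker[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
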