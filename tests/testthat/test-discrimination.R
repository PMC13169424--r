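# Midrank AUC, DeLong comparison, PH labelling, matching, guideline score.

test_that("AUC handles separation, complete ties, orientation, and label flips", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(3)
  m <- rnorm(40); lab <- rbinom(40, 1, 0.5)
  a <- roc_auc(m, lab)$auc
  # invariant under strictly increasing transforms
  expect_equal(roc_auc(exp(m), lab)$auc, a)
  expect_equal(roc_auc(rank(m), lab)$auc, a)
  # label flip maps AUC -> 1 - AUC
  expect_equal(roc_auc(m, 1 - lab)$auc, 1 - a)
  # 'lower' direction equals flipping the marker
  expect_equal(roc_auc(m, lab, direction = "lower")$auc, roc_auc(-m, lab)$auc)
  # orientation registry: TAPSE is a lower-is-disease marker
  expect_equal(roc_auc(m, lab, direction = "auto", parameter = "TAPSE")$auc,
               roc_auc(-m, lab)$auc)
  expect_error(roc_auc(m, rep(1, 40)), "both classes")
})

test_that("midrank AUC equals brute-force pair counting on random tied data", {
  set.seed(60)
  for (rep in 1:40) {
    n <- sample(10:100, 1)
    marker <- sample(round(rnorm(n), sample(0:1, 1)))  # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(marker, labels)$auc, oracle_auc(marker, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC and DeLong agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  n <- 80
  lab <- rbinom(n, 1, 0.5)
  m1 <- rnorm(n, lab); m2 <- rnorm(n, 0.5 * lab)
  expect_equal(roc_auc(m1, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, m1, direction = "<", quiet = TRUE))))
  mine <- delong_compare(m1, m2, lab)
  ref <- pROC::roc.test(pROC::roc(lab, m1, direction = "<", quiet = TRUE),
                        pROC::roc(lab, m2, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(mine$z), unname(ref$statistic), tolerance = 1e-9)
})

test_that("self-comparison gives z = 0, p = 1; degenerate unequal AUCs are flagged", {
  set.seed(14)
  m <- rnorm(30); lab <- rep(c(0, 1), 15)
  res <- delong_compare(m, m, lab)
  expect_equal(res$auc1, res$auc2)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_gte(res$var1, 0)
  expect_gte(res$var2, 0)
})

test_that("DeLong variance approximates the bootstrap variance of the AUC difference", {
  set.seed(26)
  n <- 60
  lab <- rep(c(0, 1), n / 2)
  m1 <- rnorm(n, 1.2 * lab)
  m2 <- 0.8 * m1 + rnorm(n, 0.4 * lab)
  res <- delong_compare(m1, m2, lab)
  var_delong <- res$var1 + res$var2 - 2 * res$covariance
  boot <- replicate(2000, {
    i <- c(sample(which(lab == 0), replace = TRUE),
           sample(which(lab == 1), replace = TRUE))
    roc_auc(m1[i], lab[i])$auc - roc_auc(m2[i], lab[i])$auc
  })
  expect_equal(var_delong, var(boot), tolerance = 0.35)
})

test_that("single-AUC DeLong variance matches the closed-form null Mann-Whitney variance", {
  # continuous null, no ties: var(AUC) ~= (m + n + 1) / (12 m n)
  set.seed(48)
  m <- 40; n <- 40
  vs <- replicate(300, roc_auc(rnorm(m + n), rep(c(0, 1), c(n, m)))$var)
  expect_equal(mean(vs), (m + n + 1) / (12 * m * n), tolerance = 0.1)
})

test_that("PH labels use the strict 20 mm Hg rule and the 35 mm Hg referral band", {
  expect_equal(as.character(classify_ph(c(20, 21, 36))), c("no_PH", "PH", "PH"))
  expect_equal(referral_eligible(c(20, 35, 36)), c(TRUE, TRUE, FALSE))
  expect_error(classify_ph(0), "> 0")
  expect_error(referral_eligible(-5), "> 0")
})

test_that("matching is sex-exact, nearest-age, caliper-bounded, and deterministic", {
  cases <- data.frame(id = "case1", age = 50, sex = "F")
  controls <- data.frame(id = c("c48", "c53"), age = c(48, 53), sex = "F")
  m <- match_case_control(cases, controls, caliper_years = 3)
  expect_equal(m$pairs$control_id, "c48")
  expect_equal(m$pairs$age_gap, 2)

  # identical (age, sex) multisets -> everyone matched at gap 0
  cases2 <- data.frame(id = paste0("k", 1:4), age = c(40, 50, 60, 70),
                       sex = c("F", "F", "M", "M"))
  controls2 <- data.frame(id = paste0("c", 1:4), age = c(70, 60, 50, 40),
                          sex = c("M", "M", "F", "F"))
  m2 <- match_case_control(cases2, controls2)
  expect_equal(nrow(m2$pairs), 4L)
  expect_equal(m2$pairs$age_gap, rep(0, 4))
  expect_equal(length(m2$unmatched_cases), 0L)

  # sex-exact: male case with only female controls stays unmatched
  m3 <- match_case_control(data.frame(id = "m1", age = 55, sex = "M"),
                           data.frame(id = c("f1", "f2"), age = c(54, 56), sex = "F"))
  expect_equal(nrow(m3$pairs), 0L)
  expect_equal(m3$unmatched_cases, "m1")

  # hardest-to-match case goes first: the scarce-sex case keeps its control
  cases4 <- data.frame(id = c("easy", "hard"), age = c(50, 50), sex = c("F", "F"))
  controls4 <- data.frame(id = c("u", "v"), age = c(50, 90), sex = c("F", "F"))
  m4 <- match_case_control(cases4, controls4, caliper_years = 5)
  # both cases tie on difficulty (1 eligible each: only 'u' within caliper);
  # 'easy' (lexicographically first) takes it, 'hard' is left unmatched
  expect_equal(nrow(m4$pairs), 1L)
  expect_equal(m4$pairs$control_id, "u")
})

test_that("guideline supporting-criteria category encodes bands and the upgrade rule", {
  expect_equal(as.character(supporting_criteria_score(2.5, 0)), "low")
  expect_equal(as.character(supporting_criteria_score(3.0, 2)), "high")
  expect_equal(as.character(supporting_criteria_score(4.0, 0)), "high")
  expect_equal(as.character(supporting_criteria_score(2.8, 0)), "low")
  expect_equal(as.character(supporting_criteria_score(3.4, 0)), "intermediate")
  expect_equal(as.character(supporting_criteria_score(2.5, 3)), "intermediate")
  expect_equal(as.character(supporting_criteria_score(NA, 2)), "intermediate")
  expect_equal(as.character(supporting_criteria_score(NA, 0)), "low")
  expect_error(supporting_criteria_score(3.0, -1), "nonnegative")
})

test_that("synthetic case-control TRV discriminates nearly perfectly after matching", {
  cc <- generate_case_control_cohort(cohort_config(n_healthy = 200, n_case = 200),
                                     seed = 42)
  m <- as.data.frame(cc$measurements)
  trv <- m[m$parameter == "TRV" & m$reader == "DL", ]
  subj <- unique(m[, c("subject_id", "group", "age_years", "sex")])
  cases <- subj[subj$group == "PAH", ]
  controls <- subj[subj$group == "healthy", ]
  mc <- match_case_control(
    data.frame(id = cases$subject_id, age = cases$age_years, sex = cases$sex),
    data.frame(id = controls$subject_id, age = controls$age_years, sex = controls$sex),
    caliper_years = 10)
  ids <- c(mc$pairs$case_id, mc$pairs$control_id)
  lab <- as.integer(ids %in% cases$subject_id)
  marker <- trv$value[match(ids, trv$subject_id)]
  keep <- !is.na(marker)
  expect_gt(roc_auc(marker[keep], lab[keep])$auc, 0.95)
})
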