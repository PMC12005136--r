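# Cohort sizes here are chosen to keep binomial/Monte-Carlo tolerances
# meaningful while the whole file runs in seconds.

test_that("noise-free, bias-free, flip-free cohorts are perfectly concordant", {
  spec <- cohort_spec(n_subjects = 400, seed = 9,
                      sbp_white_coat = 0, height_bias_cm = 0,
                      measurement_sd = list(sbp = 0, dbp = 0,
                                            height = 0, weight = 0),
                      history_flip_prob = lapply(
                        cohort_spec()$history_flip_prob, function(x) 0),
                      interim_event_prob = 0)
  coh <- generate_cohort(spec)
  rep <- run_pipeline(coh$encounters)
  expect_equal(rep$kappa_results$primary_weighted$estimate, 1)
  expect_equal(nrow(rep$discordance_labels), 0)
  expect_equal(rep$bland_altman_rows$sbp$bias, 0)
  # engine classification of noiseless physician records equals the latent
  # status (the generator's calibration guarantee)
  phys <- coh$encounters[coh$encounters$evaluator == "PHYSICIAN" &
                           coh$encounters$visit == "PRIMARY", ]
  expect_equal(phys$classification,
               coh$truth$latent_status[match(phys$subject_id,
                                             coh$truth$subject_id)])
})

test_that("generated cohorts reproduce the specified margins", {
  spec <- cohort_spec(n_subjects = 5000, seed = 21)
  coh <- generate_cohort(spec)
  phys <- coh$encounters[coh$encounters$evaluator == "PHYSICIAN" &
                           coh$encounters$visit == "PRIMARY", ]
  n <- nrow(phys)
  # physician possible+confirmed fraction near the latent 14%
  frac <- mean(phys$classification != "NO_HTN")
  expect_lt(abs(frac - 0.14), 2 * sqrt(0.14 * 0.86 / n) + 0.01)
  # diabetes prevalence near its status-weighted marginal
  # (0.86*0.083 + 0.09*0.385 + 0.05*0.295 = 0.121, printed as 12.0%)
  p_dia <- sum(c(0.86, 0.09, 0.05) * c(0.083, 0.385, 0.295))
  expect_lt(abs(mean(phys$diabetes) - p_dia),
            2.5 * sqrt(p_dia * (1 - p_dia) / n))
  # demographics
  expect_lt(abs(mean(phys$sex == "F") - 0.83), 2 * sqrt(0.83 * 0.17 / n))
  expect_lt(abs(mean(phys$age_years) - 45.9), 2.5)
  expect_true(all(phys$age_years >= 18))
})

test_that("same seed gives byte-identical output; different seed differs", {
  spec <- cohort_spec(n_subjects = 150, seed = 33)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_encounters(a$encounters, f1)
  write_encounters(b$encounters, f2)
  expect_identical(readLines(f1), readLines(f2))
  spec2 <- cohort_spec(n_subjects = 150, seed = 34)
  expect_false(identical(generate_cohort(spec2), a))
})

test_that("Bland-Altman on generated measurements recovers the evaluator biases", {
  spec <- cohort_spec(n_subjects = 4000, seed = 55)
  coh <- generate_cohort(spec)
  rep <- run_pipeline(coh$encounters)
  ba <- rep$bland_altman_rows$sbp
  mc_se <- ba$sd_diff / sqrt(ba$n)
  expect_lt(abs(ba$bias - spec$sbp_white_coat), 2 * mc_se)
  # CHW heights run high, so physician-minus-CHW height bias is negative
  bh <- rep$bland_altman_rows$height
  expect_lt(abs(bh$bias - (-spec$height_bias_cm)),
            2 * bh$sd_diff / sqrt(bh$n))
  # higher CHW heights depress CHW BMI: positive physician-minus-CHW bias
  expect_gt(rep$bland_altman_rows$bmi$bias, 0)
})

test_that("the generator's records honour protocol and record invariants", {
  coh <- generate_cohort(cohort_spec(n_subjects = 800, seed = 77))
  enc <- coh$encounters
  trig <- repeat_trigger(enc$sbp1, enc$dbp1)
  expect_true(all(!is.na(enc$sbp2[trig]) & !is.na(enc$sbp3[trig])))
  expect_true(all(is.na(enc$sbp2[!trig])))
  expect_true(all(enc$sbp1 > enc$dbp1))
  expect_true(all(enc$cigarettes_per_day[!enc$smokes] == 0))
  expect_true(all(enc$cigarettes_per_day[enc$smokes] > 0))
  expect_true(all(enc$drinks_30d[!enc$alcohol_30d] == 0))
  # secondary visits exist only for physician-possible subjects
  sec_ids <- unique(enc$subject_id[enc$visit == "SECONDARY"])
  prim_phys <- enc[enc$visit == "PRIMARY" & enc$evaluator == "PHYSICIAN", ]
  poss_ids <- prim_phys$subject_id[prim_phys$classification == "POSSIBLE_HTN"]
  expect_true(all(sec_ids %in% poss_ids))
  # secondary classifications are binary
  expect_false(any(enc$classification[enc$visit == "SECONDARY"] ==
                     "POSSIBLE_HTN"))
})

test_that("default spec passes calibration unchanged; zero-noise spec cannot", {
  spec <- cohort_spec(seed = 88)
  calibrated <- calibrate_cohort_spec(spec, n = 4000)
  expect_identical(calibrated, spec)
  # a noise-free spec yields kappa 1, outside the band, and must move
  quiet <- cohort_spec(seed = 88, sbp_white_coat = 1.51,
                       measurement_sd = list(sbp = 0, dbp = 0,
                                             height = 0, weight = 0),
                       history_flip_prob = lapply(
                         cohort_spec()$history_flip_prob, function(x) 0))
  recal <- tryCatch(
    calibrate_cohort_spec(quiet, n = 4000,
                          sbp_sd_grid = c(0, 6),
                          flip_scale_grid = 1),
    error = function(e) e)
  if (inherits(recal, "cohort_spec")) {
    expect_gt(recal$measurement_sd$sbp, 0)
  } else {
    expect_s3_class(recal, "calibration_failure")
  }
})
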