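primary_tab <- study_crosstabs()$primary

test_that("clinical weight matrix has the published structure", {
  w <- cicchetti_weights(3)
  expect_equal(diag(w), c(NO_HTN = 1, POSSIBLE_HTN = 1, CONFIRMED_HTN = 1))
  expect_equal(unname(w[1, 2]), 1 / 3)
  expect_equal(unname(w[1, 3]), 0)
  expect_equal(unname(w[2, 3]), 2 / 3)
  expect_equal(w, t(w))
  # linear-weight fallback at r = 2 is the identity
  expect_equal(cicchetti_weights(2), diag(2))
  expect_error(cicchetti_weights(1), "two categories")
})

test_that("weighted kappa reproduces the study's primary-visit results", {
  wk <- weighted_kappa(primary_tab, cicchetti_weights(3))
  expect_equal(round(wk$estimate, 2), 0.80)
  expect_equal(round(wk$ci_low, 2), 0.72)
  expect_equal(round(wk$ci_high, 2), 0.88)
  expect_true(wk$mac_cleared)
  uk <- weighted_kappa(primary_tab)
  expect_equal(round(uk$estimate, 2), 0.75)
  expect_equal(round(uk$ci_low, 2), 0.67)
  expect_equal(round(uk$ci_high, 2), 0.84)
  expect_true(uk$mac_cleared)
})

test_that("kappa with identity weights equals unweighted Cohen's kappa", {
  set.seed(101)
  for (r in c(2, 3, 4)) {
    for (rep in 1:10) {
      tab <- random_table(r)
      got <- weighted_kappa(tab, identity_weights(r))$estimate
      expect_equal(got, oracle_unweighted_kappa(tab), tolerance = 1e-12)
      if (requireNamespace("e1071", quietly = TRUE)) {
        expect_equal(got, e1071::classAgreement(tab)$kappa,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("weighted kappa matches a scalar-loop oracle on random tables", {
  set.seed(202)
  w3 <- cicchetti_weights(3)
  for (rep in 1:15) {
    tab <- random_table(3)
    expect_equal(weighted_kappa(tab, w3)$estimate,
                 oracle_weighted_kappa(tab, w3), tolerance = 1e-12)
  }
})

test_that("kappa bounds, perfect agreement, and scale invariance hold", {
  set.seed(303)
  w3 <- cicchetti_weights(3)
  for (rep in 1:10) {
    tab <- random_table(3)
    k <- weighted_kappa(tab, w3)
    expect_gte(k$estimate, -1)
    expect_lte(k$estimate, 1)
    expect_true(k$ci_low <= k$estimate && k$estimate <= k$ci_high)
    expect_equal(k$mac_cleared, k$one_sided_low > k$mac)
    # multiplying all cells by a constant keeps the estimate, shrinks se
    k5 <- weighted_kappa(tab * 5L, w3)
    expect_equal(k5$estimate, k$estimate, tolerance = 1e-12)
    expect_equal(k5$se, k$se / sqrt(5), tolerance = 1e-12)
    # symmetric weights make kappa transpose-invariant
    expect_equal(weighted_kappa(t(tab), w3)$estimate, k$estimate,
                 tolerance = 1e-12)
  }
  diag_tab <- diag(c(10L, 5L, 3L))
  expect_equal(weighted_kappa(diag_tab, w3)$estimate, 1)
  # degenerate marginals: all mass in one category
  degen <- matrix(c(9L, 0L, 0L, 0L), 2)
  expect_error(weighted_kappa(degen, identity_weights(2)), "undefined")
})

test_that("proportional agreement reproduces the study's accuracy values", {
  st <- study_crosstabs()
  pa <- proportional_agreement(st$primary)
  expect_equal(round(100 * pa$estimate, 1), 93.0)
  expect_equal(round(100 * pa$ci_low, 1), 90.4)
  expect_equal(round(100 * pa$ci_high, 1), 95.7)
  expect_true(pa$mac_cleared)
  ov <- proportional_agreement(st$overall)
  expect_equal(round(100 * ov$estimate, 1), 92.8)
  expect_equal(round(100 * ov$ci_low, 1), 90.1)
  expect_equal(round(100 * ov$ci_high, 1), 95.4)
  sec <- proportional_agreement(st$secondary)
  expect_equal(round(100 * sec$estimate, 1), 63.6)
  expect_false(sec$mac_cleared)
  # 25 discordant primary pairs (off-diagonal sum)
  expect_equal(sum(st$primary) - sum(diag(st$primary)), 25)
})

test_that("binary metrics recover the published smoking row", {
  tab <- matrix(c(12L, 1L, 0L, 346L), nrow = 2, byrow = TRUE)
  b <- binary_metrics(tab)
  expect_equal(round(b$kappa$estimate, 2), 0.96)
  expect_equal(round(b$mcc, 2), 0.96)
  expect_equal(b$sensitivity, 1.00)
  expect_equal(round(b$ppv, 2), 0.92)
  expect_equal(round(100 * b$overall_agreement, 2), 99.72)
  expect_equal(b$prevalence_count, 12)
})

test_that("binary metrics handle perfect and hand-computed tables", {
  perfect <- binary_metrics(matrix(c(5L, 0L, 0L, 5L), 2, byrow = TRUE))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa$estimate, 1)
  expect_equal(perfect$sensitivity, 1)
  b <- binary_metrics(matrix(c(2L, 1L, 1L, 6L), 2, byrow = TRUE))
  expect_equal(b$sensitivity, 2 / 3)
  expect_equal(b$specificity, 6 / 7)
  expect_equal(b$mcc, 11 / 21)
  expect_equal(b$kappa$estimate, 11 / 21, tolerance = 1e-12)
  expect_error(binary_metrics(diag(3)), "2x2")
})

test_that("zero denominators give undefined (NA) metrics, not zero", {
  # no reference positives: sensitivity and PPV undefined
  tab <- matrix(c(0L, 2L, 0L, 98L), nrow = 2, byrow = TRUE)
  b <- binary_metrics(tab)
  expect_true(is.na(b$sensitivity))
  expect_equal(b$ppv, 0)  # ppv is defined here: 0 / (0 + 2)
  tab2 <- matrix(c(0L, 0L, 0L, 10L), nrow = 2, byrow = TRUE)
  b2 <- binary_metrics(tab2)
  expect_true(is.na(b2$sensitivity))
  expect_true(is.na(b2$ppv))
  expect_equal(b2$specificity, 1)
})

test_that("kappa equals MCC on every 2x2 table with symmetric marginals", {
  # brute force over all tables with N <= 12
  for (n in 2:12) {
    combos <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
    combos <- combos[combos$tp + combos$fp + combos$fn <= n, ]
    for (i in seq_len(nrow(combos))) {
      tp <- combos$tp[i]; fp <- combos$fp[i]; fn <- combos$fn[i]
      tn <- n - tp - fp - fn
      if (fp != fn) next  # symmetric marginals require FP = FN
      tab <- matrix(c(tp, fp, fn, tn), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      b <- binary_metrics(tab)
      if (is.na(b$mcc)) next
      expect_equal(b$kappa$estimate, b$mcc, tolerance = 1e-10,
                   info = paste(tp, fp, fn, tn))
    }
  }
})

test_that("transposing a 2x2 swaps Se with PPV and Sp with NPV", {
  set.seed(404)
  for (rep in 1:10) {
    tab <- random_table(2, n = 60)
    a <- binary_metrics(tab)
    b <- binary_metrics(t(tab))
    expect_equal(a$sensitivity, b$ppv)
    expect_equal(a$specificity, b$npv)
    expect_equal(a$kappa$estimate, b$kappa$estimate, tolerance = 1e-12)
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
})

test_that("2x2 reconstruction from published marginals round-trips", {
  sm <- study_history_rows()
  smoke <- sm[sm$item == "smokes", ]
  tab <- reconstruct_2x2(smoke$n, smoke$positives, smoke$sensitivity,
                         smoke$overall_agreement)
  expect_equal(unname(tab), matrix(c(12, 1, 0, 346), 2, byrow = TRUE))
  dia <- sm[sm$item == "diabetes", ]
  tab2 <- reconstruct_2x2(dia$n, dia$positives, dia$sensitivity,
                          dia$overall_agreement)
  expect_equal(unname(tab2), matrix(c(41, 3, 2, 313), 2, byrow = TRUE))
  # all-negative cohort: undefined sensitivity treated as 0
  empty <- reconstruct_2x2(10, 0, NA, 1.0)
  expect_equal(unname(empty), matrix(c(0, 0, 0, 10), 2, byrow = TRUE))
  expect_error(reconstruct_2x2(20, 10, 0.1, 0.99), "infeasible")
  # every published history row must be feasible
  for (i in seq_len(nrow(sm))) {
    expect_no_error(reconstruct_2x2(sm$n[i], sm$positives[i],
                                    sm$sensitivity[i],
                                    sm$overall_agreement[i]))
  }
})

test_that("Bland-Altman matches hand computation and is antisymmetric", {
  ref <- c(11, 22, 33, 44)
  cmp <- c(10, 20, 30, 40)
  ba <- bland_altman(ref, cmp)  # differences 1, 2, 3, 4
  expect_equal(ba$bias, 2.5)
  expect_equal(ba$sd_diff, sd(c(1, 2, 3, 4)))
  expect_equal(ba$loa_low, 2.5 - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, 2.5 + 1.96 * ba$sd_diff)
  expect_equal(ba$bias_ci_low, 2.5 - qt(0.975, 3) * ba$sd_diff / 2)
  # swapping roles negates bias and mirrors the limits
  rev <- bland_altman(cmp, ref)
  expect_equal(rev$bias, -ba$bias)
  expect_equal(rev$loa_low, -ba$loa_high)
  expect_equal(rev$loa_high, -ba$loa_low)
  # self-paired data has exactly zero bias and no significant bias
  same <- bland_altman(ref, ref)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_false(same$significant_bias)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("discordance attribution follows the counterfactual rule", {
  # identical histories, only BP differs across the elevation threshold
  chw <- make_record(138, 86, 139, 87, 137, 85)
  phys <- make_record(142, 88, 143, 89, 141, 87)
  lab <- attribute_discordance(chw, phys)
  expect_equal(lab$cause, "BP_ONLY")
  expect_equal(lab$direction, "UNDERDIAGNOSIS")

  # same elevation on both sides, history flag differs
  chw2 <- make_record(150, 95, 151, 96, 149, 94)
  phys2 <- make_record(150, 95, 151, 96, 149, 94, prior_htn_dx = TRUE)
  lab2 <- attribute_discordance(chw2, phys2)
  expect_equal(lab2$cause, "HISTORY_ONLY")
  expect_equal(lab2$direction, "UNDERDIAGNOSIS")

  # both BP elevation status and history differ
  chw3 <- make_record(120, 70)
  phys3 <- make_record(150, 95, 151, 96, 149, 94, prior_htn_dx = TRUE)
  lab3 <- attribute_discordance(chw3, phys3)
  expect_equal(lab3$cause, "BP_AND_HISTORY")
  expect_equal(lab3$direction, "UNDERDIAGNOSIS")

  # overdiagnosis direction
  lab4 <- attribute_discordance(phys2, chw2)
  expect_equal(lab4$direction, "OVERDIAGNOSIS")

  # concordant pair has no label
  expect_error(attribute_discordance(chw, chw), "concordant")
})

test_that("weight matrices load from JSON and YAML and are validated", {
  w <- cicchetti_weights(3)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(apply(unname(w), 1, identity, simplify = FALSE), js,
                       digits = NA)
  expect_equal(read_weight_matrix(js), unname(w), tolerance = 1e-12)
  ym <- tempfile(fileext = ".yaml")
  yaml::write_yaml(apply(unname(w), 1, identity, simplify = FALSE), ym)
  expect_equal(read_weight_matrix(ym), unname(w), tolerance = 1e-6)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(c(1, 0.5), c(0.2, 1)), bad, digits = NA)
  expect_error(read_weight_matrix(bad), "symmetric")
})
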