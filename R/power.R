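#' Generative specification for the agreement power analysis
#'
#' Defines the multinomial model under which simulated CHW/physician
#' cross-tabulations are drawn. The physician category is drawn from
#' `physician_probs` (default 86% no hypertension, 9% possible, 5%
#' confirmed, the anticipated split at initial physician assessment). The
#' CHW agrees with the physician with probability `chw_agreement`; the
#' remaining disagreement mass goes to the adjacent category with
#' conditional share `adjacent_share` (default 2/3, e.g. at 80% agreement a
#' physician "No" becomes CHW "Possible" 13.3% and CHW "Confirmed" 6.7% of
#' the time). For the middle category both neighbours are one step away and
#' the disagreement splits equally between them.
#'
#' @param physician_probs Probability 3-vector over physician categories.
#' @param chw_agreement Per-category probability the CHW agrees.
#' @param adjacent_share Fraction of disagreement mass on the adjacent
#'   category for the outer categories.
#' @param n Subjects per simulated dataset.
#' @param reps Number of simulated datasets.
#' @param alpha One-sided test level.
#' @param mac Minimally acceptable kappa.
#' @return List of class `generative_spec`.
#' @export
generative_spec <- function(physician_probs = c(0.86, 0.09, 0.05),
                            chw_agreement = 0.80, adjacent_share = 2 / 3,
                            n = 350, reps = 10000, alpha = 0.05,
                            mac = 0.61) {
  stopifnot(length(physician_probs) == 3, all(physician_probs >= 0),
            abs(sum(physician_probs) - 1) < 1e-8,
            chw_agreement >= 0, chw_agreement <= 1,
            adjacent_share >= 0, adjacent_share <= 1,
            n >= 1, reps >= 1, alpha > 0, alpha < 1)
  structure(list(physician_probs = physician_probs,
                 chw_agreement = chw_agreement,
                 adjacent_share = adjacent_share,
                 n = n, reps = reps, alpha = alpha, mac = mac),
            class = "generative_spec")
}

#' CHW category probabilities conditional on the physician category
#'
#' @param spec A [generative_spec()].
#' @return 3x3 matrix, rows = physician category, columns = CHW category;
#'   rows sum to 1.
#' @export
chw_conditional_probs <- function(spec) {
  a <- spec$chw_agreement
  s <- spec$adjacent_share
  dis <- 1 - a
  m <- rbind(c(a, dis * s, dis * (1 - s)),          # phys No
             c(dis / 2, a, dis / 2),                # phys Possible (middle)
             c(dis * (1 - s), dis * s, a))          # phys Confirmed
  dimnames(m) <- list(physician = htn_levels(), chw = htn_levels())
  m
}

#' Population cell probabilities of the generative model
#'
#' @param spec A [generative_spec()].
#' @return 3x3 matrix of joint probabilities, rows = CHW category,
#'   columns = physician category (matching the cross-tab orientation).
#' @export
population_cell_probs <- function(spec) {
  joint <- diag(spec$physician_probs) %*% chw_conditional_probs(spec)
  out <- t(joint)  # rows CHW, cols physician
  dimnames(out) <- list(chw = htn_levels(), physician = htn_levels())
  out
}

#' Exact population weighted kappa of the generative model
#'
#' Weighted kappa evaluated on the exact population cell-probability
#' matrix, with no sampling — the "true" alternative kappa from which power
#' is assessed.
#'
#' @param spec A [generative_spec()].
#' @param weights Agreement weight matrix (default the clinical scheme).
#' @return Numeric scalar.
#' @export
population_weighted_kappa <- function(spec, weights = cicchetti_weights(3)) {
  p <- population_cell_probs(spec)
  po <- sum(weights * p)
  pe <- sum(weights * outer(rowSums(p), colSums(p)))
  (po - pe) / (1 - pe)
}

#' Simulate one CHW/physician cross-tabulation
#'
#' Draws `spec$n` physician categories from `physician_probs` and, for
#' each, a CHW category from the conditional model; returns the 3x3
#' cross-tab (CHW rows, physician columns). Uses the current RNG stream;
#' call `set.seed()` for reproducibility.
#'
#' @param spec A [generative_spec()].
#' @return 3x3 integer matrix.
#' @export
simulate_table <- function(spec) {
  cond <- chw_conditional_probs(spec)
  phys <- sample.int(3L, spec$n, replace = TRUE, prob = spec$physician_probs)
  u <- stats::runif(spec$n)
  cum <- t(apply(cond, 1, cumsum))
  chw <- 1L + (u > cum[phys, 1]) + (u > cum[phys, 2])
  tab <- matrix(tabulate((phys - 1L) * 3L + chw, nbins = 9L), nrow = 3)
  dimnames(tab) <- list(chw = htn_levels(), physician = htn_levels())
  tab
}

#' Monte-Carlo power of the weighted-kappa non-inferiority test
#'
#' For each replicate, simulates a cross-tabulation from the generative
#' model, computes weighted kappa and its asymptotic standard error, and
#' rejects non-inferiority when
#' `(kappa_hat - mac) / SE < -z[1 - alpha]`. Power is the rejection
#' fraction. A replicate whose table is degenerate (expected weighted
#' agreement 1, so kappa is undefined) is retained and counted as a
#' non-rejection rather than dropped; at realistic sample sizes this has
#' vanishing probability.
#'
#' @param spec A [generative_spec()] (`reps >= 100`).
#' @param weights Agreement weight matrix.
#' @param seed Integer seed; the result is fully reproducible from it.
#' @return Object of class `power_result`: `power`, `mc_se`
#'   (`sqrt(power (1 - power) / reps)`), `rejections`, `reps`, `n`,
#'   `population_kappa`.
#' @export
kappa_power <- function(spec, weights = cicchetti_weights(3), seed = 1L) {
  stopifnot(spec$reps >= 100)
  set.seed(seed)
  zcrit <- stats::qnorm(1 - spec$alpha)
  rejections <- 0L
  for (r in seq_len(spec$reps)) {
    tab <- simulate_table(spec)
    k <- tryCatch(weighted_kappa(tab, weights, mac = spec$mac),
                  error = function(e) NULL)
    if (!is.null(k) && k$se > 0 &&
        (k$estimate - spec$mac) / k$se < -zcrit) {
      rejections <- rejections + 1L
    }
  }
  power <- rejections / spec$reps
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / spec$reps),
                 rejections = rejections, reps = spec$reps, n = spec$n,
                 population_kappa = population_weighted_kappa(spec, weights)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (MC SE %.4f) from %d/%d rejections at n = %d; population kappa %.3f\n",
    x$power, x$mc_se, x$rejections, x$reps, x$n, x$population_kappa))
  invisible(x)
}

#' Power curve of the kappa non-inferiority test over sample sizes
#'
#' @param spec A [generative_spec()]; its `n` is overridden by `n_grid`.
#' @param n_grid Integer vector of sample sizes.
#' @param weights Agreement weight matrix.
#' @param seed Base seed; each grid point uses `seed + index`.
#' @return Data frame with columns `n`, `power`, `mc_se`.
#' @export
kappa_power_curve <- function(spec, n_grid, weights = cicchetti_weights(3),
                              seed = 1L) {
  rows <- lapply(seq_along(n_grid), function(i) {
    s <- spec
    s$n <- n_grid[i]
    pr <- kappa_power(s, weights, seed = seed + i)
    data.frame(n = n_grid[i], power = pr$power, mc_se = pr$mc_se)
  })
  do.call(rbind, rows)
}

#' Exact binomial power for inferior diagnostic accuracy
#'
#' One-sided exact test that accuracy is below a null value: the critical
#' value is the largest `c` with `P(X <= c | n, null_acc) <= alpha`, and
#' power is `P(X <= c | n, true_acc)`. Infeasible designs (no valid
#' critical value) have power 0.
#'
#' @param n Number of subjects.
#' @param true_acc True (inferior) accuracy, strictly below `null_acc`.
#' @param null_acc Null accuracy.
#' @param alpha One-sided level.
#' @return Numeric power in \[0, 1\].
#' @examples
#' accuracy_power(350, 0.80, 0.90)
#' @export
accuracy_power <- function(n, true_acc, null_acc, alpha = 0.05) {
  stopifnot(n >= 1, true_acc > 0, true_acc < 1, null_acc > 0, null_acc < 1,
            true_acc < null_acc)
  crit <- stats::qbinom(alpha, n, null_acc)
  while (crit >= 0 && stats::pbinom(crit, n, null_acc) > alpha) {
    crit <- crit - 1L
  }
  if (crit < 0) return(0)
  stats::pbinom(crit, n, true_acc)
}
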