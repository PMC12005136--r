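# Independent oracles used to cross-check the package's own formulas.
# These deliberately take the long way round (per-pair expansion, explicit
# loops) so they share no code path with the implementation.

# Unweighted Cohen's kappa by expanding the table into rater vectors.
oracle_unweighted_kappa <- function(tab) {
  r <- nrow(tab)
  a <- rep(seq_len(r), rowSums(tab))                 # row index per pair
  b <- unlist(lapply(seq_len(r), function(i) rep(seq_len(r), tab[i, ])))
  po <- mean(a == b)
  pe <- sum(vapply(seq_len(r), function(k) mean(a == k) * mean(b == k), 0))
  (po - pe) / (1 - pe)
}

# Weighted kappa straight from the definition, scalar loops only.
oracle_weighted_kappa <- function(tab, w) {
  n <- sum(tab)
  r <- nrow(tab)
  po <- pe <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      po <- po + w[i, j] * tab[i, j] / n
      pe <- pe + w[i, j] * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

# MCC as the Pearson correlation (phi) of the two binary indicator vectors.
oracle_mcc <- function(tab) {
  a <- c(rep(1, tab[1, 1] + tab[1, 2]), rep(0, tab[2, 1] + tab[2, 2]))
  b <- c(rep(1, tab[1, 1]), rep(0, tab[1, 2]),
         rep(1, tab[2, 1]), rep(0, tab[2, 2]))
  suppressWarnings(stats::cor(a, b))
}

# Random square contingency table with all marginals positive.
random_table <- function(r, n = 200) {
  repeat {
    cells <- stats::rmultinom(1, n, prob = stats::runif(r * r, 0.2, 1))
    tab <- matrix(cells, nrow = r)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# Minimal encounter record for the classification engine.
make_record <- function(sbp1, dbp1, sbp2 = NA, dbp2 = NA, sbp3 = NA,
                        dbp3 = NA, prior_htn_dx = FALSE,
                        taking_antihypertensive = FALSE, visit = "PRIMARY",
                        interim_htn_dx = FALSE,
                        interim_antihypertensive = FALSE) {
  list(sbp1 = sbp1, dbp1 = dbp1, sbp2 = sbp2, dbp2 = dbp2,
       sbp3 = sbp3, dbp3 = dbp3, prior_htn_dx = prior_htn_dx,
       taking_antihypertensive = taking_antihypertensive, visit = visit,
       interim_htn_dx = interim_htn_dx,
       interim_antihypertensive = interim_antihypertensive)
}
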