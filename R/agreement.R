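#' Clinical (Cicchetti-style) agreement weights for weighted kappa
#'
#' Returns the r x r agreement weight matrix used for weighted kappa.
#' For the three hypertension categories (No / Possible / Confirmed, in that
#' order on both axes) the scheme penalises clinically concerning
#' disagreement most heavily: a CHW "No" against a physician "Confirmed"
#' (or vice versa) receives weight 0, a missed "Possible" weight 1/3, while
#' the less dangerous Possible/Confirmed confusion keeps weight 2/3:
#'
#' \preformatted{
#'            phys No  Possible  Confirmed
#' CHW No        1       1/3        0
#' Possible     1/3       1        2/3
#' Confirmed     0       2/3        1
#' }
#'
#' For other category counts the standard linear weights
#' `1 - |i - j| / (r - 1)` are returned.
#'
#' @param r Number of ordered categories (>= 2); default 3.
#' @return Symmetric r x r numeric matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
cicchetti_weights <- function(r = 3) {
  if (r < 2) stop("need at least two categories", call. = FALSE)
  if (r == 3) {
    w <- matrix(c(1, 1 / 3, 0,
                  1 / 3, 1, 2 / 3,
                  0, 2 / 3, 1), nrow = 3, byrow = TRUE)
    dimnames(w) <- list(htn_levels(), htn_levels())
    return(w)
  }
  idx <- seq_len(r)
  1 - abs(outer(idx, idx, "-")) / (r - 1)
}

#' Identity agreement weights
#'
#' Weight matrix giving credit only to exact agreement; [weighted_kappa()]
#' with these weights is the ordinary (unweighted) Cohen's kappa.
#'
#' @param r Number of categories.
#' @return r x r identity matrix.
#' @export
identity_weights <- function(r) diag(r)

#' Load an agreement weight matrix from JSON or YAML
#'
#' Accepts a file holding a square numeric matrix (nested arrays), e.g.
#' `[[1, 0.333, 0], [0.333, 1, 0.667], [0, 0.667, 1]]`. The matrix must be
#' symmetric with unit diagonal and entries in \[0, 1\].
#'
#' @param path File path; format inferred from the `.json` / `.yaml` /
#'   `.yml` extension.
#' @return Numeric weight matrix.
#' @export
read_weight_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  w <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    do.call(rbind, yaml::read_yaml(path))
  } else {
    stop("unsupported weight-matrix format: .", ext, call. = FALSE)
  }
  w <- matrix(as.numeric(w), nrow = nrow(w))
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop("weight matrix must be square", call. = FALSE)
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-12) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(w) - 1) > 1e-12)) {
    stop("weight matrix diagonal must be 1", call. = FALSE)
  }
  invisible(w)
}

as_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) {
    stop("contingency table must be square (shared ordered categories)",
         call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) <= 0) stop("contingency table is empty", call. = FALSE)
  tab
}

#' Cross-tabulate two raters' categorical assignments
#'
#' @param rater_a,rater_b Vectors of category labels (rater A indexes rows;
#'   in this package's conventions A is the CHW, B the physician reference).
#' @param levels Shared ordered category labels; defaults to the sorted
#'   union of observed values.
#' @return Square integer matrix with named dimnames.
#' @export
crosstab <- function(rater_a, rater_b, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(rater_a, rater_b)))
  as.matrix(table(factor(rater_a, levels = levels),
                  factor(rater_b, levels = levels)))
}

#' Weighted Cohen's kappa with non-inferiority test
#'
#' Chance-corrected agreement with partial credit for specific
#' disagreements. With cell proportions `p_ij`, marginals `p_i.` and `p_.j`,
#' and agreement weights `w_ij` in \[0, 1\]:
#' \deqn{\kappa_w = \frac{P_{o,w} - P_{e,w}}{1 - P_{e,w}}, \quad
#'       P_{o,w} = \sum w_{ij} p_{ij}, \quad
#'       P_{e,w} = \sum w_{ij} p_{i\cdot} p_{\cdot j}.}
#' The asymptotic standard error is the Fleiss–Cohen–Everitt (1969)
#' large-sample formula for weighted kappa (which reduces to the usual
#' Cohen-kappa standard error under identity weights):
#' \deqn{\widehat{\mathrm{var}}(\hat\kappa_w) =
#'   \frac{\sum_{ij} p_{ij}\,[w_{ij}(1-P_{e,w}) -
#'   (\bar w_{i\cdot}+\bar w_{\cdot j})(1-P_{o,w})]^2 -
#'   (P_{o,w}P_{e,w} - 2P_{e,w} + P_{o,w})^2}{N (1-P_{e,w})^4}}
#' with \eqn{\bar w_{i\cdot} = \sum_j p_{\cdot j} w_{ij}} and
#' \eqn{\bar w_{\cdot j} = \sum_i p_{i\cdot} w_{ij}}.
#'
#' Non-inferiority against a minimally acceptable criterion (MAC) is
#' assessed with a one-sided lower confidence bound
#' \eqn{\hat\kappa_w - z_{1-\alpha}\,\mathrm{SE}}: the MAC is cleared when
#' that bound exceeds it.
#'
#' @param tab Square contingency table (rows rater A, columns rater B).
#' @param weights Agreement weight matrix; defaults to identity (unweighted
#'   kappa). Use [cicchetti_weights()] for the clinical scheme.
#' @param mac Minimally acceptable criterion for kappa (default 0.61,
#'   the lower edge of "substantial agreement").
#' @param conf_level Two-sided confidence level (default 0.95); the
#'   one-sided bound uses the same nominal level.
#' @return Object of class `kappa_result`: list with `estimate`, `se`,
#'   `ci_low`, `ci_high` (two-sided Wald), `one_sided_low`, `mac`,
#'   `mac_cleared`, plus the observed/expected weighted agreement `po`,
#'   `pe`, the table total `n`, and the `weights` used.
#' @examples
#' tab <- matrix(c(292, 1, 7, 6, 9, 4, 4, 3, 33), nrow = 3, byrow = TRUE)
#' weighted_kappa(tab, cicchetti_weights(3))
#' @export
weighted_kappa <- function(tab, weights = identity_weights(nrow(as.matrix(tab))),
                           mac = 0.61, conf_level = 0.95) {
  tab <- as_contingency(tab)
  validate_weights(weights)
  if (!all(dim(weights) == dim(tab))) {
    stop("weight matrix and table dimensions differ", call. = FALSE)
  }
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(weights * p)
  pe <- sum(weights * outer(pi_, pj_))
  if (abs(1 - pe) < 1e-12) {
    stop("kappa undefined: expected weighted agreement is 1 (degenerate marginals)",
         call. = FALSE)
  }
  est <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance; zero marginals simply drop
  # out of the sums, so empty categories need no special casing.
  wbar_i <- as.vector(weights %*% pj_)
  wbar_j <- as.vector(t(weights) %*% pi_)
  dev <- weights * (1 - pe) - outer(wbar_i, wbar_j, "+") * (1 - po)
  v <- (sum(p * dev^2) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z2 <- stats::qnorm(1 - (1 - conf_level) / 2)
  z1 <- stats::qnorm(conf_level)
  one_sided_low <- est - z1 * se
  structure(list(estimate = est, se = se,
                 ci_low = est - z2 * se, ci_high = est + z2 * se,
                 one_sided_low = one_sided_low,
                 mac = mac, mac_cleared = one_sided_low > mac,
                 po = po, pe = pe, n = n,
                 conf_level = conf_level, weights = weights),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa = %.2f (SE %.3f), %d%% CI (%.2f, %.2f)\n",
              x$estimate, x$se, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  cat(sprintf("One-sided lower bound %.3f vs MAC %.2f: %s\n",
              x$one_sided_low, x$mac,
              if (x$mac_cleared) "MAC cleared (non-inferior)" else "MAC not cleared"))
  invisible(x)
}

#' Proportional agreement with Wald confidence interval
#'
#' Overall proportion of exact agreement (the trace of the cross-tabulation
#' over its total), with the normal-approximation (Wald) interval
#' `p +/- z * sqrt(p(1-p)/N)` and a one-sided lower bound tested against a
#' minimally acceptable criterion (default 90%).
#'
#' @param tab Square contingency table.
#' @param mac Minimally acceptable proportion (default 0.90).
#' @param conf_level Two-sided confidence level.
#' @return Object of class `agreement_result`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `one_sided_low`, `mac`, `mac_cleared`, `agree` (count),
#'   `n`.
#' @export
proportional_agreement <- function(tab, mac = 0.90, conf_level = 0.95) {
  tab <- as_contingency(tab)
  n <- sum(tab)
  agree <- sum(diag(tab))
  p <- agree / n
  se <- sqrt(p * (1 - p) / n)
  z2 <- stats::qnorm(1 - (1 - conf_level) / 2)
  z1 <- stats::qnorm(conf_level)
  one_sided_low <- p - z1 * se
  structure(list(estimate = p, se = se,
                 ci_low = p - z2 * se, ci_high = p + z2 * se,
                 one_sided_low = one_sided_low,
                 mac = mac, mac_cleared = one_sided_low > mac,
                 agree = agree, n = n, conf_level = conf_level),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement %d/%d = %.1f%%, %d%% CI (%.1f%%, %.1f%%)\n",
              x$agree, x$n, 100 * x$estimate, round(100 * x$conf_level),
              100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("One-sided lower bound %.1f%% vs MAC %.0f%%: %s\n",
              100 * x$one_sided_low, 100 * x$mac,
              if (x$mac_cleared) "MAC cleared" else "MAC not cleared"))
  invisible(x)
}

#' Binary agreement metrics for a 2x2 table
#'
#' For a 2x2 cross-tabulation with CHW calls on rows (positive first) and
#' physician reference calls on columns (positive first), so that
#' `tab[1,1] = TP`, `tab[1,2] = FP`, `tab[2,1] = FN`, `tab[2,2] = TN`:
#' overall agreement, Cohen's kappa, the Matthews correlation coefficient
#' \deqn{\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and predictive
#' values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`. A metric whose
#' denominator is zero is undefined and reported as `NA` (not coerced to
#' zero), as happens for sensitivity when no reference-positive subjects
#' exist.
#'
#' @param tab 2x2 matrix of counts.
#' @return Object of class `binary_agreement`: list with
#'   `overall_agreement`, `kappa` (a `kappa_result`), `mcc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `prevalence_count` (reference positives),
#'   `n`.
#' @export
binary_metrics <- function(tab) {
  tab <- as_contingency(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  tp <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tn <- tab[2, 2]
  n <- sum(tab)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(denom)
  # degenerate marginals (all mass in one category) leave kappa undefined;
  # report an NA marker rather than raising, matching the other metrics
  kap <- tryCatch(weighted_kappa(tab, identity_weights(2)),
                  error = function(e) {
                    structure(list(estimate = NA_real_, se = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   one_sided_low = NA_real_, mac = 0.61,
                                   mac_cleared = NA, po = NA_real_,
                                   pe = 1, n = n, conf_level = 0.95,
                                   weights = identity_weights(2)),
                              class = "kappa_result")
                  })
  structure(list(
    overall_agreement = (tp + tn) / n,
    kappa = kap,
    mcc = mcc,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    prevalence_count = tp + fn,
    n = n
  ), class = "binary_agreement")
}

#' Reconstruct a 2x2 table from published marginals
#'
#' Rebuilds the full 2x2 confusion matrix from the summary statistics a
#' report typically prints per item: cohort size, number of
#' reference-positive subjects, sensitivity, and overall agreement.
#' `TP = round(Se * positives)`, the discordant count is
#' `round(N * (1 - agreement))`, `FN = positives - TP`,
#' `FP = discordant - FN`, `TN` the remainder. An undefined sensitivity
#' (zero positives, passed as `NA`) is treated as 0.
#'
#' @param n Total subjects.
#' @param positives Reference-positive count.
#' @param sensitivity Reported sensitivity (may be `NA` when `positives`
#'   is 0).
#' @param overall_agreement Reported overall agreement proportion.
#' @return 2x2 integer matrix (rows CHW +/-, cols reference +/-).
#' @export
reconstruct_2x2 <- function(n, positives, sensitivity, overall_agreement) {
  if (is.na(sensitivity)) sensitivity <- 0
  tp <- round(sensitivity * positives)
  discordant <- round(n * (1 - overall_agreement))
  fn <- positives - tp
  fp <- discordant - fn
  tn <- n - tp - fn - fp
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0)) {
    stop("infeasible marginals: implied cell counts ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  matrix(cells, nrow = 2, byrow = TRUE,
         dimnames = list(CHW = c("pos", "neg"),
                         reference = c("pos", "neg")))
}

#' Bland-Altman measurement-agreement analysis
#'
#' Summarises paired measurements by the mean reference-minus-comparison
#' difference (bias), its t-based confidence interval, and the limits of
#' agreement `bias +/- 1.96 * SD` of the differences. Bias is declared
#' statistically significant when the confidence interval excludes zero.
#' In this package's convention the reference is the physician and the
#' comparison the CHW, so a positive SBP bias means physicians record
#' higher pressures (the "white coat" direction).
#'
#' @param reference,comparison Numeric vectors of paired measurements
#'   (same length, no missing values, at least 3 pairs).
#' @param conf_level Confidence level for the bias interval.
#' @return Object of class `bland_altman`: `bias`, `bias_ci_low`,
#'   `bias_ci_high`, `sd_diff`, `loa_low`, `loa_high`,
#'   `significant_bias`, `n`.
#' @examples
#' bland_altman(c(120, 130, 125, 140), c(119, 128, 122, 136))
#' @export
bland_altman <- function(reference, comparison, conf_level = 0.95) {
  if (length(reference) != length(comparison)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (anyNA(reference) || anyNA(comparison)) {
    stop("missing values not allowed", call. = FALSE)
  }
  n <- length(reference)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- reference - comparison
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  half <- tq * sd_diff / sqrt(n)
  ci <- c(bias - half, bias + half)
  structure(list(bias = bias, bias_ci_low = ci[1], bias_ci_high = ci[2],
                 sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 significant_bias = ci[1] > 0 || ci[2] < 0,
                 n = n, conf_level = conf_level),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bias %.2f (%d%% CI %.2f to %.2f), LoA (%.2f, %.2f), n = %d%s\n",
              x$bias, round(100 * x$conf_level), x$bias_ci_low,
              x$bias_ci_high, x$loa_low, x$loa_high, x$n,
              if (x$significant_bias) " [significant bias]" else ""))
  invisible(x)
}

#' Attribute a discordant classification pair to its cause
#'
#' For a subject whose CHW and physician classifications differ, decides
#' counterfactually whether the disagreement is attributable to blood
#' pressure measurement alone, to recorded history alone, or to both.
#' "History" here means the fields the decision table actually consumes:
#' prior hypertension diagnosis and current antihypertensive use (interim
#' events at secondary visits). The rule:
#' \enumerate{
#'   \item identical decision-relevant history on both records implies the
#'     blood pressure must be responsible: `BP_ONLY`;
#'   \item otherwise, if both effective pressures fall on the same side of
#'     the 140/90 elevation threshold, pressure cannot explain the flip:
#'     `HISTORY_ONLY`;
#'   \item otherwise both differ: `BP_AND_HISTORY`.
#' }
#' The direction is `UNDERDIAGNOSIS` when the CHW category is below the
#' physician's in the severity ordering NO < POSSIBLE < CONFIRMED, else
#' `OVERDIAGNOSIS`.
#'
#' @param chw,phys Encounter records (list-like, same subject and visit)
#'   with reading columns and history flags as in [classify_encounter()].
#' @return List with elements `cause` and `direction`.
#' @export
attribute_discordance <- function(chw, phys) {
  c_chw <- classify_encounter(chw)
  c_phys <- classify_encounter(phys)
  if (c_chw == c_phys) {
    stop("pair is concordant; discordance label undefined", call. = FALSE)
  }
  secondary <- identical(toupper(as.character(chw$visit)), "SECONDARY")
  hist_fields <- if (secondary) {
    c("interim_htn_dx", "interim_antihypertensive")
  } else {
    c("prior_htn_dx", "taking_antihypertensive")
  }
  hist_same <- all(vapply(hist_fields, function(f) {
    identical(isTRUE(as.logical(chw[[f]])), isTRUE(as.logical(phys[[f]])))
  }, logical(1)))
  eff <- function(rec) {
    sbps <- as.numeric(c(rec$sbp1, rec$sbp2, rec$sbp3))
    dbps <- as.numeric(c(rec$dbp1, rec$dbp2, rec$dbp3))
    keep <- !is.na(sbps) & !is.na(dbps)
    session_blood_pressure(data.frame(sbp = sbps[keep], dbp = dbps[keep]))
  }
  cause <- if (hist_same) {
    "BP_ONLY"
  } else if (is_elevated(eff(chw)) == is_elevated(eff(phys))) {
    "HISTORY_ONLY"
  } else {
    "BP_AND_HISTORY"
  }
  ord <- match(c(c_chw, c_phys), htn_levels())
  list(cause = cause,
       direction = if (ord[1] < ord[2]) "UNDERDIAGNOSIS" else "OVERDIAGNOSIS")
}
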