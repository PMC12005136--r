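#' Published cross-tabulations from the CHW hypertension screening study
#'
#' The cross-tabulations printed by the diagnostic-accuracy study this
#' package models (359 adults in rural Guatemala, paired blinded CHW and
#' physician assessments). Rows are the CHW assessment, columns the
#' physician reference assessment.
#'
#' \describe{
#'   \item{primary}{3x3 classification table at the initial screening
#'     visit (No / Possible / Confirmed hypertension).}
#'   \item{secondary}{2x2 table for the 11 subjects who completed the
#'     confirmatory visit (No / Confirmed).}
#'   \item{overall}{3x3 table of final classifications, with the
#'     confirmatory result superseding the initial one where available.}
#' }
#'
#' @return Named list of integer matrices.
#' @export
study_crosstabs <- function() {
  lv <- htn_levels()
  primary <- matrix(c(292, 1, 7,
                      6, 9, 4,
                      4, 3, 33), nrow = 3, byrow = TRUE,
                    dimnames = list(chw = lv, physician = lv))
  secondary <- matrix(c(0, 2,
                        2, 7), nrow = 2, byrow = TRUE,
                      dimnames = list(chw = c("NO_HTN", "CONFIRMED_HTN"),
                                      physician = c("NO_HTN", "CONFIRMED_HTN")))
  overall <- matrix(c(292, 0, 9,
                      6, 1, 4,
                      6, 1, 40), nrow = 3, byrow = TRUE,
                    dimnames = list(chw = lv, physician = lv))
  list(primary = primary, secondary = secondary, overall = overall)
}

#' Published per-item history agreement summary
#'
#' The per-item agreement summary for the binary medical and social
#' history variables as reported by the study (cohort N = 359): the number
#' of physician-identified positives, overall agreement, and sensitivity
#' — the marginals from which the underlying 2x2 tables can be rebuilt
#' with [reconstruct_2x2()]. Sensitivity printed as 0 with zero kappa
#' structure (the CAD and heart-failure rows, where the CHW found none of
#' the reference positives) is retained as the printed value.
#'
#' @return Data frame with columns `item`, `n`, `positives`,
#'   `overall_agreement`, `sensitivity`.
#' @export
study_history_rows <- function() {
  data.frame(
    item = c("cad", "heart_failure", "diabetes", "stroke",
             "hyperlipidemia", "ckd", "prior_htn_dx",
             "taking_antihypertensive", "smokes", "alcohol_30d"),
    n = 359L,
    positives = c(1L, 5L, 43L, 8L, 30L, 9L, 93L, 26L, 12L, 27L),
    overall_agreement = c(0.9694, 0.9805, 0.9861, 0.9694, 0.9415,
                          0.9499, 0.8914, 0.9833, 0.9972, 0.9805),
    sensitivity = c(0.00, 0.00, 0.95, 0.40, 0.70, 0.26, 0.81, 0.92,
                    1.00, 0.88),
    stringsAsFactors = FALSE
  )
}
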