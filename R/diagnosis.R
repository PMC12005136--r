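#' @title Hypertension classification engine
#'
#' @description
#' The classification rules encoded here mirror the branching-logic decision
#' support used in paired CHW/physician hypertension screening encounters.
#' Blood pressure is measured one to three times per session: when the first
#' reading is at or above the repeat trigger (130/85 mmHg), two further
#' readings are taken and their average is the effective session pressure.
#' Elevated blood pressure is defined as SBP >= 140 mmHg or DBP >= 90 mmHg.
#' At the primary screening visit a subject is classified into one of three
#' categories (no hypertension, possible hypertension, confirmed
#' hypertension); at the confirmatory secondary visit only two categories
#' (no current hypertension, confirmed hypertension) are allowed.
#'
#' @name diagnosis
NULL

#' Ordered hypertension status levels
#'
#' Category labels in increasing clinical severity. All classification
#' functions return values from this set; the ordering (NO < POSSIBLE <
#' CONFIRMED) is what "underdiagnosis" and "overdiagnosis" refer to in
#' discordance attribution.
#'
#' @return Character vector `c("NO_HTN", "POSSIBLE_HTN", "CONFIRMED_HTN")`.
#' @export
htn_levels <- function() c("NO_HTN", "POSSIBLE_HTN", "CONFIRMED_HTN")

#' Construct and validate a blood-pressure reading
#'
#' @param sbp Systolic pressure in mmHg (positive, finite).
#' @param dbp Diastolic pressure in mmHg (positive, finite, strictly below
#'   `sbp`).
#' @return A named numeric vector `c(sbp = , dbp = )` of class `bp_reading`.
#' @examples
#' bp_reading(125, 80)
#' @export
bp_reading <- function(sbp, dbp) {
  stopifnot(length(sbp) == 1L, length(dbp) == 1L)
  if (!is.finite(sbp) || !is.finite(dbp)) {
    stop("blood-pressure readings must be finite", call. = FALSE)
  }
  if (dbp <= 0 || sbp <= dbp) {
    stop("invalid reading: require sbp > dbp > 0, got (",
         sbp, ", ", dbp, ")", call. = FALSE)
  }
  structure(c(sbp = as.numeric(sbp), dbp = as.numeric(dbp)),
            class = "bp_reading")
}

#' Does a first reading trigger repeat measurements?
#'
#' The measurement protocol repeats the reading twice more (at 1-minute
#' intervals) when the initial pressure is at or above 130/85 mmHg,
#' interpreted disjunctively: SBP >= 130 OR DBP >= 85.
#'
#' @param sbp,dbp Numeric vectors of systolic/diastolic pressure (mmHg).
#' @param sbp_threshold,dbp_threshold Trigger thresholds, default 130/85.
#' @return Logical vector.
#' @export
repeat_trigger <- function(sbp, dbp, sbp_threshold = 130, dbp_threshold = 85) {
  sbp >= sbp_threshold | dbp >= dbp_threshold
}

#' Reduce a measurement session to one effective blood pressure
#'
#' Applies the session protocol: if the first reading is below the repeat
#' trigger the session consists of that single reading, which is the
#' effective pressure. If the trigger is met, readings two and three must be
#' present and the effective pressure is their component-wise arithmetic
#' mean, kept at full precision (averaging two integers can give a half, and
#' no rounding happens before threshold comparison).
#'
#' @param readings A 1- or 3-row matrix or data frame with columns `sbp` and
#'   `dbp`, in measurement order.
#' @param sbp_trigger,dbp_trigger Repeat-trigger thresholds (mmHg).
#' @return A `bp_reading` with the effective session pressure.
#' @examples
#' session_blood_pressure(data.frame(sbp = 125, dbp = 80))
#' session_blood_pressure(data.frame(sbp = c(135, 142, 138),
#'                                   dbp = c(88, 90, 86)))
#' @export
session_blood_pressure <- function(readings, sbp_trigger = 130,
                                   dbp_trigger = 85) {
  readings <- as.data.frame(readings)
  if (nrow(readings) == 0L) stop("empty blood-pressure session", call. = FALSE)
  if (!all(c("sbp", "dbp") %in% names(readings))) {
    stop("readings need columns 'sbp' and 'dbp'", call. = FALSE)
  }
  first <- bp_reading(readings$sbp[1], readings$dbp[1])
  if (!repeat_trigger(first["sbp"], first["dbp"], sbp_trigger, dbp_trigger)) {
    return(first)
  }
  if (nrow(readings) < 3L || anyNA(readings$sbp[2:3]) || anyNA(readings$dbp[2:3])) {
    stop("protocol violation: first reading at or above ", sbp_trigger, "/",
         dbp_trigger, " mmHg requires three readings", call. = FALSE)
  }
  for (k in 2:3) bp_reading(readings$sbp[k], readings$dbp[k])  # validate
  bp_reading(mean(readings$sbp[2:3]), mean(readings$dbp[2:3]))
}

#' Is a blood pressure elevated?
#'
#' Elevated means SBP >= 140 mmHg or DBP >= 90 mmHg (both thresholds
#' inclusive), following international hypertension guidelines.
#'
#' @param sbp A `bp_reading`, or a numeric vector of systolic pressures.
#' @param dbp Numeric vector of diastolic pressures (ignored when `sbp` is a
#'   `bp_reading`).
#' @param sbp_threshold,dbp_threshold Elevation thresholds, default 140/90.
#' @return Logical vector.
#' @export
is_elevated <- function(sbp, dbp = NULL, sbp_threshold = 140,
                        dbp_threshold = 90) {
  if (inherits(sbp, "bp_reading")) {
    dbp <- sbp[["dbp"]]
    sbp <- sbp[["sbp"]]
  }
  sbp >= sbp_threshold | dbp >= dbp_threshold
}

#' Classify hypertension status at the primary screening visit
#'
#' Decision table for the three-way classification:
#' \itemize{
#'   \item CONFIRMED_HTN if the subject currently takes antihypertensive
#'     medication (treated hypertension is hypertension regardless of the
#'     measured pressure), or if the pressure is elevated and the subject
#'     reports a prior hypertension diagnosis;
#'   \item POSSIBLE_HTN if the pressure is elevated with no prior diagnosis
#'     and no antihypertensive use (a confirmatory visit on another date is
#'     then required);
#'   \item NO_HTN otherwise, including a prior diagnosis with neither
#'     current elevation nor medication.
#' }
#' All arguments are vectorized.
#'
#' @param elevated Logical: is the effective session pressure elevated?
#'   (see [is_elevated()]).
#' @param prior_htn_dx Logical: prior diagnosis of (or told about) elevated
#'   blood pressure / hypertension.
#' @param taking_antihypertensive Logical: current antihypertensive use.
#' @return Character vector of [htn_levels()] values.
#' @export
classify_primary <- function(elevated, prior_htn_dx, taking_antihypertensive) {
  stopifnot(is.logical(elevated), is.logical(prior_htn_dx),
            is.logical(taking_antihypertensive))
  out <- rep("NO_HTN", length(elevated))
  out[elevated & !prior_htn_dx & !taking_antihypertensive] <- "POSSIBLE_HTN"
  out[taking_antihypertensive | (elevated & prior_htn_dx)] <- "CONFIRMED_HTN"
  out
}

#' Classify hypertension status at the secondary (confirmatory) visit
#'
#' Subjects classified POSSIBLE_HTN at the primary visit return for a
#' confirmatory assessment. Medical history is not re-taken; only interim
#' events (a hypertension diagnosis by another provider, or a new
#' antihypertensive prescription) can alter it. The outcome is binary:
#' CONFIRMED_HTN when the pressure is elevated or an interim event is
#' reported, NO_HTN otherwise. POSSIBLE_HTN is never emitted here.
#'
#' @param elevated Logical: effective session pressure elevated?
#' @param interim_htn_dx Logical: interim hypertension diagnosis reported.
#' @param interim_antihypertensive Logical: interim antihypertensive
#'   prescription reported.
#' @return Character vector, each element `"CONFIRMED_HTN"` or `"NO_HTN"`.
#' @export
classify_secondary <- function(elevated, interim_htn_dx = FALSE,
                               interim_antihypertensive = FALSE) {
  stopifnot(is.logical(elevated))
  ifelse(elevated | interim_htn_dx | interim_antihypertensive,
         "CONFIRMED_HTN", "NO_HTN")
}

#' Classify a single encounter record
#'
#' Convenience wrapper that applies the session protocol and the visit's
#' decision table to one encounter (a list or one-row data frame with
#' reading columns `sbp1,dbp1,...,sbp3,dbp3` and the history flags).
#'
#' @param rec A list-like encounter record.
#' @return The engine classification, one of [htn_levels()].
#' @export
classify_encounter <- function(rec) {
  sbps <- as.numeric(c(rec$sbp1, rec$sbp2, rec$sbp3))
  dbps <- as.numeric(c(rec$dbp1, rec$dbp2, rec$dbp3))
  keep <- !is.na(sbps) & !is.na(dbps)
  eff <- session_blood_pressure(data.frame(sbp = sbps[keep], dbp = dbps[keep]))
  elev <- is_elevated(eff)
  if (identical(toupper(as.character(rec$visit)), "SECONDARY")) {
    classify_secondary(elev,
                       isTRUE(as.logical(rec$interim_htn_dx)),
                       isTRUE(as.logical(rec$interim_antihypertensive)))
  } else {
    classify_primary(elev,
                     isTRUE(as.logical(rec$prior_htn_dx)),
                     isTRUE(as.logical(rec$taking_antihypertensive)))
  }
}
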