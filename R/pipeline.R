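#' Pipeline configuration
#'
#' Thresholds and criteria used throughout the analysis, defaulting to the
#' study's values: 140/90 mmHg elevation, 130/85 repeat trigger, kappa MAC
#' 0.61, accuracy MAC 90%, one-sided alpha 5%, clinical weight matrix.
#'
#' @param sbp_elevated,dbp_elevated Elevation thresholds (mmHg).
#' @param sbp_repeat,dbp_repeat Repeat-measurement trigger (mmHg).
#' @param kappa_mac,accuracy_mac Minimally acceptable criteria.
#' @param conf_level Two-sided confidence level.
#' @param weights Agreement weight matrix for the 3x3 kappa.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sbp_elevated = 140, dbp_elevated = 90,
                            sbp_repeat = 130, dbp_repeat = 85,
                            kappa_mac = 0.61, accuracy_mac = 0.90,
                            conf_level = 0.95,
                            weights = cicchetti_weights(3)) {
  structure(list(sbp_elevated = sbp_elevated, dbp_elevated = dbp_elevated,
                 sbp_repeat = sbp_repeat, dbp_repeat = dbp_repeat,
                 kappa_mac = kappa_mac, accuracy_mac = accuracy_mac,
                 conf_level = conf_level, weights = weights),
            class = "pipeline_config")
}

history_items <- c("cad", "heart_failure", "diabetes", "stroke",
                   "hyperlipidemia", "ckd", "prior_htn_dx",
                   "taking_antihypertensive", "smokes", "alcohol_30d")

encounter_columns <- c("subject_id", "visit", "evaluator", "age_years",
                       "sex", "height_cm", "weight_kg",
                       "sbp1", "dbp1", "sbp2", "dbp2", "sbp3", "dbp3",
                       history_items,
                       "cigarettes_per_day", "drinks_30d",
                       "activity_days_per_week", "stove_type",
                       "cooking_location", "interim_htn_dx",
                       "interim_antihypertensive", "classification")

#' Read paired encounter records
#'
#' Reads the flat encounter schema (one row per evaluator-visit; the three
#' readings as `sbp1/dbp1 ... sbp3/dbp3`, missing readings as empty
#' fields, never 0) from CSV or JSON-lines. Schema violations are reported
#' with their row numbers.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"`; inferred from the extension by
#'   default.
#' @return Data frame of encounter records.
#' @export
read_encounters <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("jsonl", "json"))
      "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), encoding = "UTF-8")
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  missing_cols <- setdiff(c("subject_id", "visit", "evaluator",
                            "sbp1", "dbp1"), names(df))
  if (length(missing_cols) > 0) {
    stop("encounter file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c(history_items, "interim_htn_dx",
                          "interim_antihypertensive"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  bad <- which(is.na(df$sbp1) | is.na(df$dbp1))
  if (length(bad) > 0) {
    stop("missing first reading in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # readings 2 and 3 must be jointly present or jointly absent
  half <- which(xor(is.na(df$sbp2), is.na(df$sbp3)) |
                  xor(is.na(df$dbp2), is.na(df$dbp3)) |
                  xor(is.na(df$sbp2), is.na(df$dbp2)))
  if (length(half) > 0) {
    stop("protocol violation (incomplete repeat readings) in rows: ",
         paste(half, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write encounter records
#'
#' @param encounters Data frame of encounter records.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(encounters, path,
                             format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("jsonl", "json"))
      "jsonl" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(encounters, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(encounters, con, verbose = FALSE, na = "null")
  }
  invisible(path)
}

# Vectorized effective session BP over a data frame of records.
effective_bp <- function(df, config = pipeline_config()) {
  trig <- repeat_trigger(df$sbp1, df$dbp1, config$sbp_repeat, config$dbp_repeat)
  viol <- trig & (is.na(df$sbp2) | is.na(df$sbp3) |
                    is.na(df$dbp2) | is.na(df$dbp3))
  if (any(viol)) {
    stop("protocol violation (trigger met, repeats missing) in rows: ",
         paste(which(viol), collapse = ", "), call. = FALSE)
  }
  data.frame(
    sbp = ifelse(trig, (df$sbp2 + df$sbp3) / 2, df$sbp1),
    dbp = ifelse(trig, (df$dbp2 + df$dbp3) / 2, df$dbp1)
  )
}

# Vectorized engine classification of encounter rows.
classify_records <- function(df, config = pipeline_config()) {
  eff <- effective_bp(df, config)
  elev <- is_elevated(eff$sbp, eff$dbp, config$sbp_elevated,
                      config$dbp_elevated)
  secondary <- toupper(df$visit) == "SECONDARY"
  out <- classify_primary(elev,
                          df$prior_htn_dx %in% TRUE,
                          df$taking_antihypertensive %in% TRUE)
  if (any(secondary)) {
    out[secondary] <- classify_secondary(
      elev[secondary],
      df$interim_htn_dx[secondary] %in% TRUE,
      df$interim_antihypertensive[secondary] %in% TRUE)
  }
  out
}

validate_pairing <- function(df) {
  key <- paste(df$subject_id, df$visit, df$evaluator, sep = "|")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicate subject-visit-evaluator keys: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  sv <- unique(df[, c("subject_id", "visit")])
  orphan <- character(0)
  for (i in seq_len(nrow(sv))) {
    ev <- df$evaluator[df$subject_id == sv$subject_id[i] &
                         df$visit == sv$visit[i]]
    if (!setequal(ev, c("CHW", "PHYSICIAN"))) {
      orphan <- c(orphan, paste(sv$subject_id[i], sv$visit[i], sep = "|"))
    }
  }
  if (length(orphan) > 0) {
    stop("orphan records (missing paired evaluator) for: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Run the complete paired-agreement analysis
#'
#' Recomputes the engine classification for every record (logging
#' evaluator overrides where the recorded classification differs), then
#' assembles the full agreement report: per-visit and overall
#' cross-tabulations; weighted and unweighted kappa with MAC
#' non-inferiority tests at the primary visit; proportional agreement with
#' Wald intervals per visit and overall; per-item binary agreement metrics
#' for the medical and social history; Bland-Altman rows for systolic and
#' diastolic pressure, height, weight and BMI; and the counterfactual
#' discordance attribution summary.
#'
#' The overall classification takes, for each subject, the secondary-visit
#' result when a confirmatory visit was completed and the primary result
#' otherwise (so subjects lost to follow-up remain possible hypertension).
#'
#' @param encounters Data frame of paired encounter records (every
#'   subject-visit must have exactly one CHW and one PHYSICIAN row).
#' @param config A [pipeline_config()].
#' @return Object of class `analysis_report` with elements `cross_tabs`,
#'   `kappa_results`, `accuracy_results`, `binary_metric_rows`,
#'   `bland_altman_rows`, `discordance_summary`, `discordance_labels`,
#'   `overrides`, `n_subjects`, `n_encounters`.
#' @export
run_pipeline <- function(encounters, config = pipeline_config()) {
  if (nrow(encounters) == 0) stop("no encounter records", call. = FALSE)
  validate_pairing(encounters)
  df <- encounters
  df$engine_classification <- classify_records(df, config)
  overrides <- if ("classification" %in% names(df)) {
    df[!is.na(df$classification) &
         df$classification != df$engine_classification,
       c("subject_id", "visit", "evaluator", "classification",
         "engine_classification")]
  } else df[0, c("subject_id", "visit", "evaluator")]

  chw <- df[df$evaluator == "CHW", ]
  phys <- df[df$evaluator == "PHYSICIAN", ]
  phys <- phys[match(paste(chw$subject_id, chw$visit),
                     paste(phys$subject_id, phys$visit)), ]

  prim <- chw$visit == "PRIMARY"
  sec <- chw$visit == "SECONDARY"
  cross_tabs <- list(
    primary = crosstab(chw$engine_classification[prim],
                       phys$engine_classification[prim],
                       levels = htn_levels())
  )
  if (any(sec)) {
    cross_tabs$secondary <- crosstab(chw$engine_classification[sec],
                                     phys$engine_classification[sec],
                                     levels = c("NO_HTN", "CONFIRMED_HTN"))
  }
  # overall: secondary result supersedes the primary one where completed
  final_class <- function(side) {
    cls <- side$engine_classification[side$visit == "PRIMARY"]
    names(cls) <- side$subject_id[side$visit == "PRIMARY"]
    s <- side[side$visit == "SECONDARY", ]
    cls[s$subject_id] <- s$engine_classification
    cls
  }
  fc_chw <- final_class(chw)
  fc_phys <- final_class(phys)
  cross_tabs$overall <- crosstab(fc_chw, fc_phys[names(fc_chw)],
                                 levels = htn_levels())

  kappa_results <- list(
    primary_weighted = weighted_kappa(cross_tabs$primary, config$weights,
                                      mac = config$kappa_mac,
                                      conf_level = config$conf_level),
    primary_unweighted = weighted_kappa(cross_tabs$primary,
                                        identity_weights(3),
                                        mac = config$kappa_mac,
                                        conf_level = config$conf_level)
  )
  accuracy_results <- lapply(cross_tabs, proportional_agreement,
                             mac = config$accuracy_mac,
                             conf_level = config$conf_level)

  items <- intersect(history_items, names(chw))
  binary_metric_rows <- lapply(stats::setNames(items, items), function(it) {
    a <- chw[[it]][prim] %in% TRUE
    b <- phys[[it]][prim] %in% TRUE
    binary_metrics(crosstab(a, b, levels = c(TRUE, FALSE)))
  })

  eff_chw <- effective_bp(chw[prim, ], config)
  eff_phys <- effective_bp(phys[prim, ], config)
  bmi <- function(side, i) side$weight_kg[i] / (side$height_cm[i] / 100)^2
  # a measurement row is omitted when it cannot be computed (fewer than 3
  # pairs, or the anthropometric columns are absent)
  ba_try <- function(ref, cmp) {
    tryCatch(bland_altman(ref, cmp, config$conf_level),
             error = function(e) NULL)
  }
  bland_altman_rows <- Filter(Negate(is.null), list(
    sbp = ba_try(eff_phys$sbp, eff_chw$sbp),
    dbp = ba_try(eff_phys$dbp, eff_chw$dbp),
    height = ba_try(phys$height_cm[prim], chw$height_cm[prim]),
    weight = ba_try(phys$weight_kg[prim], chw$weight_kg[prim]),
    bmi = ba_try(bmi(phys, prim), bmi(chw, prim))
  ))

  disc <- which(chw$engine_classification != phys$engine_classification)
  labels <- lapply(disc, function(i) {
    lab <- attribute_discordance(as.list(chw[i, ]), as.list(phys[i, ]))
    data.frame(subject_id = chw$subject_id[i], visit = chw$visit[i],
               cause = lab$cause, direction = lab$direction,
               stringsAsFactors = FALSE)
  })
  labels <- if (length(labels) > 0) do.call(rbind, labels) else
    data.frame(subject_id = character(0), visit = character(0),
               cause = character(0), direction = character(0))
  discordance_summary <- as.matrix(table(
    factor(labels$cause, c("BP_ONLY", "BP_AND_HISTORY", "HISTORY_ONLY")),
    factor(labels$direction, c("UNDERDIAGNOSIS", "OVERDIAGNOSIS"))))

  structure(list(cross_tabs = cross_tabs,
                 kappa_results = kappa_results,
                 accuracy_results = accuracy_results,
                 binary_metric_rows = binary_metric_rows,
                 bland_altman_rows = bland_altman_rows,
                 discordance_summary = discordance_summary,
                 discordance_labels = labels,
                 overrides = overrides,
                 n_subjects = length(unique(encounters$subject_id)),
                 n_encounters = nrow(encounters)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Paired-agreement analysis:", x$n_subjects, "subjects,",
      x$n_encounters, "encounter records\n\n")
  cat("Primary-visit cross-tabulation (CHW rows, physician columns):\n")
  print(x$cross_tabs$primary)
  cat("\n")
  print(x$kappa_results$primary_weighted)
  cat("\n")
  print(x$accuracy_results$primary)
  if (nrow(x$discordance_labels) > 0) {
    cat("\nDiscordance attribution (cause x direction):\n")
    print(x$discordance_summary)
  }
  invisible(x)
}

report_to_list <- function(report) {
  num <- function(x) unclass(x)[!vapply(unclass(x), is.matrix, logical(1))]
  list(
    n_subjects = report$n_subjects,
    n_encounters = report$n_encounters,
    cross_tabs = lapply(report$cross_tabs, function(m) {
      list(labels = rownames(m), counts = unname(apply(m, 1, as.integer,
                                                       simplify = FALSE)))
    }),
    kappa = lapply(report$kappa_results, num),
    accuracy = lapply(report$accuracy_results, unclass),
    binary_metrics = lapply(report$binary_metric_rows, function(b) {
      out <- unclass(b)
      out$kappa <- out$kappa$estimate
      out
    }),
    bland_altman = lapply(report$bland_altman_rows, unclass),
    discordance = list(
      summary = list(causes = rownames(report$discordance_summary),
                     directions = colnames(report$discordance_summary),
                     counts = unname(apply(report$discordance_summary, 1,
                                           as.integer, simplify = FALSE))),
      labels = report$discordance_labels),
    overrides = report$overrides
  )
}

#' Write an analysis report to JSON or markdown
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output file.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    lines <- utils::capture.output(print(report))
    md <- c("# Paired-agreement analysis report", "", "```", lines, "```", "")
    for (nm in names(report$binary_metric_rows)) {
      b <- report$binary_metric_rows[[nm]]
      md <- c(md, sprintf(
        "- **%s**: agreement %.1f%%, kappa %.2f, MCC %.2f, Se %s, Sp %s, PPV %s, NPV %s",
        nm, 100 * b$overall_agreement, b$kappa$estimate, b$mcc,
        fmt_or_na(b$sensitivity), fmt_or_na(b$specificity),
        fmt_or_na(b$ppv), fmt_or_na(b$npv)))
    }
    md <- c(md, "")
    for (nm in names(report$bland_altman_rows)) {
      ba <- report$bland_altman_rows[[nm]]
      md <- c(md, sprintf(
        "- **%s**: bias %.2f (CI %.2f to %.2f), LoA (%.2f, %.2f)%s",
        nm, ba$bias, ba$bias_ci_low, ba$bias_ci_high, ba$loa_low,
        ba$loa_high, if (ba$significant_bias) " *significant*" else ""))
    }
    writeLines(md, path, useBytes = FALSE)
  }
  invisible(path)
}

fmt_or_na <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f", x)
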