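#' @keywords internal
"_PACKAGE"

.physio_cols <- c("respiratory_rate", "spo2", "heart_rate", "systolic_bp",
                  "temperature_c", "consciousness")
.social_cols <- c("age_years", "socially_isolated", "chronic_disease",
                  "performance_status")
.required_cols <- c("patient_id", .physio_cols, .social_cols)

# map from CSV column to band-table name
.band_for_col <- c(
  respiratory_rate = "respiratory_rate",
  spo2 = "spo2",
  heart_rate = "heart_rate",
  systolic_bp = "systolic_bp",
  temperature_c = "temperature"
)

#' Validate a patient-record table
#'
#' Checks the cohort table against the scoring data model: required columns,
#' unique patient identifiers, flags coded 0/1, performance status in 0-4,
#' non-negative age, physiologically plausible vital signs, and recognised
#' consciousness tokens. Under the default `missing = "strict"` policy any
#' missing value is an error (mirroring an instrument form that must be
#' fully completed); `missing = "zero"` tolerates missing *physiological*
#' measurements, which the scorer will count as normal.
#'
#' @param records data frame of patient records (see [read_patient_csv()]
#'   for the column schema).
#' @param tables band tables from [pmews_band_tables()].
#' @param missing missing-data policy, `"strict"` (default) or `"zero"`.
#' @return `records`, invisibly, with numeric columns coerced.
#' @export
validate_patients <- function(records, tables = pmews_band_tables(),
                              missing = c("strict", "zero")) {
  missing <- match.arg(missing)
  if (!is.data.frame(records)) validation_error("records must be a data frame")
  absent <- setdiff(.required_cols, names(records))
  if (length(absent) > 0) {
    validation_error(sprintf("required column(s) missing: %s",
                             paste(absent, collapse = ", ")))
  }
  if (nrow(records) == 0) validation_error("empty cohort")
  if (anyDuplicated(records$patient_id)) {
    dup <- records$patient_id[duplicated(records$patient_id)][1]
    validation_error(sprintf("duplicate patient_id '%s'", dup))
  }
  num_cols <- c(names(.band_for_col), "age_years", "socially_isolated",
                "chronic_disease", "performance_status")
  for (cl in num_cols) {
    if (is.logical(records[[cl]])) records[[cl]] <- as.numeric(records[[cl]])
    if (!is.numeric(records[[cl]])) {
      validation_error(sprintf("column '%s' must be numeric", cl))
    }
  }
  check_missing <- function(col) {
    i <- which(is.na(records[[col]]))
    if (length(i) > 0) {
      validation_error(sprintf(
        "missing %s for patient(s): %s", col,
        paste(utils::head(records$patient_id[i], 5), collapse = ", ")
      ))
    }
  }
  if (missing == "strict") for (cl in .physio_cols) check_missing(cl)
  for (cl in .social_cols) check_missing(cl)
  # range checks, reported with the offending patient
  check_range <- function(col, ok, what) {
    bad <- which(!ok & !is.na(records[[col]]))
    if (length(bad) > 0) {
      validation_error(sprintf(
        "patient '%s': %s value %s %s",
        records$patient_id[bad[1]], col, format(records[[col]][bad[1]]), what
      ))
    }
  }
  for (cl in names(.band_for_col)) {
    tb <- tables[[.band_for_col[[cl]]]]
    v <- records[[cl]]
    check_range(cl, v >= tb$plausible[1] & v <= tb$plausible[2],
                sprintf("outside plausible range [%s, %s]",
                        tb$plausible[1], tb$plausible[2]))
  }
  check_range("age_years", records$age_years >= 0, "is negative")
  check_range("socially_isolated", records$socially_isolated %in% c(0, 1),
              "is not a 0/1 flag")
  check_range("chronic_disease", records$chronic_disease %in% c(0, 1),
              "is not a 0/1 flag")
  check_range("performance_status", records$performance_status %in% 0:4,
              "is not an integer in 0-4")
  score_consciousness(records$consciousness)  # token check
  if ("needs_ems" %in% names(records)) {
    if (is.logical(records$needs_ems)) {
      records$needs_ems <- as.numeric(records$needs_ems)
    }
    check_range("needs_ems", records$needs_ems %in% c(0, 1),
                "is not a 0/1 flag")
  }
  invisible(records)
}

#' Physiological (MEWS) component score
#'
#' Sums the six physiological sub-scores: respiratory rate, oxygen
#' saturation, heart rate, systolic blood pressure, temperature (each banded
#' per the instrument's tables) and consciousness. Range 0-17 (temperature
#' contributes at most 2, the other five at most 3 each).
#'
#' @inheritParams validate_patients
#' @param vitals data frame with columns `respiratory_rate`, `spo2`,
#'   `heart_rate`, `systolic_bp`, `temperature_c`, `consciousness`.
#' @return integer vector of physiological scores.
#' @export
physiological_score <- function(vitals, tables = pmews_band_tables(),
                                missing = c("strict", "zero")) {
  as.integer(rowSums(physio_subscores(vitals, tables, match.arg(missing))))
}

# matrix of the six physiological sub-scores, missing policy applied
physio_subscores <- function(vitals, tables, missing) {
  cols <- lapply(names(.band_for_col), function(cl) {
    score_parameter(tables[[.band_for_col[[cl]]]], vitals[[cl]])
  })
  cols <- c(cols, list(score_consciousness(vitals$consciousness)))
  sub <- do.call(cbind, cols)
  if (any(is.na(sub))) {
    if (missing == "strict") {
      bad <- which(rowSums(is.na(sub)) > 0)[1]
      id <- if ("patient_id" %in% names(vitals)) vitals$patient_id[bad] else bad
      validation_error(sprintf("patient '%s': missing physiological data", id))
    }
    n_imp <- sum(rowSums(is.na(sub)) > 0)
    ids <- if ("patient_id" %in% names(vitals)) {
      vitals$patient_id[rowSums(is.na(sub)) > 0]
    } else which(rowSums(is.na(sub)) > 0)
    message(sprintf(
      "scored %d missing physiological value(s) as 0 (normal) for patient(s): %s",
      sum(is.na(sub)), paste(utils::head(ids, 10), collapse = ", ")
    ))
    sub[is.na(sub)] <- 0L
  }
  colnames(sub) <- c(names(.band_for_col), "consciousness")
  sub
}

#' Social (patient-data) component score
#'
#' One point each for age over 65 (strictly greater), social isolation
#' (living alone or of no fixed abode) and chronic disease, plus the 0-4
#' performance-status scale. Range 0-7.
#'
#' @param social data frame with columns `age_years`, `socially_isolated`,
#'   `chronic_disease`, `performance_status`.
#' @return integer vector of social scores.
#' @export
social_score <- function(social) {
  as.integer(
    (social$age_years > 65) +
      (social$socially_isolated > 0) +
      (social$chronic_disease > 0) +
      social$performance_status
  )
}

#' Score a cohort with the full PMEWS instrument
#'
#' Validates the records, computes the six physiological sub-scores and the
#' social items, and appends per-parameter sub-score columns (`score_*`)
#' together with `physiological_score` (0-17), `social_score` (0-7) and
#' `total_pmews` (0-24, the sum of the two components).
#'
#' @inheritParams validate_patients
#' @return the input data frame with sub-score and score columns appended.
#' @examples
#' rec <- data.frame(
#'   patient_id = "P1", respiratory_rate = 20, spo2 = 92, heart_rate = 105,
#'   systolic_bp = 95, temperature_c = 38.2, consciousness = "confused",
#'   age_years = 65, socially_isolated = 0, chronic_disease = 1,
#'   performance_status = 2
#' )
#' score_cohort(rec)[, c("physiological_score", "social_score", "total_pmews")]
#' @export
score_cohort <- function(records, tables = pmews_band_tables(),
                         missing = c("strict", "zero")) {
  missing <- match.arg(missing)
  records <- validate_patients(records, tables, missing)
  sub <- physio_subscores(records, tables, missing)
  out <- records
  for (cl in colnames(sub)) out[[paste0("score_", cl)]] <- as.integer(sub[, cl])
  out$physiological_score <- as.integer(rowSums(sub))
  out$social_score <- social_score(records)
  out$total_pmews <- out$physiological_score + out$social_score
  out
}

#' Read / write patient cohorts
#'
#' `read_patient_csv()` reads a cohort in the package's patient CSV schema
#' (header required; columns `patient_id`, `respiratory_rate`, `spo2`,
#' `heart_rate`, `systolic_bp`, `temperature_c`, `consciousness`,
#' `age_years`, `socially_isolated`, `chronic_disease`,
#' `performance_status`, and optionally the gold-standard `needs_ems` 0/1
#' label). `write_patient_csv()` writes one; [score_cohort()] output can be
#' written with the same function.
#'
#' @param path file path.
#' @return `read_patient_csv()`: a data frame; `write_patient_csv()`: the
#'   path, invisibly.
#' @export
read_patient_csv <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(.required_cols, names(df))
  if (length(absent) > 0) {
    validation_error(sprintf("required column(s) missing: %s",
                             paste(absent, collapse = ", ")))
  }
  df
}

#' @rdname read_patient_csv
#' @param records data frame of (scored or unscored) patient records.
#' @export
write_patient_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
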