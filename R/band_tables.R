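#' Load the PMEWS physiological band tables
#'
#' The scoring instrument assigns each physiological measurement a sub-score
#' of 0-3 (0-2 for temperature) through an ordered table of intervals.
#' Tables ship as a versioned JSON resource so the instrument is auditable
#' and swappable; bands are stored exactly as printed on the admission form
#' and two normalisation steps are applied at load time:
#'
#' 1. **Gap closure.** The printed grid leaves a few values uncovered (for
#'    example SpO2 89 falls between "<89" and "90-93"). After rounding to the
#'    table's precision, any residual uncovered value is assigned to the
#'    adjacent band with the *higher* sub-score - a fail-safe rule for a
#'    triage instrument, where an ambiguous reading should escalate rather
#'    than reassure.
#' 2. **Validation.** Bands must be ordered, non-overlapping, and
#'    valley-shaped around a single zero band (sub-scores never decrease as
#'    a value moves away from the normal range); after gap closure every
#'    plausible value must map to exactly one band.
#'
#' @param file path to a band-table JSON file; `NULL` (default) loads the
#'   instrument shipped with the package (cached after first load).
#' @return A named list of `pmews_band_table` objects, one per physiological
#'   parameter (`respiratory_rate`, `spo2`, `heart_rate`, `systolic_bp`,
#'   `temperature`).
#' @seealso [score_parameter()], [score_consciousness()]
#' @examples
#' tables <- pmews_band_tables()
#' tables$respiratory_rate
#' @export
pmews_band_tables <- function(file = NULL) {
  use_cache <- is.null(file)
  if (use_cache && !is.null(.pmews_env$band_tables)) {
    return(.pmews_env$band_tables)
  }
  if (is.null(file)) {
    file <- system.file("extdata", "pmews_bands.json", package = "pmews")
    if (file == "") config_error("shipped band-table resource not found")
  }
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(raw$parameters)) {
    config_error(sprintf("band-table file '%s' has no 'parameters' entry", file))
  }
  tables <- lapply(names(raw$parameters), function(nm) {
    build_band_table(nm, raw$parameters[[nm]])
  })
  names(tables) <- names(raw$parameters)
  attr(tables, "version") <- raw$version %||% "unversioned"
  if (use_cache) .pmews_env$band_tables <- tables
  tables
}

# Construct and validate a single band table from its JSON description.
build_band_table <- function(name, spec) {
  if (is.null(spec$bands) || length(spec$bands) == 0) {
    config_error(sprintf("band table '%s': no bands defined", name))
  }
  digits <- spec$digits %||% 0
  step <- 10^(-digits)
  plausible <- as.numeric(unlist(spec$plausible %||% c(-Inf, Inf)))
  printed <- data.frame(
    lo = vapply(spec$bands, function(b) if (is.null(b[[1]])) -Inf else as.numeric(b[[1]]), 0),
    hi = vapply(spec$bands, function(b) if (is.null(b[[2]])) Inf else as.numeric(b[[2]]), 0),
    score = vapply(spec$bands, function(b) as.integer(b[[3]]), 0L)
  )
  ord <- order(printed$lo)
  printed <- printed[ord, , drop = FALSE]
  rownames(printed) <- NULL
  if (any(printed$lo > printed$hi)) {
    config_error(sprintf("band table '%s': band with lower bound above upper bound", name))
  }
  eps <- step * 1e-6
  nb <- nrow(printed)
  for (i in seq_len(nb - 1)) {
    if (printed$lo[i + 1] <= printed$hi[i] + eps) {
      config_error(sprintf(
        "band table '%s': overlapping bands [%s, %s] and [%s, %s]",
        name, printed$lo[i], printed$hi[i], printed$lo[i + 1], printed$hi[i + 1]
      ))
    }
  }
  # valley shape: exactly one zero band, sub-scores non-increasing towards it
  # and non-decreasing away from it
  zero <- which(printed$score == 0)
  if (length(zero) != 1) {
    config_error(sprintf("band table '%s': expected exactly one zero band", name))
  }
  left <- printed$score[seq_len(zero)]
  right <- printed$score[zero:nb]
  if (any(diff(left) > 0) || any(diff(right) < 0)) {
    config_error(sprintf("band table '%s': sub-scores must not decrease away from the zero band", name))
  }
  # gap closure (DD: extend the adjacent band with the higher sub-score)
  bands <- printed
  for (i in seq_len(nb - 1)) {
    if (bands$lo[i + 1] - bands$hi[i] > step * 1.5) {
      if (bands$score[i] >= bands$score[i + 1]) {
        bands$hi[i] <- bands$lo[i + 1] - step
      } else {
        bands$lo[i + 1] <- bands$hi[i] + step
      }
    }
  }
  tbl <- structure(
    list(
      parameter = name,
      units = spec$units %||% "",
      digits = digits,
      step = step,
      plausible = plausible,
      printed = printed,
      bands = bands,
      max_score = max(bands$score)
    ),
    class = "pmews_band_table"
  )
  check_band_coverage(tbl)
  tbl
}

# Assert every plausible grid value maps to exactly one band.
check_band_coverage <- function(tbl) {
  lo <- max(tbl$plausible[1], min(tbl$bands$lo[is.finite(tbl$bands$lo)]) - 5 * tbl$step)
  hi <- min(tbl$plausible[2], max(tbl$bands$hi[is.finite(tbl$bands$hi)]) + 5 * tbl$step)
  grid <- round(seq(lo, hi, by = tbl$step), tbl$digits)
  hits <- vapply(grid, function(v) {
    sum(v >= tbl$bands$lo - tbl$step * 1e-6 & v <= tbl$bands$hi + tbl$step * 1e-6)
  }, 0)
  if (any(hits != 1)) {
    bad <- grid[which(hits != 1)[1]]
    config_error(sprintf(
      "band table '%s': value %s is covered by %d bands after gap closure",
      tbl$parameter, format(bad), hits[which(hits != 1)[1]]
    ))
  }
  invisible(tbl)
}

#' @export
print.pmews_band_table <- function(x, ...) {
  cat(sprintf("PMEWS band table: %s (%s), rounded to %d decimal(s)\n",
              x$parameter, x$units, x$digits))
  b <- x$bands
  lab <- ifelse(is.infinite(b$lo), sprintf("<= %s", format(b$hi)),
         ifelse(is.infinite(b$hi), sprintf(">= %s", format(b$lo)),
                sprintf("%s-%s", format(b$lo), format(b$hi))))
  cat(paste(sprintf("  %-12s -> %d", lab, b$score), collapse = "\n"), "\n")
  invisible(x)
}

#' Score a single physiological parameter
#'
#' Rounds the measurement half-up to the table's precision, checks it lies in
#' the physiologically plausible range, and returns the sub-score of the
#' unique band containing the rounded value. Missing values propagate as
#' `NA` so the caller can apply its missing-data policy.
#'
#' @param table a `pmews_band_table` (an element of [pmews_band_tables()]).
#' @param value numeric vector of raw measurements.
#' @return integer vector of sub-scores.
#' @examples
#' tables <- pmews_band_tables()
#' score_parameter(tables$respiratory_rate, c(8, 14, 31))
#' score_parameter(tables$spo2, 89)  # gap value, escalates to 3
#' @export
score_parameter <- function(table, value) {
  if (!inherits(table, "pmews_band_table")) {
    config_error("'table' must be a pmews_band_table")
  }
  if (!is.numeric(value)) {
    validation_error(sprintf("%s: non-numeric measurement", table$parameter))
  }
  x <- round_half_up(value, table$digits)
  ok <- is.na(x) | (x >= table$plausible[1] & x <= table$plausible[2])
  if (!all(ok)) {
    bad <- value[!ok][1]
    validation_error(sprintf(
      "%s value %s outside plausible range [%s, %s]",
      table$parameter, format(bad), table$plausible[1], table$plausible[2]
    ))
  }
  out <- rep(NA_integer_, length(x))
  idx <- findInterval(x, table$bands$lo)
  valid <- !is.na(x)
  out[valid] <- as.integer(table$bands$score[idx[valid]])
  out
}

.consciousness_map <- c(
  alert = 0L,
  confused = 1L, agitated = 1L, confused_agitated = 1L,
  voice = 2L,
  pain = 3L, unresponsive = 3L, pain_unresponsive = 3L, pain_unconscious = 3L
)

#' Score the consciousness level
#'
#' Maps the instrument's four-level consciousness scale (an AVPU scale with
#' an added confused/agitated level) to its sub-score: alert scores 0,
#' confused/agitated 1, responds to voice 2, responds only to pain or
#' unresponsive 3. Tokens are case-insensitive; `confused` and `agitated`
#' are synonymous, as are `pain` and `unresponsive`.
#'
#' @param level character vector of consciousness tokens.
#' @return integer vector of sub-scores (`NA` in gives `NA` out).
#' @examples
#' score_consciousness(c("alert", "Confused/agitated", "voice", "PAIN"))
#' @export
score_consciousness <- function(level) {
  if (!is.character(level) && !is.factor(level)) {
    validation_error("consciousness: expected character levels")
  }
  tok <- tolower(trimws(as.character(level)))
  tok <- gsub("[ /]+", "_", tok)
  out <- .consciousness_map[tok]
  bad <- !is.na(tok) & is.na(out)
  if (any(bad)) {
    validation_error(sprintf(
      "consciousness: unknown level '%s'; accepted tokens: %s",
      level[bad][1], paste(unique(names(.consciousness_map)), collapse = ", ")
    ))
  }
  unname(out)
}
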