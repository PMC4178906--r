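#' Percentage with half-up rounding
#'
#' `100 * count / total`, rounded half-up to one decimal - the display
#' convention used for cohort characteristic tables.
#'
#' @param count non-negative integer numerator.
#' @param total positive integer denominator, `count <= total`.
#' @return percentage rounded to one decimal.
#' @examples
#' percentage(2157, 2305)  # 93.6
#' @export
percentage <- function(count, total) {
  if (any(total == 0)) validation_error("percentage: total must be positive")
  if (any(count < 0 | count > total)) {
    validation_error("percentage: count must be in [0, total]")
  }
  round_half_up(100 * count / total, 1)
}

#' Descriptive cohort summary
#'
#' Counts and percentages of the social risk factors and of the
#' gold-standard disposition (when labels are present), together with means
#' and sample standard deviations (n - 1 denominator) of age and of the
#' physiological, social and total scores - the structure of a standard
#' cohort characteristics table.
#'
#' @param scored a scored cohort from [score_cohort()] (the gold-standard
#'   `needs_ems` column is optional).
#' @return an object of class `pmews_cohort_summary`: `n_total`, a `counts`
#'   data frame (`characteristic`, `n`, `pct`) and a `moments` data frame
#'   (`measure`, `mean`, `sd`), all at full precision; the print method
#'   rounds half-up to 1 decimal (percentages) and 2 decimals (means/SDs).
#' @export
describe_cohort <- function(scored) {
  if (!is.data.frame(scored) || nrow(scored) == 0) {
    validation_error("empty cohort")
  }
  need <- c("age_years", "socially_isolated", "chronic_disease",
            "physiological_score", "social_score", "total_pmews")
  absent <- setdiff(need, names(scored))
  if (length(absent) > 0) {
    validation_error(sprintf(
      "describe_cohort: expected a scored cohort; missing column(s): %s",
      paste(absent, collapse = ", ")
    ))
  }
  n <- nrow(scored)
  counts <- data.frame(
    characteristic = c("age > 65", "social isolation", "chronic disease"),
    n = c(sum(scored$age_years > 65),
          sum(scored$socially_isolated > 0),
          sum(scored$chronic_disease > 0)),
    stringsAsFactors = FALSE
  )
  if ("needs_ems" %in% names(scored) && !all(is.na(scored$needs_ems))) {
    counts <- rbind(counts, data.frame(
      characteristic = c("needed EMS response", "did not need EMS response"),
      n = c(sum(scored$needs_ems == 1), sum(scored$needs_ems == 0))
    ))
  }
  counts$pct <- percentage(counts$n, n)
  moments <- data.frame(
    measure = c("age (years)", "physiological score", "social score",
                "total PMEWS"),
    mean = c(mean(scored$age_years), mean(scored$physiological_score),
             mean(scored$social_score), mean(scored$total_pmews)),
    sd = c(stats::sd(scored$age_years), stats::sd(scored$physiological_score),
           stats::sd(scored$social_score), stats::sd(scored$total_pmews)),
    stringsAsFactors = FALSE
  )
  structure(list(n_total = n, counts = counts, moments = moments),
            class = "pmews_cohort_summary")
}

#' @export
format.pmews_cohort_summary <- function(x, ...) {
  c(
    sprintf("Cohort summary (n = %d)", x$n_total),
    sprintf("  %-28s %6s %6s", "characteristic", "n", "%"),
    sprintf("  %-28s %6d %6.1f", x$counts$characteristic, x$counts$n,
            x$counts$pct),
    sprintf("  %-28s %6s %6s", "measure", "mean", "sd"),
    sprintf("  %-28s %6.2f %6.2f", x$moments$measure,
            round_half_up(x$moments$mean, 2), round_half_up(x$moments$sd, 2))
  )
}

#' @export
print.pmews_cohort_summary <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param x a `pmews_cohort_summary` from [describe_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
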