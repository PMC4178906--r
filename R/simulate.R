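# Latent-severity synthetic cohort generator.
#
# Generative model: the gold-standard label is drawn first
# (Bernoulli(prevalence)), then a latent illness severity z. Negatives draw
# z ~ Normal(mu0, sigma0). Positives are a two-component mixture: with
# probability q2 a clearly-critical mode Normal(mu2, sigma2), otherwise a
# mildly-shifted bulk Normal(mu1, sigma1) - patients judged to need an EMS
# response without being physiologically extreme. q2 = 0 recovers a single
# class-conditional normal. Every observable measurement then derives
# from z:
#  * each banded physiological parameter picks a severity *level* (its
#    eventual sub-score) through a cumulative-logit link
#    P(level >= k | z) = plogis(slope * (z - thresholds[k])), then a side
#    (low/high) where the instrument has abnormal bands on both sides, then
#    a raw value uniformly on the band's measurement grid (open-ended bands
#    truncated at documented physiological caps);
#  * social isolation and chronic disease are Bernoulli with logistic links
#    on z; performance status uses a cumulative-logit link;
#  * age is Normal(mean + slope * z, sd) truncated to [min, max].
# Labels therefore influence measurements only through z, and the scorer is
# genuinely exercised: the generator emits raw measurements, never scores.

#' Construct a generator configuration
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' Defaults are an uncalibrated but plausible starting point; the shipped
#' calibrated configuration is returned by [reference_config()].
#'
#' @param prevalence probability a patient needs EMS, in (0, 1).
#' @param latent list `mu0`, `sigma0` (negatives' latent severity mean/SD),
#'   `mu1`, `sigma1` (the non-critical bulk of the positive class) and
#'   optionally `mu2`, `sigma2`, `q2`: with probability `q2` a positive
#'   patient comes from a clearly-critical mode `Normal(mu2, sigma2)`
#'   instead of the bulk. Defaults to `q2 = 0` (a single normal per class)
#'   when the mixture fields are absent.
#' @param physio named list (one entry per physiological parameter,
#'   including `consciousness`) of `slope`, `thresholds` (increasing, one
#'   per non-zero level) and, for parameters with two abnormal sides,
#'   `low_side_prob`.
#' @param social list with `isolation` and `chronic` (`intercept`, `slope`
#'   on the log-odds scale) and `performance` (`slope`, 4 increasing
#'   `thresholds`).
#' @param age list `mean`, `slope`, `sd`, `min`, `max` of the truncated
#'   normal age model.
#' @param caps named list of `c(lower, upper)` sampling caps for the
#'   open-ended bands of each vital sign.
#' @param seed default seed used by [simulate_cohort()] when none is given.
#' @return an object of class `pmews_generator_config`.
#' @export
generator_config <- function(prevalence = 0.684,
                             latent = list(mu0 = 0, sigma0 = 1,
                                           mu1 = 0.7, sigma1 = 1.1,
                                           mu2 = 3.2, sigma2 = 0.8,
                                           q2 = 0.3),
                             physio = default_physio_links(),
                             social = list(
                               isolation = list(intercept = -2.2, slope = 0.3),
                               chronic = list(intercept = -1.4, slope = 0.35),
                               performance = list(slope = 0.8,
                                                  thresholds = c(2.5, 3.3, 4.1, 4.9))
                             ),
                             age = list(mean = 47, slope = 3, sd = 21,
                                        min = 12, max = 100),
                             caps = list(
                               respiratory_rate = c(2, 60),
                               spo2 = c(60, 100),
                               heart_rate = c(20, 200),
                               systolic_bp = c(40, 250),
                               temperature = c(30, 42)
                             ),
                             seed = NULL) {
  cfg <- structure(
    list(version = "1.0", prevalence = prevalence, latent = latent,
         physio = physio, social = social, age = age, caps = caps,
         seed = seed),
    class = "pmews_generator_config"
  )
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @export
default_physio_links <- function() {
  list(
    respiratory_rate = list(slope = 1.2, thresholds = c(2.6, 3.6, 4.6),
                            low_side_prob = 0.15),
    spo2 = list(slope = 1.2, thresholds = c(2.8, 3.8, 4.8)),
    heart_rate = list(slope = 1.2, thresholds = c(2.4, 3.4, 4.4),
                      low_side_prob = 0.15),
    systolic_bp = list(slope = 1.2, thresholds = c(2.8, 3.8, 4.8)),
    temperature = list(slope = 1.2, thresholds = c(3.0, 4.0),
                       low_side_prob = 0.25),
    consciousness = list(slope = 1.2, thresholds = c(3.0, 4.0, 5.0))
  )
}

#' Validate a generator configuration
#'
#' @param config a `pmews_generator_config`.
#' @param tables band tables the simulated vitals must be scorable with.
#' @return `config`, invisibly, on success; a configuration error otherwise.
#' @export
validate_generator_config <- function(config, tables = pmews_band_tables()) {
  cc <- function(ok, msg) if (!ok) config_error(paste("generator config:", msg))
  cc(is.numeric(config$prevalence) && config$prevalence > 0 &&
       config$prevalence < 1, "prevalence must be in (0, 1)")
  lat <- config$latent
  cc(all(c("mu0", "sigma0", "mu1", "sigma1") %in% names(lat)),
     "latent must define mu0, sigma0, mu1, sigma1")
  cc(lat$sigma0 > 0 && lat$sigma1 > 0, "latent sigmas must be positive")
  q2 <- lat$q2 %||% 0
  cc(is.numeric(q2) && q2 >= 0 && q2 < 1, "latent q2 must be in [0, 1)")
  if (q2 > 0) {
    cc(!is.null(lat$mu2) && !is.null(lat$sigma2) && lat$sigma2 > 0,
       "latent mixture needs mu2 and sigma2 > 0 when q2 > 0")
  }
  need <- c(names(.band_for_col_sim()), "consciousness")
  cc(all(need %in% names(config$physio)),
     paste("physio links required for:", paste(need, collapse = ", ")))
  klev <- c(respiratory_rate = 3, spo2 = 3, heart_rate = 3, systolic_bp = 3,
            temperature = 2, consciousness = 3)
  for (p in need) {
    lk <- config$physio[[p]]
    cc(is.numeric(lk$slope) && length(lk$slope) == 1,
       sprintf("%s: scalar slope required", p))
    cc(length(lk$thresholds) == klev[[p]] &&
         all(diff(lk$thresholds) > 0 | klev[[p]] == 1),
       sprintf("%s: %d strictly increasing thresholds required", p, klev[[p]]))
  }
  for (f in c("isolation", "chronic")) {
    cc(all(c("intercept", "slope") %in% names(config$social[[f]])),
       sprintf("social$%s needs intercept and slope", f))
  }
  perf <- config$social$performance
  cc(length(perf$thresholds) == 4 && all(diff(perf$thresholds) > 0),
     "performance needs 4 strictly increasing thresholds")
  ag <- config$age
  cc(ag$sd > 0 && ag$min < ag$max, "age model needs sd > 0 and min < max")
  # caps must leave every score level a non-empty sampling interval
  for (p in names(.band_for_col_sim())) {
    tb <- tables[[.band_for_col_sim()[[p]]]]
    cap <- config$caps[[p]]
    cc(!is.null(cap) && length(cap) == 2 && cap[1] < cap[2],
       sprintf("caps$%s must be c(lower, upper)", p))
    iv <- level_intervals(tb, cap)
    for (k in seq_along(iv)) {
      cc(length(iv[[k]]) > 0,
         sprintf("caps$%s leave no sampleable interval for level %d", p, k - 1))
    }
  }
  invisible(config)
}

# band-table name per generator parameter (temperature column is
# temperature_c in the CSV schema; the generator indexes by table name)
.band_for_col_sim <- function() {
  c(respiratory_rate = "respiratory_rate", spo2 = "spo2",
    heart_rate = "heart_rate", systolic_bp = "systolic_bp",
    temperature = "temperature")
}

# For one band table: list (by level 0..max_score) of sampling intervals,
# each a matrix row c(lo, hi) on the measurement grid, clipped to caps.
level_intervals <- function(tbl, cap) {
  lapply(0:tbl$max_score, function(k) {
    rows <- which(tbl$bands$score == k)
    out <- list()
    for (r in rows) {
      lo <- max(tbl$bands$lo[r], cap[1])
      hi <- min(tbl$bands$hi[r], cap[2])
      if (lo <= hi) out[[length(out) + 1]] <- c(lo, hi)
    }
    out
  })
}

# inverse-CDF ordinal draw: P(level >= k | z) = plogis(slope * (z - thr[k]))
sample_ordinal <- function(z, slope, thresholds) {
  u <- stats::runif(length(z))
  lev <- integer(length(z))
  for (k in seq_along(thresholds)) {
    lev <- lev + as.integer(u < stats::plogis(slope * (z - thresholds[k])))
  }
  lev
}

# uniform draw on the measurement grid of an interval; u in [0,1)
grid_draw <- function(lo, hi, u, step, digits) {
  ngrid <- round((hi - lo) / step) + 1
  idx <- pmin(floor(u * ngrid), ngrid - 1)
  round_half_up(lo + idx * step, digits)
}

#' Simulate a labeled synthetic cohort
#'
#' Draws `n` patient records from the latent-severity model described in
#' [generator_config()]. Output is in the patient CSV schema (raw
#' measurements plus the `needs_ems` label) and always passes
#' [validate_patients()]. The draw is fully reproducible: identical
#' `(config, n, seed)` give identical cohorts.
#'
#' @param config a `pmews_generator_config`.
#' @param n number of patients (>= 1).
#' @param seed integer seed; defaults to `config$seed`.
#' @param tables band tables used to locate the sampling intervals.
#' @return data frame of `n` patient records with `needs_ems` labels.
#' @examples
#' cohort <- simulate_cohort(generator_config(), n = 50, seed = 1)
#' head(cohort)
#' @export
simulate_cohort <- function(config, n, seed = config$seed,
                            tables = pmews_band_tables()) {
  validate_generator_config(config, tables)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != round(n)) {
    validation_error("n must be a positive integer")
  }
  if (is.null(seed)) validation_error("a seed is required (argument or config$seed)")
  n <- as.integer(n)
  with_seed(as.integer(seed), simulate_cohort_impl(config, n, tables))
}

simulate_cohort_impl <- function(config, n, tables) {
  lat <- config$latent
  y <- as.integer(stats::runif(n) < config$prevalence)
  # the mixture draw is taken for every patient so the RNG stream does not
  # depend on parameter values (common random numbers during calibration)
  crit <- stats::runif(n) < (lat$q2 %||% 0) & y == 1
  mu <- ifelse(crit, lat$mu2 %||% 0, ifelse(y == 1, lat$mu1, lat$mu0))
  sd_ <- ifelse(crit, lat$sigma2 %||% 1,
                ifelse(y == 1, lat$sigma1, lat$sigma0))
  z <- stats::rnorm(n, mean = mu, sd = sd_)
  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
  # RNG draws happen in a fixed order and fixed count regardless of
  # parameter values, so a common seed acts as common random numbers
  # across configurations during calibration.
  for (p in names(.band_for_col_sim())) {
    tb <- tables[[.band_for_col_sim()[[p]]]]
    lk <- config$physio[[p]]
    iv <- level_intervals(tb, config$caps[[p]])
    lev <- sample_ordinal(z, lk$slope, lk$thresholds)
    u_side <- stats::runif(n)
    u_val <- stats::runif(n)
    val <- numeric(n)
    for (k in 0:tb$max_score) {
      sel <- which(lev == k)
      if (length(sel) == 0) next
      ints <- iv[[k + 1]]
      if (length(ints) == 1) {
        val[sel] <- grid_draw(ints[[1]][1], ints[[1]][2], u_val[sel],
                              tb$step, tb$digits)
      } else {
        low <- u_side[sel] < (lk$low_side_prob %||% 0.5)
        val[sel[low]] <- grid_draw(ints[[1]][1], ints[[1]][2],
                                   u_val[sel[low]], tb$step, tb$digits)
        val[sel[!low]] <- grid_draw(ints[[2]][1], ints[[2]][2],
                                    u_val[sel[!low]], tb$step, tb$digits)
      }
    }
    col <- if (p == "temperature") "temperature_c" else p
    out[[col]] <- val
  }
  neuro <- config$physio$consciousness
  lev <- sample_ordinal(z, neuro$slope, neuro$thresholds)
  out$consciousness <- c("alert", "confused", "voice", "pain")[lev + 1]
  iso <- config$social$isolation
  chr <- config$social$chronic
  out$socially_isolated <- as.integer(
    stats::runif(n) < stats::plogis(iso$intercept + iso$slope * z))
  out$chronic_disease <- as.integer(
    stats::runif(n) < stats::plogis(chr$intercept + chr$slope * z))
  perf <- config$social$performance
  out$performance_status <- sample_ordinal(z, perf$slope, perf$thresholds)
  ag <- config$age
  mu <- ag$mean + ag$slope * z
  plo <- stats::pnorm(ag$min, mu, ag$sd)
  phi <- stats::pnorm(ag$max, mu, ag$sd)
  u <- stats::runif(n)
  age <- stats::qnorm(plo + u * (phi - plo), mu, ag$sd)
  # inverse-CDF truncation degenerates to +/-Inf when the conditional mean
  # sits many SDs outside [min, max]; clamp to the truncation bounds
  out$age_years <- round_half_up(pmin(pmax(age, ag$min), ag$max), 0)
  out$needs_ems <- y
  out[, c("patient_id", "respiratory_rate", "spo2", "heart_rate",
          "systolic_bp", "temperature_c", "consciousness", "age_years",
          "socially_isolated", "chronic_disease", "performance_status",
          "needs_ems")]
}

#' Read / write generator configurations
#'
#' Generator configurations serialize as JSON so the calibrated instrument
#' settings are auditable and swappable.
#'
#' @param path file path.
#' @return `read_generator_config()`: a validated
#'   `pmews_generator_config`; `write_generator_config()`: `path`,
#'   invisibly.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("generator config file not found: %s", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$caps <- lapply(raw$caps, as.numeric)
  cfg <- structure(raw, class = "pmews_generator_config")
  validate_generator_config(cfg)
}

#' @rdname read_generator_config
#' @param config a `pmews_generator_config`.
#' @export
write_generator_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' The shipped calibrated generator configuration
#'
#' Returns the generator configuration distributed with the package, frozen
#' after calibrating against [default_constraints()] (with the three
#' characteristic-rate constraints down-weighted; see the methods vignette
#' for why the published constraint set is not jointly attainable). The
#' calibration report is attached as the `"calibration"` attribute.
#'
#' This configuration is one member of the family of generators consistent
#' with the published summary constraints - the underlying patient-level
#' distributions are not published, so distributional choices beyond the
#' constraints are modelling assumptions.
#'
#' @return a `pmews_generator_config`.
#' @export
reference_config <- function() {
  path <- system.file("extdata", "pmews_reference_config.json",
                      package = "pmews")
  if (path == "") {
    config_error(paste(
      "reference generator config not found;",
      "run calibrate_generator(default_constraints(), generator_config(), ...)",
      "and save the result with write_generator_config()"
    ))
  }
  cfg <- read_generator_config(path)
  rpt <- system.file("extdata", "pmews_reference_calibration.json",
                     package = "pmews")
  if (rpt != "") {
    attr(cfg, "calibration") <- jsonlite::read_json(rpt, simplifyVector = TRUE)
  }
  cfg
}
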