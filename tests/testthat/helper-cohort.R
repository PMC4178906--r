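# Random valid patient records spanning the full admissible measurement
# space (including fractional values that exercise the rounding rule and
# synonym/case variants of the consciousness tokens).
random_records <- function(n, seed) {
  with_seed_helper(seed, {
    data.frame(
      patient_id = sprintf("R%04d", seq_len(n)),
      respiratory_rate = runif(n, 0, 80),
      spo2 = runif(n, 0, 100),
      heart_rate = runif(n, 0, 250),
      systolic_bp = runif(n, 0, 300),
      temperature_c = runif(n, 25, 45),
      consciousness = sample(c("alert", "ALERT", "confused", "Agitated",
                               "confused/agitated", "voice", "Voice", "pain",
                               "unresponsive", "Pain unconscious"),
                             n, replace = TRUE),
      age_years = runif(n, 0, 100),
      socially_isolated = rbinom(n, 1, 0.2),
      chronic_disease = rbinom(n, 1, 0.4),
      performance_status = sample(0:4, n, replace = TRUE),
      needs_ems = rbinom(n, 1, 0.6),
      stringsAsFactors = FALSE
    )
  })
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# O(n^2) brute-force AUROC oracle: pair counting with half credit for ties.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# A single all-normal patient record (every parameter in its zero band).
normal_record <- function(id = "N1") {
  data.frame(
    patient_id = id, respiratory_rate = 14, spo2 = 98, heart_rate = 80,
    systolic_bp = 120, temperature_c = 37.0, consciousness = "alert",
    age_years = 30, socially_isolated = 0, chronic_disease = 0,
    performance_status = 0, stringsAsFactors = FALSE
  )
}
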