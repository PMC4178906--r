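test_that("simulation is seed-deterministic and validates its own output", {
  cfg <- generator_config()
  a <- simulate_cohort(cfg, 500, seed = 11)
  b <- simulate_cohort(cfg, 500, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, 500, seed = 12)))
  expect_silent(validate_patients(a))
  # full pipeline reproducibility
  s1 <- score_cohort(a)
  s2 <- score_cohort(simulate_cohort(cfg, 500, seed = 11))
  expect_identical(s1, s2)
})

test_that("simulated records stay valid across varied configurations", {
  for (seed in 1:5) {
    cfg <- with_seed_helper(seed + 500, generator_config(
      prevalence = runif(1, 0.2, 0.9),
      latent = list(mu0 = 0, sigma0 = 1, mu1 = runif(1, 0.3, 2.5),
                    sigma1 = runif(1, 0.5, 3))
    ))
    co <- simulate_cohort(cfg, 300, seed = seed)
    expect_silent(validate_patients(co))
    expect_equal(nrow(co), 300)
    expect_true(all(co$needs_ems %in% 0:1))
  }
})

test_that("simulation rejects invalid sizes and configs before sampling", {
  cfg <- generator_config()
  expect_error(simulate_cohort(cfg, 0, seed = 1), class = "pmews_validation_error")
  expect_error(simulate_cohort(cfg, 10), "seed",
               class = "pmews_validation_error")
  expect_error(generator_config(prevalence = 1.2), "prevalence",
               class = "pmews_config_error")
  expect_error(generator_config(latent = list(mu0 = 0, sigma0 = -1,
                                              mu1 = 1, sigma1 = 1)),
               "sigma", class = "pmews_config_error")
  bad_caps <- generator_config()$caps
  bad_caps$spo2 <- c(98, 100)  # no sampleable interval for levels 1-3
  expect_error(generator_config(caps = bad_caps), "spo2",
               class = "pmews_config_error")
})

test_that("empirical label rate concentrates on the configured prevalence", {
  cfg <- generator_config(prevalence = 0.684)
  co <- simulate_cohort(cfg, 100000, seed = 31)
  expect_lt(abs(mean(co$needs_ems) - 0.684), 0.005)
})

test_that("zero severity slopes remove all signal (AUROC ~ 0.5, no leakage)", {
  cfg <- generator_config()
  for (p in names(cfg$physio)) cfg$physio[[p]]$slope <- 0
  cfg$social$isolation$slope <- 0
  cfg$social$chronic$slope <- 0
  cfg$social$performance$slope <- 0
  cfg$age$slope <- 0
  scored <- score_cohort(simulate_cohort(cfg, 10000, seed = 17))
  expect_lt(abs(auroc(scored$total_pmews, scored$needs_ems) - 0.5), 0.02)
  # conditional-independence smoke test: labels uncorrelated with raw
  # measurements when nothing loads on severity
  for (cl in c("respiratory_rate", "heart_rate", "systolic_bp", "age_years")) {
    expect_lt(abs(cor(scored[[cl]], scored$needs_ems)), 0.03)
  }
})

test_that("raising severity slopes never lowers the simulated AUROC", {
  base <- generator_config()
  auc_at <- function(mult) {
    cfg <- base
    for (p in names(cfg$physio)) cfg$physio[[p]]$slope <-
      cfg$physio[[p]]$slope * mult
    cfg$social$isolation$slope <- cfg$social$isolation$slope * mult
    cfg$social$chronic$slope <- cfg$social$chronic$slope * mult
    cfg$social$performance$slope <- cfg$social$performance$slope * mult
    scored <- score_cohort(simulate_cohort(cfg, 10000, seed = 23))
    auroc(scored$total_pmews, scored$needs_ems)
  }
  # below saturation, more severity loading means more discrimination;
  # once links are near-deterministic given z only tie structure changes,
  # so the ladder stops short of that regime
  ladder <- vapply(c(0, 0.25, 0.5, 1), auc_at, 0)
  expect_true(all(diff(ladder) > -0.005))  # non-decreasing up to MC jitter
})

test_that("generator configs survive a JSON round trip", {
  cfg <- generator_config()
  f <- tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_identical(simulate_cohort(cfg, 100, seed = 3),
                   simulate_cohort(back, 100, seed = 3))
})

test_that("the shipped reference config loads with its calibration report", {
  cfg <- reference_config()
  expect_s3_class(cfg, "pmews_generator_config")
  expect_false(is.null(attr(cfg, "calibration")))
  co <- simulate_cohort(cfg, 200, seed = 1)
  expect_silent(validate_patients(co))
})
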