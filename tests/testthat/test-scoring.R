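test_that("worked vignette patients score as on the printed form", {
  rec <- rbind(
    normal_record("P1"),
    data.frame(patient_id = "P2", respiratory_rate = 35, spo2 = 85,
               heart_rate = 140, systolic_bp = 65, temperature_c = 39.5,
               consciousness = "pain", age_years = 70, socially_isolated = 1,
               chronic_disease = 1, performance_status = 4),
    data.frame(patient_id = "P3", respiratory_rate = 20, spo2 = 92,
               heart_rate = 105, systolic_bp = 95, temperature_c = 38.2,
               consciousness = "confused", age_years = 65,
               socially_isolated = 0, chronic_disease = 1,
               performance_status = 2)
  )
  s <- score_cohort(rec)
  expect_identical(s$physiological_score, c(0L, 17L, 7L))
  expect_identical(s$social_score, c(0L, 7L, 3L))
  expect_identical(s$total_pmews, c(0L, 24L, 10L))
})

test_that("scores are additive, bounded, and deterministic on random records", {
  rec <- random_records(400, seed = 42)
  s1 <- score_cohort(rec)
  s2 <- score_cohort(rec)
  expect_identical(s1, s2)
  sub_cols <- paste0("score_", c("respiratory_rate", "spo2", "heart_rate",
                                 "systolic_bp", "temperature_c",
                                 "consciousness"))
  expect_identical(s1$physiological_score,
                   as.integer(rowSums(s1[, sub_cols])))
  expect_identical(s1$total_pmews, s1$physiological_score + s1$social_score)
  expect_true(all(s1$physiological_score >= 0 & s1$physiological_score <= 17))
  expect_true(all(s1$social_score >= 0 & s1$social_score <= 7))
  expect_true(all(s1$total_pmews >= 0 & s1$total_pmews <= 24))
})

test_that("the age > 65 criterion is a strict inequality", {
  rec <- normal_record()
  rec$age_years <- 65
  expect_identical(score_cohort(rec)$social_score, 0L)
  rec$age_years <- 66
  expect_identical(score_cohort(rec)$social_score, 1L)
})

test_that("missing physiological data errors by default, scores 0 on opt-in", {
  rec <- rbind(normal_record("A"), normal_record("B"))
  rec$spo2[2] <- NA
  expect_error(score_cohort(rec), "missing",
               class = "pmews_validation_error")
  expect_message(s <- score_cohort(rec, missing = "zero"), "B")
  expect_identical(s$physiological_score, c(0L, 0L))
  # missing social data is an error under either policy
  rec$spo2[2] <- 98
  rec$performance_status[1] <- NA
  expect_error(score_cohort(rec, missing = "zero"),
               class = "pmews_validation_error")
})

test_that("validation failures carry the patient and the offending value", {
  rec <- rbind(normal_record("OK1"), normal_record("BAD"))
  rec$systolic_bp[2] <- 400
  expect_error(score_cohort(rec), "BAD.*systolic_bp.*400",
               class = "pmews_validation_error")
  rec2 <- rbind(normal_record("X"), normal_record("X"))
  expect_error(score_cohort(rec2), "duplicate",
               class = "pmews_validation_error")
  rec3 <- normal_record()
  rec3$performance_status <- 5
  expect_error(score_cohort(rec3), "performance_status",
               class = "pmews_validation_error")
})

test_that("patient CSV round-trips and scores identically", {
  rec <- random_records(50, seed = 7)
  f <- tempfile(fileext = ".csv")
  write_patient_csv(rec, f)
  back <- read_patient_csv(f)
  expect_identical(score_cohort(back)$total_pmews, score_cohort(rec)$total_pmews)
  # missing required column is named in the error
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(rec[, setdiff(names(rec), "heart_rate")], f2,
                   row.names = FALSE)
  expect_error(read_patient_csv(f2), "heart_rate",
               class = "pmews_validation_error")
})
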