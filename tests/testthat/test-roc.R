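test_that("roc_points reproduces hand-counted operating points", {
  pts <- roc_points(c(0, 1, 2, 3), c(0, 0, 1, 1))
  at <- function(t) pts[pts$threshold == t, ]
  expect_equal(at(2)$sensitivity, 1)
  expect_equal(at(2)$specificity, 1)
  expect_equal(at(-1)$sensitivity, 1)  # everyone flagged
  expect_equal(at(-1)$specificity, 0)
  expect_equal(at(4)$sensitivity, 0)
  expect_equal(at(4)$specificity, 1)
  pts2 <- roc_points(c(1, 1, 2, 2), c(0, 1, 0, 1))
  expect_equal(pts2[pts2$threshold == 2, ]$sensitivity, 0.5)
  expect_equal(pts2[pts2$threshold == 2, ]$specificity, 0.5)
})

test_that("roc endpoints are always (1,0) and (0,1), sensitivity monotone", {
  for (seed in 1:5) {
    rec <- with_seed_helper(seed, data.frame(
      s = sample(0:10, 60, replace = TRUE), l = rbinom(60, 1, 0.5)))
    pts <- roc_points(rec$s, rec$l)
    expect_equal(pts$sensitivity[1], 1)
    expect_equal(pts$specificity[1], 0)
    expect_equal(pts$sensitivity[nrow(pts)], 0)
    expect_equal(pts$specificity[nrow(pts)], 1)
    expect_true(all(diff(pts$sensitivity) <= 0))
    expect_true(all(diff(pts$specificity) >= 0))
  }
})

test_that("auroc equals brute-force pair counting on random small cohorts", {
  n_match <- 0
  for (seed in 1:1000) {
    d <- with_seed_helper(seed, {
      n <- sample(4:50, 1)
      list(s = sample(0:12, n, replace = TRUE),
           l = c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8))))
    })
    a <- auroc(d$s, d$l)
    expect_equal(a, auroc_brute(d$s, d$l), tolerance = 1e-12)
    n_match <- n_match + 1
  }
  expect_equal(n_match, 1000)
})

test_that("auroc matches its worked examples and invariances", {
  expect_equal(auroc(c(0, 1, 2, 3), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(3, 2, 1, 0), c(0, 0, 1, 1)), 0)
  expect_equal(auroc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  d <- with_seed_helper(9, list(s = sample(0:20, 200, replace = TRUE),
                                l = rbinom(200, 1, 0.5)))
  # invariant under strictly increasing transforms of the score
  expect_equal(auroc(d$s, d$l), auroc(d$s^3, d$l))
  expect_equal(auroc(d$s, d$l), auroc(2 * d$s + 5, d$l))
  # complement symmetry
  expect_equal(auroc(d$s, d$l) + auroc(d$s, 1 - d$l), 1)
  expect_error(auroc(c(1, 2), c(1, 1)), "degenerate cohort",
               class = "pmews_validation_error")
})

test_that("auroc and the trapezoidal area under roc_points agree", {
  d <- with_seed_helper(21, list(s = sample(0:15, 300, replace = TRUE),
                                 l = rbinom(300, 1, 0.6)))
  pts <- roc_points(d$s, d$l)
  fpr <- 1 - pts$specificity
  tpr <- pts$sensitivity
  o <- order(fpr, tpr)
  trap <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  expect_equal(auroc(d$s, d$l), trap, tolerance = 1e-12)
})

test_that("DeLong agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 14)) {
    d <- with_seed_helper(seed, list(
      s = sample(0:20, 400, replace = TRUE),
      l = rbinom(400, 1, 0.6)))
    d$s <- d$s + 5 * d$l  # give the score some signal
    ci <- auroc_ci(d$s, d$l, method = "delong")
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(d$l, d$s,
                                                   direction = "<",
                                                   quiet = TRUE)))
    expect_equal(auroc(d$s, d$l), as.numeric(pROC::auc(pROC::roc(
      d$l, d$s, direction = "<", quiet = TRUE))), tolerance = 1e-12)
    expect_equal(ci[1], ref[1], tolerance = 1e-9)
    expect_equal(ci[2], ref[3], tolerance = 1e-9)
  }
})

test_that("DeLong and a 10,000-replicate bootstrap agree on a 500-patient cohort", {
  cohort <- simulate_cohort(generator_config(), 500, seed = 5)
  scored <- score_cohort(cohort)
  dl <- auroc_ci(scored$total_pmews, scored$needs_ems, "delong")
  bs <- auroc_ci(scored$total_pmews, scored$needs_ems, "bootstrap",
                 boot_reps = 10000, seed = 99)
  expect_lt(abs(dl[1] - bs[1]), 0.01)
  expect_lt(abs(dl[2] - bs[2]), 0.01)
})

test_that("degenerate-but-valid CI inputs behave", {
  # a single positive: no crash, a valid interval
  s <- c(9, with_seed_helper(2, sample(0:6, 40, replace = TRUE)))
  l <- c(1, rep(0, 40))
  ci <- auroc_ci(s, l, "delong")
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= ci[2])
  expect_warning(auroc_ci(s, l, "bootstrap", boot_reps = 50, seed = 1),
                 "unreliable")
})

test_that("confusion_at_cutoff counts check against hand tallies", {
  cm <- confusion_at_cutoff(c(5, 5, 3, 3), c(1, 0, 1, 0), 4)
  expect_equal(cm[, c("tp", "fp", "tn", "fn")],
               data.frame(tp = 1L, fp = 1L, tn = 1L, fn = 1L),
               ignore_attr = TRUE)
  expect_equal(cm$ppv, 0.5)
  perfect <- confusion_at_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), 2)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  low <- confusion_at_cutoff(c(2, 3, 4), c(0, 1, 1), 2)
  expect_equal(low$sensitivity, 1)
  expect_warning(confusion_at_cutoff(c(2, 3, 4), c(0, 1, 1), 9), "outside")
})

test_that("cutoff counts are consistent with the roc curve and the cohort", {
  d <- with_seed_helper(31, list(s = sample(0:24, 500, replace = TRUE),
                                 l = rbinom(500, 1, 0.68)))
  pts <- roc_points(d$s, d$l)
  for (k in c(0, 4, 10, 20)) {
    cm <- suppressWarnings(confusion_at_cutoff(d$s, d$l, k))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 500)
    expect_equal(cm$tp + cm$fn, sum(d$l == 1))
    expect_equal(cm$sensitivity, pts$sensitivity[pts$threshold == k])
    expect_equal(cm$specificity, pts$specificity[pts$threshold == k])
  }
})

test_that("disposal_by_score partitions the cohort", {
  d <- list(s = c(0, 0, 1, 4, 4, 4, 10), l = c(0, 1, 0, 1, 1, 0, 1))
  tab <- disposal_by_score(d$s, d$l)
  expect_equal(sum(tab$n_patients), 7)
  expect_equal(sum(tab$n_needing_ems), sum(d$l))
  expect_equal(tab$proportion_needing_ems[tab$score == 10], 1)
  expect_equal(tab$proportion_needing_ems[tab$score == 1], 0)
  expect_false(2 %in% tab$score)  # empty levels omitted
})

test_that("youden cutoff equals exhaustive search, ties break high", {
  expect_equal(youden_cutoff(roc_points(c(0, 1, 2, 3), c(0, 0, 1, 1))), 2)
  # all-identical scores: J = 0 everywhere, highest threshold wins
  pts <- roc_points(c(4, 4, 4, 4), c(0, 1, 0, 1))
  expect_equal(youden_cutoff(pts), max(pts$threshold))
  for (seed in 1:20) {
    d <- with_seed_helper(seed + 100, list(
      s = sample(0:24, 200, replace = TRUE), l = rbinom(200, 1, 0.5)))
    pts <- roc_points(d$s, d$l)
    j <- vapply(pts$threshold, function(t) {
      cm <- suppressWarnings(confusion_at_cutoff(d$s, d$l, t))
      cm$sensitivity + cm$specificity - 1
    }, 0)
    best <- max(pts$threshold[j >= max(j) - 1e-12])
    expect_equal(youden_cutoff(pts), best)
  }
})
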