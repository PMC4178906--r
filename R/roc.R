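# Diagnostic evaluation of an integer score against a binary gold standard.
# Positivity convention throughout: a patient is *predicted positive*
# (flagged as needing EMS) when score >= threshold.

check_score_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    validation_error("scores and labels must have equal length")
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    validation_error("labels must be binary 0/1")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(scores) == 0) validation_error("no complete score/label pairs")
  if (!is.numeric(scores) || any(scores != round(scores))) {
    validation_error("scores must be integer-valued")
  }
  if (length(unique(labels)) < 2) {
    validation_error("degenerate cohort: labels contain a single class")
  }
  list(scores = as.numeric(scores), labels = as.integer(labels))
}

#' ROC points for an integer score
#'
#' Sweeps every integer threshold from `min(scores) - 1` to
#' `max(scores) + 1` under the "positive if score >= threshold" rule and
#' returns sensitivity and specificity at each. The sweep always includes
#' the trivial operating points (sensitivity 1, specificity 0) and
#' (sensitivity 0, specificity 1).
#'
#' @param scores integer-valued numeric vector.
#' @param labels binary gold-standard labels (0/1 or logical), 1 = positive.
#' @return data frame with columns `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  d <- check_score_labels(scores, labels)
  pos <- d$scores[d$labels == 1]
  neg <- d$scores[d$labels == 0]
  thr <- seq(min(d$scores) - 1, max(d$scores) + 1)
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), 0),
    specificity = vapply(thr, function(t) mean(neg < t), 0)
  )
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) identity: the proportion of
#' positive-negative pairs in which the positive patient has the higher
#' score, counting ties as one half. This equals the trapezoidal area under
#' the empirical ROC curve.
#'
#' @inheritParams roc_points
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(1, 2, 2, 3), c(0, 0, 1, 1))  # 0.875
#' @export
auroc <- function(scores, labels) {
  d <- check_score_labels(scores, labels)
  n1 <- sum(d$labels == 1)
  n0 <- sum(d$labels == 0)
  r <- rank(d$scores)
  (sum(r[d$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the AUROC
#'
#' `method = "delong"` (default) uses the DeLong variance estimate from the
#' pairwise placement components; `method = "bootstrap"` uses a stratified
#' percentile bootstrap (resampling positives and negatives separately so
#' each replicate keeps both classes).
#'
#' @inheritParams roc_points
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf confidence level (default 0.95).
#' @param boot_reps bootstrap replicates (default 2000); fewer than 100
#'   triggers a warning.
#' @param seed optional integer seed for the bootstrap (RNG state is
#'   restored afterwards).
#' @return numeric vector `c(low, high)`, truncated to \[0, 1\].
#' @export
auroc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                     conf = 0.95, boot_reps = 2000, seed = NULL) {
  method <- match.arg(method)
  d <- check_score_labels(scores, labels)
  if (method == "delong") {
    delong_ci(d$scores, d$labels, conf)
  } else {
    if (boot_reps < 100) {
      warning(sprintf("bootstrap with %d replicates is unreliable (< 100)",
                      boot_reps))
    }
    run <- function() boot_ci(d$scores, d$labels, conf, boot_reps)
    if (is.null(seed)) run() else with_seed(seed, run())
  }
}

delong_ci <- function(scores, labels, conf) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  rall <- rank(c(x, y))
  v10 <- (rall[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (rall[m + seq_len(n)] - rank(y)) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  half <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(s10 / m + s01 / n)
  c(max(0, auc - half), min(1, auc + half))
}

boot_ci <- function(scores, labels, conf, reps) {
  ipos <- which(labels == 1)
  ineg <- which(labels == 0)
  stat <- vapply(seq_len(reps), function(i) {
    s <- c(sample(scores[ipos], length(ipos), replace = TRUE),
           sample(scores[ineg], length(ineg), replace = TRUE))
    l <- c(rep(1L, length(ipos)), rep(0L, length(ineg)))
    auroc(s, l)
  }, 0)
  unname(stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Full ROC analysis of a score
#'
#' Bundles the ROC points, AUROC and its confidence interval into one
#' object.
#'
#' @inheritParams auroc_ci
#' @return an object of class `pmews_roc` with elements `points`, `auroc`,
#'   `ci_low`, `ci_high`, `ci_method`, `conf`, `n_positive`, `n_negative`.
#' @export
roc_analysis <- function(scores, labels, method = c("delong", "bootstrap"),
                         conf = 0.95, boot_reps = 2000, seed = NULL) {
  method <- match.arg(method)
  d <- check_score_labels(scores, labels)
  ci <- auroc_ci(d$scores, d$labels, method, conf, boot_reps, seed)
  structure(
    list(
      points = roc_points(d$scores, d$labels),
      auroc = auroc(d$scores, d$labels),
      ci_low = ci[1],
      ci_high = ci[2],
      ci_method = method,
      conf = conf,
      n_positive = sum(d$labels == 1),
      n_negative = sum(d$labels == 0)
    ),
    class = "pmews_roc"
  )
}

#' @export
print.pmews_roc <- function(x, ...) {
  cat(sprintf(
    "ROC analysis: AUROC %.3f (%.0f%% CI %.3f-%.3f, %s), %d positive / %d negative\n",
    x$auroc, 100 * x$conf, x$ci_low, x$ci_high, x$ci_method,
    x$n_positive, x$n_negative
  ))
  invisible(x)
}

#' Confusion-matrix performance at a cutoff
#'
#' Counts and diagnostic metrics under the "positive if score >= cutoff"
#' rule. PPV is the proportion of flagged patients whose gold-standard
#' label is positive; it is `NaN` when no patient is flagged.
#'
#' @inheritParams roc_points
#' @param cutoff integer decision threshold.
#' @return one-row data frame: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  d <- check_score_labels(scores, labels)
  if (cutoff < min(d$scores) || cutoff > max(d$scores)) {
    warning(sprintf("cutoff %s outside observed score range [%s, %s]",
                    cutoff, min(d$scores), max(d$scores)))
  }
  pred <- d$scores >= cutoff
  tp <- sum(pred & d$labels == 1)
  fp <- sum(pred & d$labels == 0)
  fn <- sum(!pred & d$labels == 1)
  tn <- sum(!pred & d$labels == 0)
  data.frame(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn)
  )
}

#' Sweep every integer cutoff
#'
#' @inheritParams roc_points
#' @param cutoffs integer cutoffs to evaluate; defaults to the observed
#'   score range extended by one on each side.
#' @return data frame with one [confusion_at_cutoff()] row per cutoff.
#' @export
cutoff_sweep <- function(scores, labels, cutoffs = NULL) {
  d <- check_score_labels(scores, labels)
  if (is.null(cutoffs)) {
    cutoffs <- seq(min(d$scores) - 1, max(d$scores) + 1)
  }
  do.call(rbind, lapply(cutoffs, function(k) {
    suppressWarnings(confusion_at_cutoff(d$scores, d$labels, k))
  }))
}

#' Score-by-disposal distribution
#'
#' For each observed score value, the number of patients, the number whose
#' gold-standard label is positive (needed EMS), and the proportion - the
#' tabular form of a score-versus-final-disposal bar chart. Score values
#' with no patients are omitted.
#'
#' @inheritParams roc_points
#' @return data frame with columns `score`, `n_patients`, `n_needing_ems`,
#'   `proportion_needing_ems`, sorted by score.
#' @export
disposal_by_score <- function(scores, labels) {
  d <- check_score_labels(scores, labels)
  agg <- stats::aggregate(d$labels, by = list(score = d$scores),
                          FUN = function(v) c(n = length(v), pos = sum(v)))
  out <- data.frame(
    score = agg$score,
    n_patients = agg$x[, "n"],
    n_needing_ems = agg$x[, "pos"]
  )
  out$proportion_needing_ems <- out$n_needing_ems / out$n_patients
  out[order(out$score), , drop = FALSE]
}

#' Youden-optimal cutoff
#'
#' The threshold maximising Youden's J = sensitivity + specificity - 1 over
#' the ROC points; ties are broken towards the *higher* (more specific)
#' cutoff, which flags fewer patients at equal J.
#'
#' @param points ROC points from [roc_points()] (or a `pmews_roc` object).
#' @return the optimal integer threshold.
#' @export
youden_cutoff <- function(points) {
  if (inherits(points, "pmews_roc")) points <- points$points
  if (!is.data.frame(points) || nrow(points) == 0) {
    validation_error("non-empty ROC points required")
  }
  j <- points$sensitivity + points$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  max(points$threshold[best])
}
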