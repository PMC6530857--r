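#' Area under the ROC curve (Mann-Whitney rank statistic)
#'
#' Computes AUC as the mean over all positive-negative pairs of the
#' indicator that the positive's score exceeds the negative's, with ties
#' credited 0.5. Implemented in O(n log n) via midranks; equivalent to the
#' trapezoidal area under the empirical ROC curve with tie handling.
#'
#' @param scores numeric vector of test scores (higher = more positive).
#' @param labels binary (0/1) reference labels, same length.
#' @return AUC in `[0, 1]`, or `NA` if `labels` contains a single class
#'   (undefined metric, flagged rather than thrown so batch runs can
#'   record it as missing).
#' @examples
#' auc(c(1, 2, 2, 3), c(0, 0, 1, 1)) # 0.875
#' @export
auc <- function(scores, labels) {
  labels <- as_binary(labels, "labels")
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' lengths differ", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores) # midranks give the 0.5 tie credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-table metrics of binary calls against reference labels
#'
#' Counts the 2x2 table of `calls` against `labels` and derives positive
#' percent agreement (PPA, computed identically to sensitivity), negative
#' percent agreement (NPA, computed identically to specificity), PPV and
#' NPV. The agreement terminology acknowledges that the reference may be an
#' imperfect comparator rather than ground truth. Ratios with an empty
#' denominator are `NA`, never silently zero.
#'
#' @param calls binary (0/1) test calls.
#' @param labels binary (0/1) reference labels, same length.
#' @return A `metric_set`: list with counts `tp`, `fp`, `tn`, `fn` and
#'   proportions `ppa`, `npa`, `ppv`, `npv` (each possibly `NA`).
#' @examples
#' m <- confusion_metrics(rep(c(1, 0, 0, 1), c(97, 3, 85, 15)),
#'                        rep(c(1, 0), c(100, 100)))
#' round(c(m$ppv, m$npv), 3) # 0.866 0.966
#' @export
confusion_metrics <- function(calls, labels) {
  calls <- as_binary(calls, "calls")
  labels <- as_binary(labels, "labels")
  if (length(calls) != length(labels)) {
    stop("'calls' and 'labels' lengths differ", call. = FALSE)
  }
  if (length(calls) == 0L) stop("empty input", call. = FALSE)
  tp <- sum(calls == 1L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  tn <- sum(calls == 0L & labels == 0L)
  fn <- sum(calls == 0L & labels == 1L)
  new_metric_set(tp = tp, fp = fp, tn = tn, fn = fn)
}

new_metric_set <- function(tp, fp, tn, fn, auc = NA_real_) {
  structure(list(
    auc = auc,
    ppa = safe_ratio(tp, tp + fn),
    npa = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "metric_set")
}

safe_ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  v <- unlist(x[c("auc", "ppa", "npa", "ppv", "npv")])
  print(round(v, 4))
  invisible(x)
}

#' Evaluate a test cohort against reference labels
#'
#' Computes the full metric set (AUC from scores plus the four agreement
#' metrics from calls) of a cohort's test against an arbitrary label
#' vector -- ground truth by default, or comparator labels from
#' [inject()].
#'
#' @param cohort a [cohort()] with calls (or a threshold to derive them).
#' @param labels binary reference labels; defaults to `cohort$truth`.
#'   A `comparator_labels` object is also accepted.
#' @return A `metric_set` including `auc`.
#' @export
evaluate_test <- function(cohort, labels = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(labels)) labels <- cohort$truth
  if (inherits(labels, "comparator_labels")) labels <- labels$comparator
  calls <- cohort_calls(cohort)
  m <- confusion_metrics(calls, labels)
  m$auc <- auc(cohort$score, labels)
  m
}

cohort_calls <- function(cohort) {
  if (!is.null(cohort$call)) return(cohort$call)
  thr <- attr(cohort, "threshold")
  if (is.null(thr)) {
    stop("cohort has neither calls nor a threshold", call. = FALSE)
  }
  as.integer(cohort$score >= thr)
}

metric_names <- c("auc", "ppa", "npa", "ppv", "npv")

compute_metric <- function(metric, scores, calls, labels) {
  if (is.function(metric)) return(metric(scores, calls, labels))
  switch(metric,
         auc = auc(scores, labels),
         ppa = , npa = , ppv = , npv = {
           m <- confusion_metrics(calls, labels)
           m[[metric]]
         },
         stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Bootstrap confidence interval for a performance metric
#'
#' Patient-level resampling with replacement: each bootstrap replicate
#' resamples whole patients (score, call and reference label together) and
#' recomputes the metric; the interval is the percentile interval of the
#' replicate distribution. Replicates on which the metric is undefined
#' (e.g. a resample without comparator positives) are dropped and counted;
#' if more than half are undefined the interval is flagged unstable.
#'
#' @param cohort a [cohort()].
#' @param labels reference labels (default ground truth); a
#'   `comparator_labels` object is accepted.
#' @param metric one of `"auc"`, `"ppa"`, `"npa"`, `"ppv"`, `"npv"`, or a
#'   function `(scores, calls, labels) -> numeric`.
#' @param n_boot number of bootstrap replicates (at least 100).
#' @param level confidence level in (0, 1).
#' @param seed integer RNG seed.
#' @return A `confidence_interval`: list with `lower`, `upper`, `level`,
#'   `method`, `estimate`, `n_undefined`, `unstable`.
#' @seealso [binomial_ci()] for the exact (Clopper-Pearson) interval of a
#'   single proportion.
#' @export
bootstrap_ci <- function(cohort, labels = NULL, metric = "ppa",
                         n_boot = 2000L, level = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (n_boot < 100L) stop("'n_boot' must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  if (is.null(labels)) labels <- cohort$truth
  if (inherits(labels, "comparator_labels")) labels <- labels$comparator
  labels <- as_binary(labels, "labels")
  scores <- cohort$score
  calls <- cohort_calls(cohort)
  n <- nrow(cohort)
  if (length(labels) != n) stop("'labels' length differs from cohort", call. = FALSE)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    compute_metric(metric, scores[idx], calls[idx], labels[idx])
  }, numeric(1))
  n_undef <- sum(is.na(reps))
  vals <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  if (length(vals) == 0L) {
    q <- c(NA_real_, NA_real_)
  } else {
    q <- unname(stats::quantile(vals, c(alpha, 1 - alpha)))
  }
  ci <- structure(list(
    lower = q[1], upper = q[2], level = level, method = "bootstrap",
    estimate = compute_metric(metric, scores, calls, labels),
    n_undefined = n_undef, unstable = n_undef > n_boot / 2
  ), class = "confidence_interval")
  if (ci$unstable) {
    warning("metric undefined in more than half of the bootstrap resamples; interval is unstable",
            call. = FALSE)
  }
  ci
}

#' Exact binomial (Clopper-Pearson) confidence interval for a proportion
#'
#' Thin wrapper around [stats::binom.test()]. This is the interval that
#' matches printed intervals of the form 0.970 (0.915-0.994) for a
#' proportion of 97 successes out of 100.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return A `confidence_interval`.
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  ci <- stats::binom.test(x, n, conf.level = level)$conf.int
  structure(list(lower = ci[1], upper = ci[2], level = level,
                 method = "exact-binomial", estimate = x / n,
                 n_undefined = 0L, unstable = FALSE),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("%.3f (%.3f-%.3f), %g%% %s%s\n", x$estimate, x$lower, x$upper,
              100 * x$level, x$method,
              if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}
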