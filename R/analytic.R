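#' Expected apparent agreement metrics under comparator misclassification
#'
#' Closed-form expectations for the apparent confusion metrics of a test
#' with true sensitivity `se` and specificity `sp`, when the comparator
#' mislabels true negatives at `fp_rate` and true positives at `fn_rate`
#' and flips are independent of the test result. Each metric is a mixture
#' over the composition of the relevant comparator (or test) margin; for
#' example the expected apparent PPA is
#'
#' \deqn{\frac{(1-fn)\,n_{pos}\,se + fp\,n_{neg}\,(1-sp)}
#'            {(1-fn)\,n_{pos} + fp\,n_{neg}}}
#'
#' because the comparator-positive group is a blend of unflipped true
#' positives (test-positive with probability `se`) and flipped true
#' negatives (test-positive with probability `1 - sp`). Under exact-count
#' class-rate injection the comparator margins are fixed, so these values
#' are exact expectations of the simulated metrics, which is how the
#' simulator is cross-validated.
#'
#' @param se,sp true sensitivity and specificity of the test.
#' @param n_neg,n_pos ground-truth class sizes.
#' @param fp_rate proportion of true negatives mislabelled positive.
#' @param fn_rate proportion of true positives mislabelled negative.
#' @return A `metric_set` of expectations (counts are expected counts;
#'   `auc` is `NA`, see [expected_apparent_auc()]).
#' @examples
#' # a 97% sensitive / 85% specific test, 5% symmetric comparator noise
#' m <- expected_apparent_metrics(0.97, 0.85, 100, 100, 0.05, 0.05)
#' round(m$ppa, 3) # 0.929
#' @export
expected_apparent_metrics <- function(se, sp, n_neg, n_pos,
                                      fp_rate, fn_rate) {
  check_prob(se, "se"); check_prob(sp, "sp")
  check_prob(fp_rate, "fp_rate"); check_prob(fn_rate, "fn_rate")
  check_count(n_neg, "n_neg"); check_count(n_pos, "n_pos")
  if (n_neg + n_pos == 0L) stop("empty cohort", call. = FALSE)
  # expected composition of the comparator margins
  cpos_tp <- (1 - fn_rate) * n_pos      # true positives labelled positive
  cpos_tn <- fp_rate * n_neg            # true negatives labelled positive
  cneg_tn <- (1 - fp_rate) * n_neg
  cneg_tp <- fn_rate * n_pos
  tp <- cpos_tp * se + cpos_tn * (1 - sp)   # test-positive & comparator-positive
  fp <- cneg_tn * (1 - sp) + cneg_tp * se
  tn <- cneg_tn * sp + cneg_tp * (1 - se)
  fn <- cpos_tp * (1 - se) + cpos_tn * sp
  new_metric_set(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Expected apparent AUC under comparator misclassification
#'
#' Mixture formula for the apparent AUC of a test with true AUC `A` when a
#' fraction `a` of comparator positives are really negatives and a
#' fraction `b` of comparator negatives are really positives:
#'
#' \deqn{(1-a)(1-b)A + [(1-a)b + a(1-b)]\,\tfrac12 + ab(1-A)}
#'
#' Pairs drawn from the same true class contribute 1/2 (scores within a
#' class are exchangeable because flip selection is independent of score);
#' reversed pairs contribute `1 - A`. For a perfect test on a balanced
#' cohort with symmetric rate `eps` this reduces to `1 - eps`: a 10%
#' comparator misclassification rate caps the apparent AUC of any test,
#' including a perfect one, at 0.90.
#'
#' @param true_auc true AUC of the test against ground truth, in
#'   `[0.5, 1]`. For finite-cohort cross-checks use the cohort's empirical
#'   noise-free AUC.
#' @param n_neg,n_pos ground-truth class sizes.
#' @param fp_rate,fn_rate comparator misclassification rates per class.
#' @return The expected apparent AUC, or `NA` if a comparator margin is
#'   empty.
#' @examples
#' expected_apparent_auc(1, 100, 100, 0.1, 0.1) # 0.9
#' @export
expected_apparent_auc <- function(true_auc, n_neg, n_pos, fp_rate, fn_rate) {
  if (!is.numeric(true_auc) || length(true_auc) != 1L ||
      true_auc < 0 || true_auc > 1) {
    stop("'true_auc' must be in [0, 1]", call. = FALSE)
  }
  check_prob(fp_rate, "fp_rate"); check_prob(fn_rate, "fn_rate")
  check_count(n_neg, "n_neg"); check_count(n_pos, "n_pos")
  cpos <- (1 - fn_rate) * n_pos + fp_rate * n_neg
  cneg <- (1 - fp_rate) * n_neg + fn_rate * n_pos
  if (cpos <= 0 || cneg <= 0) return(NA_real_)
  a <- fp_rate * n_neg / cpos  # contaminated fraction of comparator positives
  b <- fn_rate * n_pos / cneg  # contaminated fraction of comparator negatives
  A <- true_auc
  (1 - a) * (1 - b) * A + ((1 - a) * b + a * (1 - b)) * 0.5 + a * b * (1 - A)
}

#' Overall expected misclassification rate from per-class rates
#'
#' The FP rate applied to the negative patients plus the FN rate applied
#' to the positive patients, as a fraction of the whole cohort:
#' `(fp_rate * n_neg + fn_rate * n_pos) / (n_neg + n_pos)`.
#'
#' @param fp_rate,fn_rate per-class misclassification rates.
#' @param n_neg,n_pos class sizes (not both zero).
#' @return Overall misclassification proportion.
#' @export
expected_overall_misclassification <- function(fp_rate, fn_rate,
                                               n_neg, n_pos) {
  check_prob(fp_rate, "fp_rate"); check_prob(fn_rate, "fn_rate")
  check_count(n_neg, "n_neg"); check_count(n_pos, "n_pos")
  if (n_neg + n_pos == 0L) stop("empty cohort", call. = FALSE)
  (fp_rate * n_neg + fn_rate * n_pos) / (n_neg + n_pos)
}

#' Probability that a perfect test fails a performance requirement
#'
#' For a perfect test, disagreements with the comparator arise only from
#' comparator label errors, so the observed agreement count among
#' `n_labelled` comparator-positive (or -negative) patients is
#' `Binomial(n_labelled, per_label_accuracy)`. The trial "rejects" the
#' test when the observed PPA (or NPA) point estimate falls below the
#' required level, i.e. when fewer than `ceiling(required * n_labelled)`
#' agreements are observed. The exact binomial tail gives the rejection
#' probability; e.g. a 99% PPA requirement with 95% label accuracy is
#' failed by a perfect test with probability above 99.999% once the trial
#' has 1000 comparator positives.
#'
#' @param n_labelled number of comparator-positive (or -negative)
#'   patients, at least 1.
#' @param required required metric level, e.g. 0.99.
#' @param per_label_accuracy probability that a comparator label is
#'   correct, e.g. 0.95 under 5% label error.
#' @return Rejection probability
#'   `1 - P(X >= ceiling(required * n_labelled))`.
#' @examples
#' rejection_probability(100, 0.99, 0.95)  # ~0.963
#' rejection_probability(1000, 0.99, 0.95) # > 0.99999
#' @export
rejection_probability <- function(n_labelled, required, per_label_accuracy) {
  check_count(n_labelled, "n_labelled", min = 1L)
  check_prob(required, "required")
  check_prob(per_label_accuracy, "per_label_accuracy")
  k <- ceiling(required * n_labelled)
  if (k <= 0) return(0)
  # P(X <= k - 1), exact binomial CDF
  stats::pbinom(k - 1, n_labelled, per_label_accuracy)
}

#' Relative error of an apparent AUC
#'
#' `(1 - auc) / (1 - auc0)`: the apparent error rate normalised by the
#' error rate at zero comparator misclassification. A relative error of 2
#' means the comparator noise has doubled the apparent error of the test.
#'
#' @param auc apparent AUC.
#' @param auc0 AUC at zero misclassification rate (strictly below 1).
#' @return Relative error (1 when `auc == auc0`).
#' @export
relative_error <- function(auc, auc0) {
  if (any(auc0 >= 1)) {
    stop("'auc0' must be < 1: relative error is undefined for a perfect noise-free AUC",
         call. = FALSE)
  }
  (1 - auc) / (1 - auc0)
}

#' Analytic table of expected apparent performance over a noise grid
#'
#' Convenience wrapper evaluating [expected_apparent_metrics()] and
#' [expected_apparent_auc()] (the AUC ceiling when `true_auc = 1`) on a
#' grid of symmetric misclassification rates.
#'
#' @param eps numeric vector of misclassification rates (applied to both
#'   classes).
#' @param se,sp,true_auc true test characteristics.
#' @param n_neg,n_pos class sizes.
#' @return Data frame with one row per rate: `eps`, `auc`, `ppa`, `npa`,
#'   `ppv`, `npv`.
#' @export
analytic_table <- function(eps, se = 1, sp = 1, true_auc = 1,
                           n_neg = 100L, n_pos = 100L) {
  if (length(eps) == 0L) stop("empty rate grid", call. = FALSE)
  rows <- lapply(eps, function(e) {
    m <- expected_apparent_metrics(se, sp, n_neg, n_pos, e, e)
    data.frame(eps = e,
               auc = expected_apparent_auc(true_auc, n_neg, n_pos, e, e),
               ppa = m$ppa, npa = m$npa, ppv = m$ppv, npv = m$npv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
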