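#' Construct a diagnostic cohort
#'
#' A cohort is a data frame with one row per patient and columns `id`
#' (unique identifier), `truth` (ground-truth state, 0 = negative,
#' 1 = positive), `score` (continuous test output, higher = more positive)
#' and, optionally, `call` (binary test call). An optional decision
#' threshold is carried as an attribute; when both are present every call
#' must satisfy `call == (score >= threshold)` (ties at the threshold are
#' called positive).
#'
#' @param truth integer/logical vector of ground-truth states (0/1).
#' @param score numeric vector of finite test scores, same length as `truth`.
#' @param call optional binary vector of test calls. If `NULL` and
#'   `threshold` is given, calls are derived from the threshold.
#' @param threshold optional numeric cutoff mapping scores to calls.
#' @param id optional character vector of unique patient identifiers;
#'   defaults to `"p0001", "p0002", ...`.
#' @return A `cohort` object (a `data.frame` subclass).
#' @seealso [make_perfect_cohort()], [make_binormal_cohort()],
#'   [make_called_cohort()]
#' @export
cohort <- function(truth, score, call = NULL, threshold = NULL, id = NULL) {
  truth <- as_binary(truth, "truth")
  n <- length(truth)
  if (n < 1L) stop("a cohort needs at least one patient", call. = FALSE)
  if (length(score) != n) stop("'score' and 'truth' lengths differ", call. = FALSE)
  score <- as.numeric(score)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  if (is.null(id)) id <- sprintf("p%04d", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("patient ids must be unique", call. = FALSE)
  if (is.null(call) && !is.null(threshold)) {
    call <- as.integer(score >= threshold)
  } else if (!is.null(call)) {
    call <- as_binary(call, "call")
    if (length(call) != n) stop("'call' and 'truth' lengths differ", call. = FALSE)
    if (!is.null(threshold) && !all(call == as.integer(score >= threshold))) {
      stop("calls are inconsistent with the threshold", call. = FALSE)
    }
  }
  df <- data.frame(id = id, truth = truth, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(call)) df$call <- call
  structure(df, threshold = threshold, class = c("cohort", "data.frame"))
}

as_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (any(is.na(x)) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("'%s' must be binary (0/1)", what), call. = FALSE)
  }
  x
}

#' @export
print.cohort <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Cohort: %d patients (%d positive, %d negative)%s\n",
              nrow(x), sum(x$truth == 1L), sum(x$truth == 0L),
              if (is.null(thr)) "" else sprintf(", threshold %.4g", thr)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Round half away from zero
#'
#' Used for all count targets (flip counts, call counts) so that fixtures
#' such as `round(0.05 * 200) = 10` are platform-stable, unlike base
#' `round()`'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Generate a perfectly separated cohort
#'
#' Negative scores are drawn uniformly on `[0, 0.4]` and positive scores on
#' `[0.6, 1]`, so every positive strictly exceeds every negative and the
#' empirical AUC against ground truth is exactly 1. The threshold is 0.5
#' and calls equal truth.
#'
#' @param n_neg,n_pos class sizes (each at least 1).
#' @param seed integer RNG seed.
#' @return A [cohort()].
#' @examples
#' co <- make_perfect_cohort(100, 100, seed = 1)
#' auc(co$score, co$truth) # exactly 1
#' @export
make_perfect_cohort <- function(n_neg, n_pos, seed = 1L) {
  check_count(n_neg, "n_neg", min = 1L)
  check_count(n_pos, "n_pos", min = 1L)
  set.seed(seed)
  score <- c(stats::runif(n_neg, 0, 0.4), stats::runif(n_pos, 0.6, 1))
  truth <- rep(c(0L, 1L), c(n_neg, n_pos))
  cohort(truth, score, threshold = 0.5)
}

#' Generate a binormal cohort with a target AUC
#'
#' The equal-variance binormal ROC model: negative scores are standard
#' normal and positive scores are normal with unit variance and mean
#' `delta = sqrt(2) * qnorm(target_auc)`, which makes the population AUC
#' equal to `target_auc`. The threshold defaults to the midpoint of the two
#' class means.
#'
#' @param n_neg,n_pos class sizes.
#' @param target_auc population AUC in `[0.5, 1)`.
#' @param seed integer RNG seed.
#' @return A [cohort()].
#' @export
make_binormal_cohort <- function(n_neg, n_pos, target_auc, seed = 1L) {
  check_count(n_neg, "n_neg", min = 1L)
  check_count(n_pos, "n_pos", min = 1L)
  if (!is.numeric(target_auc) || length(target_auc) != 1L ||
      target_auc < 0.5 || target_auc >= 1) {
    stop("'target_auc' must lie in [0.5, 1)", call. = FALSE)
  }
  delta <- sqrt(2) * stats::qnorm(target_auc)
  set.seed(seed)
  score <- c(stats::rnorm(n_neg, 0), stats::rnorm(n_pos, delta))
  truth <- rep(c(0L, 1L), c(n_neg, n_pos))
  cohort(truth, score, threshold = delta / 2)
}

#' Generate a cohort with fixed sensitivity and specificity
#'
#' Exactly `round_half_up(se * n_pos)` positives receive a positive call and
#' `round_half_up(sp * n_neg)` negatives a negative call; which patients is
#' chosen uniformly at random. Scores are drawn consistent with the calls
#' around a fixed threshold of 0.5 (calls at or above 0.5 are positive), so
#' the confusion table of calls against ground truth is deterministic given
#' the arguments. This reproduces worked-example margins such as a test with
#' sensitivity 0.970 and specificity 0.850 on 100/100 patients
#' (TP = 97, FN = 3, TN = 85, FP = 15).
#'
#' @param n_neg,n_pos class sizes.
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A [cohort()].
#' @export
make_called_cohort <- function(n_neg, n_pos, se, sp, seed = 1L) {
  check_count(n_neg, "n_neg", min = 1L)
  check_count(n_pos, "n_pos", min = 1L)
  check_prob(se, "se")
  check_prob(sp, "sp")
  set.seed(seed)
  n_tp <- round_half_up(se * n_pos)
  n_tn <- round_half_up(sp * n_neg)
  call_pos <- integer(n_pos)
  call_pos[sample.int(n_pos, n_tp)] <- 1L
  call_neg <- integer(n_neg)
  if (n_neg > n_tn) call_neg[sample.int(n_neg, n_neg - n_tn)] <- 1L
  call <- c(call_neg, call_pos)
  # score on the side of the threshold implied by the call
  score <- ifelse(call == 1L, stats::runif(n_neg + n_pos, 0.5, 1),
                  stats::runif(n_neg + n_pos, 0, 0.5))
  truth <- rep(c(0L, 1L), c(n_neg, n_pos))
  cohort(truth, score, call = call, threshold = 0.5)
}

#' Build a cohort for a named scenario
#'
#' Dispatch helper used by the sweep engine and the command line: `shape`
#' selects one of the three generators.
#'
#' @param shape one of `"perfect"`, `"binormal"`, `"called"`.
#' @param n_neg,n_pos class sizes.
#' @param seed integer RNG seed.
#' @param target_auc population AUC for `shape = "binormal"`.
#' @param se,sp margins for `shape = "called"`.
#' @return A [cohort()].
#' @export
scenario_cohort <- function(shape = c("perfect", "binormal", "called"),
                            n_neg, n_pos, seed = 1L,
                            target_auc = 0.98, se = 0.97, sp = 0.85) {
  shape <- match.arg(shape)
  switch(shape,
         perfect  = make_perfect_cohort(n_neg, n_pos, seed),
         binormal = make_binormal_cohort(n_neg, n_pos, target_auc, seed),
         called   = make_called_cohort(n_neg, n_pos, se, sp, seed))
}

check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a proportion in [0, 1]", what), call. = FALSE)
  }
  invisible(as.numeric(x))
}
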