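#' Comparator noise specifications
#'
#' A noise specification describes how comparator misclassification is
#' injected into ground-truth labels. Three schemes are supported:
#'
#' * `noise_uniform(rate)`: a fixed number `round_half_up(rate * N)` of
#'   patients, drawn uniformly from the pooled cohort, have their label
#'   flipped. Positives and negatives are equally likely to be flipped, so
#'   the realized FP/FN split is hypergeometric. With `exact = FALSE` each
#'   patient is instead flipped independently with probability `rate`
#'   (per-patient Bernoulli noise); the realized total then varies
#'   binomially around `rate * N`, which widens the iteration-to-iteration
#'   spread of apparent metrics.
#' * `noise_class_rates(fp_rate, fn_rate)`: exactly
#'   `round_half_up(fp_rate * n_neg)` true negatives are flipped to
#'   positive and `round_half_up(fn_rate * n_pos)` true positives to
#'   negative, each drawn uniformly within its class.
#' * `noise_weighted(weights, total_rate)`: `round_half_up(total_rate * N)`
#'   patients are drawn without replacement with probability proportional
#'   to `weights` (e.g. residual classification uncertainty from an expert
#'   panel) and flipped.
#'
#' @param rate,fp_rate,fn_rate,total_rate proportions in `[0, 1]`.
#' @param exact logical; flip an exact count (default) or per-patient
#'   Bernoulli.
#' @param weights nonnegative per-patient weights.
#' @return An object of class `noise_spec`.
#' @seealso [inject()]
#' @export
noise_uniform <- function(rate, exact = TRUE) {
  check_prob(rate, "rate")
  structure(list(mode = "uniform", rate = rate, exact = isTRUE(exact)),
            class = "noise_spec")
}

#' @rdname noise_uniform
#' @export
noise_class_rates <- function(fp_rate, fn_rate) {
  check_prob(fp_rate, "fp_rate")
  check_prob(fn_rate, "fn_rate")
  structure(list(mode = "class_rates", fp_rate = fp_rate, fn_rate = fn_rate),
            class = "noise_spec")
}

#' @rdname noise_uniform
#' @export
noise_weighted <- function(weights, total_rate) {
  check_prob(total_rate, "total_rate")
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("'weights' must be finite and nonnegative", call. = FALSE)
  }
  structure(list(mode = "weighted", weights = weights, total_rate = total_rate),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(switch(x$mode,
    uniform = sprintf("Noise spec: uniform rate %.4g (%s)", x$rate,
                      if (x$exact) "exact count" else "per-patient Bernoulli"),
    class_rates = sprintf("Noise spec: FP rate %.4g, FN rate %.4g",
                          x$fp_rate, x$fn_rate),
    weighted = sprintf("Noise spec: weighted, total rate %.4g, %d weights",
                       x$total_rate, length(x$weights))), "\n")
  invisible(x)
}

#' Inject comparator misclassification into ground-truth labels
#'
#' Applies a [noise_uniform()]-family specification to a binary label
#' vector and returns the comparator labels together with flip provenance.
#'
#' @param spec a `noise_spec`.
#' @param truth binary (0/1) ground-truth label vector.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `comparator_labels`: a list with elements
#'   `comparator` (0/1 labels), `flipped` (logical), `fp_count` (true
#'   negatives labelled positive), `fn_count` (true positives labelled
#'   negative) and `n`.
#' @export
inject <- function(spec, truth, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$mode,
    uniform = inject_uniform(truth, spec$rate, seed, exact = spec$exact),
    class_rates = inject_class_rates(truth, spec$fp_rate, spec$fn_rate, seed),
    weighted = inject_weighted(truth, spec$weights, spec$total_rate, seed))
}

#' @describeIn inject flip a uniformly chosen subset of the pooled cohort:
#'   exactly `round_half_up(rate * N)` labels, or each label independently
#'   with probability `rate` when `exact = FALSE`.
#' @param truth,rate,exact,weights,total_rate,fp_rate,fn_rate see
#'   [noise_uniform()].
#' @export
inject_uniform <- function(truth, rate, seed = NULL, exact = TRUE) {
  truth <- as_binary(truth, "truth")
  n <- length(truth)
  if (n < 1L) stop("empty label sequence", call. = FALSE)
  check_prob(rate, "rate")
  if (!is.null(seed)) set.seed(seed)
  flipped <- logical(n)
  if (isTRUE(exact)) {
    k <- round_half_up(rate * n)
    if (k > 0L) flipped[sample.int(n, k)] <- TRUE
  } else {
    flipped <- stats::runif(n) < rate
  }
  new_comparator_labels(truth, flipped)
}

#' @describeIn inject flip exact per-class counts: `round_half_up(fp_rate *
#'   n_neg)` true negatives to positive, `round_half_up(fn_rate * n_pos)`
#'   true positives to negative.
#' @export
inject_class_rates <- function(truth, fp_rate, fn_rate, seed = NULL) {
  truth <- as_binary(truth, "truth")
  if (length(truth) < 1L) stop("empty label sequence", call. = FALSE)
  check_prob(fp_rate, "fp_rate")
  check_prob(fn_rate, "fn_rate")
  neg <- which(truth == 0L)
  pos <- which(truth == 1L)
  if (length(neg) == 0L && fp_rate > 0) {
    stop("nonzero 'fp_rate' with no true negatives", call. = FALSE)
  }
  if (length(pos) == 0L && fn_rate > 0) {
    stop("nonzero 'fn_rate' with no true positives", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k_fp <- round_half_up(fp_rate * length(neg))
  k_fn <- round_half_up(fn_rate * length(pos))
  flipped <- logical(length(truth))
  if (k_fp > 0L) flipped[neg[sample.int(length(neg), k_fp)]] <- TRUE
  if (k_fn > 0L) flipped[pos[sample.int(length(pos), k_fn)]] <- TRUE
  new_comparator_labels(truth, flipped)
}

#' @describeIn inject flip `round_half_up(total_rate * N)` patients drawn
#'   without replacement with probability proportional to `weights`
#'   (sequential draws with renormalization, i.e. base R's weighted
#'   `sample()` without replacement).
#' @export
inject_weighted <- function(truth, weights, total_rate, seed = NULL) {
  truth <- as_binary(truth, "truth")
  n <- length(truth)
  if (n < 1L) stop("empty label sequence", call. = FALSE)
  weights <- as.numeric(weights)
  if (length(weights) != n) {
    stop("'weights' must have one entry per patient", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("'weights' must be finite and nonnegative", call. = FALSE)
  }
  check_prob(total_rate, "total_rate")
  k <- round_half_up(total_rate * n)
  if (k > sum(weights > 0)) {
    stop(sprintf(
      "infeasible selection: %d flips requested but only %d patients have positive weight",
      k, sum(weights > 0)), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  flipped <- logical(n)
  if (k > 0L) flipped[sample.int(n, k, prob = weights)] <- TRUE
  new_comparator_labels(truth, flipped)
}

new_comparator_labels <- function(truth, flipped) {
  comparator <- ifelse(flipped, 1L - truth, truth)
  structure(list(
    comparator = as.integer(comparator),
    flipped = flipped,
    fp_count = sum(flipped & truth == 0L),
    fn_count = sum(flipped & truth == 1L),
    n = length(truth)
  ), class = "comparator_labels")
}

#' @export
print.comparator_labels <- function(x, ...) {
  cat(sprintf("Comparator labels: %d patients, %d flipped (%d FP, %d FN)\n",
              x$n, sum(x$flipped), x$fp_count, x$fn_count))
  invisible(x)
}
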