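#' Deterministic sub-seed derivation
#'
#' Counter-based scheme: each noise level (or trial size) of a sweep gets
#' its own seed derived from the master seed, and all iterations within a
#' level consume that level's single RNG stream. Adding levels therefore
#' never perturbs existing ones, extending `n_iter` leaves earlier
#' iterations unchanged, and the same master seed reproduces a run
#' exactly. Iterations deliberately do not get one seed each: reseeding a
#' Mersenne-Twister with closely spaced seeds correlates the first draws
#' across iterations, which biases Monte-Carlo means.
#'
#' @param master master integer seed.
#' @param level_index 0-based level index.
#' @param iter reserved counter (0 for the level stream).
#' @return An integer seed inside the 32-bit range.
#' @keywords internal
derive_seed <- function(master, level_index, iter = 0L) {
  as.integer((as.double(master) + level_index * 1000003 + iter * 7919) %%
               2147483647)
}

#' Repeated noise injection on a fixed cohort
#'
#' The core Monte-Carlo experiment: for each iteration, fresh comparator
#' labels are drawn from the noise specification and the test is scored
#' against them; the per-metric distributions are summarised as the median
#' and the empirical 95% interval (2.5th-97.5th percentiles across
#' iterations). Metrics undefined in an iteration (e.g. no comparator
#' positives) are recorded as missing; a metric missing in more than half
#' the iterations is flagged unstable.
#'
#' @param cohort a [cohort()] with calls or a threshold.
#' @param spec a [noise_uniform()]-family `noise_spec`.
#' @param n_iter number of noise-injection iterations (default 100).
#' @param seed master integer seed.
#' @param level_index internal offset used by [sweep_noise()] so each level
#'   gets an independent seed stream.
#' @return A `noise_run`: list with `values` (n_iter x 5 matrix of
#'   iteration metrics), `summary` (data frame `metric`, `median`,
#'   `ci_lower`, `ci_upper`, `n_missing`, `unstable`), `n_iter`, `seed`.
#' @examples
#' co <- make_perfect_cohort(50, 50, seed = 1)
#' run <- run_iterations(co, noise_uniform(0.1), n_iter = 50, seed = 42)
#' run$summary
#' @export
run_iterations <- function(cohort, spec, n_iter = 100L, seed = 1L,
                           level_index = 0L) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "noise_spec"))
  check_count(n_iter, "n_iter", min = 1L)
  truth <- cohort$truth
  scores <- cohort$score
  calls <- cohort_calls(cohort)
  values <- matrix(NA_real_, nrow = n_iter, ncol = length(metric_names),
                   dimnames = list(NULL, metric_names))
  set.seed(derive_seed(seed, level_index))
  for (i in seq_len(n_iter)) {
    cl <- inject(spec, truth, seed = NULL)
    lab <- cl$comparator
    values[i, "auc"] <- auc(scores, lab)
    m <- confusion_metrics(calls, lab)
    values[i, c("ppa", "npa", "ppv", "npv")] <-
      c(m$ppa, m$npa, m$ppv, m$npv)
  }
  structure(list(values = values,
                 summary = summarise_values(values),
                 n_iter = n_iter, seed = seed),
            class = "noise_run")
}

summarise_values <- function(values) {
  n_iter <- nrow(values)
  stats_one <- function(v) {
    ok <- v[!is.na(v)]
    if (length(ok) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(stats::median(ok),
      unname(stats::quantile(ok, c(0.025, 0.975))))
  }
  s <- t(apply(values, 2, stats_one))
  n_missing <- colSums(is.na(values))
  data.frame(metric = colnames(values),
             median = s[, 1], ci_lower = s[, 2], ci_upper = s[, 3],
             n_missing = unname(n_missing),
             unstable = unname(n_missing > n_iter / 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.noise_run <- function(x, ...) {
  cat(sprintf("Noise run: %d iterations, seed %d\n", x$n_iter, x$seed))
  print(x$summary)
  invisible(x)
}

#' Sweep apparent performance over noise levels
#'
#' Runs [run_iterations()] at each noise level and assembles the medians
#' and empirical 95% intervals into a long table, one row per
#' (level, metric). Levels may be given as a numeric vector of uniform
#' misclassification rates or as a list of `noise_spec` objects (with
#' `levels` labelling the rows). Each level draws from an independent,
#' deterministically derived seed stream, so extending the grid leaves
#' existing levels unchanged.
#'
#' @param cohort a [cohort()].
#' @param levels numeric vector of uniform rates, or a list of
#'   `noise_spec`s.
#' @param n_iter iterations per level (default 100).
#' @param seed master integer seed.
#' @param exact passed to [noise_uniform()] when `levels` is numeric.
#' @param keep_values retain the full iteration matrices as attribute
#'   `"values"` (list, one matrix per level).
#' @return A `sweep_result` data frame with columns `level`, `metric`,
#'   `median`, `ci_lower`, `ci_upper`, `n_missing`, and attributes
#'   `n_iter` and `seed`.
#' @examples
#' co <- make_perfect_cohort(50, 50, seed = 1)
#' sw <- sweep_noise(co, levels = c(0, 0.05, 0.1), n_iter = 50, seed = 7)
#' subset(sw, metric == "auc")
#' @export
sweep_noise <- function(cohort, levels, n_iter = 100L, seed = 1L,
                        exact = TRUE, keep_values = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.numeric(levels)) {
    if (length(levels) == 0L) stop("empty level sequence", call. = FALSE)
    specs <- lapply(levels, noise_uniform, exact = exact)
    level_labels <- levels
  } else if (is.list(levels) && all(vapply(levels, inherits, TRUE, "noise_spec"))) {
    if (length(levels) == 0L) stop("empty level sequence", call. = FALSE)
    specs <- levels
    level_labels <- seq_along(levels) - 1
  } else {
    stop("'levels' must be a numeric vector or a list of noise specs",
         call. = FALSE)
  }
  rows <- vector("list", length(specs))
  vals <- if (keep_values) vector("list", length(specs)) else NULL
  for (j in seq_along(specs)) {
    run <- run_iterations(cohort, specs[[j]], n_iter = n_iter, seed = seed,
                          level_index = j - 1L)
    s <- run$summary
    s <- cbind(level = level_labels[j], s)
    rows[[j]] <- s
    if (keep_values) vals[[j]] <- run$values
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_iter = n_iter, seed = seed, index = "level",
            values = vals,
            class = c("sweep_result", "data.frame"))
}

#' Sweep apparent performance over trial size
#'
#' Regenerates a scenario cohort at each trial size and applies the same
#' noise specification, summarising as in [sweep_noise()]. Used to study
#' how empirical confidence intervals shrink as the trial grows at a fixed
#' comparator misclassification rate.
#'
#' @param sizes vector of total cohort sizes (at least 4 each so both
#'   classes have at least 2 patients).
#' @param spec a `noise_spec` applied at every size.
#' @param shape,target_auc,se,sp scenario parameters, see
#'   [scenario_cohort()].
#' @param prevalence proportion of ground-truth positives.
#' @param n_iter iterations per size.
#' @param seed master integer seed (also drives cohort generation).
#' @return A `sweep_result` data frame with columns `size`, `metric`,
#'   `median`, `ci_lower`, `ci_upper`, `n_missing`.
#' @export
size_sweep <- function(sizes, spec, shape = "perfect", prevalence = 0.5,
                       target_auc = 0.98, se = 0.97, sp = 0.85,
                       n_iter = 100L, seed = 1L) {
  stopifnot(inherits(spec, "noise_spec"))
  if (length(sizes) == 0L) stop("empty size sequence", call. = FALSE)
  check_prob(prevalence, "prevalence")
  rows <- vector("list", length(sizes))
  for (j in seq_along(sizes)) {
    n <- check_count(sizes[j], "size", min = 4L)
    n_pos <- round_half_up(prevalence * n)
    n_neg <- n - n_pos
    if (n_pos < 2L || n_neg < 2L) {
      stop("each class needs at least 2 patients at every size", call. = FALSE)
    }
    co <- scenario_cohort(shape, n_neg, n_pos,
                          seed = derive_seed(seed, j - 1L, 1L),
                          target_auc = target_auc, se = se, sp = sp)
    run <- run_iterations(co, spec, n_iter = n_iter, seed = seed,
                          level_index = j - 1L)
    rows[[j]] <- cbind(size = n, run$summary)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_iter = n_iter, seed = seed, index = "size",
            class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s: %d rows, %d iterations per %s, seed %d\n",
              attr(x, "index"), nrow(x), attr(x, "n_iter"),
              attr(x, "index"), attr(x, "seed")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
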