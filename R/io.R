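#' Read and write cohort CSV files
#'
#' The cohort dialect is comma-separated UTF-8 with a mandatory header and
#' columns `id,truth,score,call` (`truth`/`call` in 0/1). The `call`
#' column may be absent when a threshold is supplied, in which case calls
#' are derived as `score >= threshold`.
#'
#' @param path file path.
#' @param threshold optional decision threshold.
#' @return [read_cohort_csv()] returns a [cohort()];
#'   [write_cohort_csv()] invisibly returns `path`.
#' @export
read_cohort_csv <- function(path, threshold = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "truth", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("cohort CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cohort(truth = df$truth, score = df$score,
         call = if ("call" %in% names(df)) df$call else NULL,
         threshold = threshold, id = df$id)
}

#' @rdname read_cohort_csv
#' @param cohort a [cohort()].
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write panel CSV files
#'
#' Dialect: `id,panelist1,panelist2,panelist3,site_dx` with call values in
#' \{pos, neg, ind\} and `site_dx` in \{pos, neg, NA\}. Malformed call
#' tokens are reported with their line numbers; rows are never silently
#' dropped. [write_panel_csv()] writes whatever assessment columns are
#' present (e.g. `confidence`, `assigned`, `stratum`, `p_wrong` after
#' [assess_panel()]).
#'
#' @param path file path.
#' @return [read_panel_csv()] returns a data frame ready for
#'   [assess_panel()].
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("id", "panelist1", "panelist2", "panelist3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("panel CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- rep(FALSE, nrow(df))
  for (col in c("panelist1", "panelist2", "panelist3")) {
    bad <- bad | !(df[[col]] %in% panel_call_levels)
  }
  if ("site_dx" %in% names(df)) {
    bad <- bad | !(is.na(df$site_dx) | df$site_dx %in% c("pos", "neg"))
  }
  if (any(bad)) {
    # +1 for the header row
    stop(sprintf("invalid call token(s) on line(s): %s",
                 paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_panel_csv
#' @param panel a panel data frame.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write comparator labels alongside a cohort
#'
#' Emits `id,comparator,flipped` (0/1 each).
#'
#' @param labels a `comparator_labels` object from [inject()].
#' @param ids patient identifiers.
#' @param path file path.
#' @export
write_comparator_csv <- function(labels, ids, path) {
  stopifnot(inherits(labels, "comparator_labels"))
  if (length(ids) != labels$n) stop("'ids' length mismatch", call. = FALSE)
  utils::write.csv(data.frame(id = ids, comparator = labels$comparator,
                              flipped = as.integer(labels$flipped)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep result as CSV
#'
#' Long format, one row per (level or size, metric):
#' `level,metric,median,ci_lower,ci_upper,n_missing`.
#'
#' @param sweep a `sweep_result` from [sweep_noise()] or [size_sweep()].
#' @param path file path.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- as.data.frame(sweep)
  df$unstable <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records every parameter needed to reproduce a run bit-for-bit. Keys are
#' sorted recursively so manifests diff cleanly.
#'
#' @param params named list of run parameters (must include the seed).
#' @param path file path.
#' @export
write_manifest <- function(params, path) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else x
  }
  jsonlite::write_json(sort_rec(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse a level-grid string
#'
#' Grids are written `start:stop:step` (inclusive of both ends within a
#' 1e-9 floating tolerance); a bare number denotes a single level. Levels
#' must lie in `[0, 1]` and be strictly increasing.
#'
#' @param text grid string, e.g. `"0:0.2:0.01"` or `"0.05"`.
#' @return Numeric vector of levels.
#' @export
parse_level_grid <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  if (any(is.na(nums)) || !length(nums) %in% c(1L, 3L)) {
    stop("levels must be a number or 'start:stop:step'", call. = FALSE)
  }
  if (length(nums) == 1L) {
    levels <- nums
  } else {
    if (nums[3] <= 0 || nums[2] < nums[1]) {
      stop("invalid level grid: need stop >= start and step > 0", call. = FALSE)
    }
    levels <- seq(nums[1], nums[2] + 1e-9, by = nums[3])
    levels <- round(levels, 9)
  }
  if (any(levels < 0 | levels > 1)) {
    stop("levels must lie in [0, 1]", call. = FALSE)
  }
  levels
}
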