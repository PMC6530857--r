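panel_call_levels <- c("neg", "ind", "pos")

panel_call_value <- function(calls, what = "calls") {
  calls <- as.character(calls)
  if (any(!calls %in% panel_call_levels)) {
    stop(sprintf("%s must be 'pos', 'neg' or 'ind'", what), call. = FALSE)
  }
  c(neg = 0, ind = 0.5, pos = 1)[calls]
}

#' Classification confidence from three panelist calls
#'
#' Each panelist call maps to a probability that the patient is positive:
#' "neg" to 0, "ind" (indeterminate) to 1/2, "pos" to 1. The patient's
#' confidence of being positive is the simple average of the three mapped
#' values, so it always lies in \{0, 1/6, 1/3, 1/2, 2/3, 5/6, 1\}.
#'
#' @param calls character vector of exactly three calls in
#'   `c("pos", "neg", "ind")`.
#' @return Probability in `[0, 1]`.
#' @examples
#' panel_confidence(c("pos", "pos", "ind")) # 5/6
#' @export
panel_confidence <- function(calls) {
  if (length(calls) != 3L) stop("exactly three panelist calls required", call. = FALSE)
  mean(panel_call_value(calls))
}

#' Assign a comparator label and agreement stratum from panelist calls
#'
#' The assigned label follows the confidence: positive above 1/2, negative
#' below, indeterminate at exactly 1/2. The stratum records the finest
#' level of agreement reached:
#'
#' * `super_unanimous`: all three panelists agree on a definitive call and
#'   the site diagnosis matches;
#' * `unanimous`: all three agree on a definitive call;
#' * `consensus`: at least two agree on a definitive call;
#' * `indeterminate`: no definitive majority.
#'
#' Strata are nested (`super_unanimous` patients are also unanimous and
#' consensus). Every patient additionally receives a forced binary label:
#' the assigned label where definitive, and positive at a confidence of
#' exactly 1/2 (ties are forced positive, the "err on the side of caution"
#' convention).
#'
#' @param calls three panelist calls, see [panel_confidence()].
#' @param site_dx optional site diagnosis, `"pos"` or `"neg"` (`NA` if
#'   unavailable).
#' @return List with `confidence`, `assigned`
#'   (`"pos"`/`"neg"`/`"ind"`), `forced` (`"pos"`/`"neg"`), and `stratum`.
#' @export
classify_patient <- function(calls, site_dx = NA) {
  conf <- panel_confidence(calls)
  if (!is.na(site_dx)) panel_call_value(site_dx, "site_dx")
  assigned <- if (conf > 0.5 + 1e-9) "pos"
              else if (conf < 0.5 - 1e-9) "neg"
              else "ind"
  forced <- if (conf >= 0.5 - 1e-9) "pos" else "neg"
  definitive <- calls[calls != "ind"]
  tab <- table(factor(definitive, levels = c("neg", "pos")))
  unanimous <- length(definitive) == 3L && length(unique(definitive)) == 1L
  consensus <- any(tab >= 2L)
  stratum <- if (unanimous && !is.na(site_dx) && site_dx == assigned) {
    "super_unanimous"
  } else if (unanimous) {
    "unanimous"
  } else if (consensus) {
    "consensus"
  } else {
    "indeterminate"
  }
  list(confidence = conf, assigned = assigned, forced = forced,
       stratum = stratum)
}

#' Assess a table of panel calls
#'
#' Vectorised [classify_patient()] over a panel data frame (columns
#' `panelist1`, `panelist2`, `panelist3`, optional `site_dx`), appending
#' `confidence`, `assigned`, `forced`, `stratum` and the residual
#' uncertainty `p_wrong = 1 - max(confidence, 1 - confidence)` -- the
#' probability, under the panel's own confidence model, that the assigned
#' label is wrong. `p_wrong` lies in `[0, 1/2]`, reaching 1/2 exactly for
#' indeterminate patients.
#'
#' @param panel data frame of panel calls, e.g. from
#'   [generate_panel_data()] or [read_panel_csv()].
#' @return The input data frame with assessment columns appended.
#' @export
assess_panel <- function(panel) {
  need <- c("panelist1", "panelist2", "panelist3")
  if (!all(need %in% names(panel))) {
    stop("panel data must have columns panelist1..panelist3", call. = FALSE)
  }
  site <- if ("site_dx" %in% names(panel)) panel$site_dx else rep(NA, nrow(panel))
  res <- lapply(seq_len(nrow(panel)), function(i) {
    classify_patient(c(panel$panelist1[i], panel$panelist2[i],
                       panel$panelist3[i]),
                     site_dx = site[i])
  })
  panel$confidence <- vapply(res, `[[`, numeric(1), "confidence")
  panel$assigned <- vapply(res, `[[`, character(1), "assigned")
  panel$forced <- vapply(res, `[[`, character(1), "forced")
  panel$stratum <- vapply(res, `[[`, character(1), "stratum")
  panel$p_wrong <- 1 - pmax(panel$confidence, 1 - panel$confidence)
  panel
}

#' Comparator misclassification rates from panel assessments
#'
#' Estimates the comparator's expected misclassification rates as the mean
#' residual uncertainty within each assigned class: the FN rate is the
#' mean `p_wrong` over assigned positives (each such patient is flipped to
#' a comparator negative with that probability when noise is injected),
#' the FP rate the mean over assigned negatives, and the overall rate
#' their prevalence-weighted combination (see
#' [expected_overall_misclassification()]).
#'
#' @param assessments data frame from [assess_panel()].
#' @param labels use the `"assigned"` labels (indeterminate patients
#'   excluded) or the `"forced"` labels (all patients).
#' @return List with `fp_rate`, `fn_rate`, `overall`, `n_pos`, `n_neg`
#'   (counts of labelled positives/negatives). A rate over an empty class
#'   is `NA`.
#' @export
misclassification_rates <- function(assessments,
                                    labels = c("assigned", "forced")) {
  labels <- match.arg(labels)
  if (!all(c(labels, "p_wrong") %in% names(assessments))) {
    stop("run assess_panel() first", call. = FALSE)
  }
  lab <- assessments[[labels]]
  p <- assessments$p_wrong
  pos <- lab == "pos"
  neg <- lab == "neg"
  fn_rate <- if (any(pos)) mean(p[pos]) else NA_real_
  fp_rate <- if (any(neg)) mean(p[neg]) else NA_real_
  overall <- if (any(pos) && any(neg)) {
    expected_overall_misclassification(fp_rate, fn_rate,
                                       sum(neg), sum(pos))
  } else NA_real_
  list(fp_rate = fp_rate, fn_rate = fn_rate, overall = overall,
       n_pos = sum(pos), n_neg = sum(neg))
}

#' Nested agreement-stratum counts
#'
#' Counts patients at each finest stratum and the cumulative nested sets
#' (super-unanimous, unanimous, consensus, all-forced). The finest strata
#' partition the cohort: `super_unanimous + unanimous + consensus +
#' indeterminate = N`.
#'
#' @param assessments data frame from [assess_panel()].
#' @return List with `finest` (named counts) and `nested` (named counts of
#'   the cumulative sets).
#' @export
strata_counts <- function(assessments) {
  if (!"stratum" %in% names(assessments)) stop("run assess_panel() first", call. = FALSE)
  lv <- c("super_unanimous", "unanimous", "consensus", "indeterminate")
  finest <- table(factor(assessments$stratum, levels = lv))
  nested <- c(
    super_unanimous = sum(finest["super_unanimous"]),
    unanimous = sum(finest[c("super_unanimous", "unanimous")]),
    consensus = sum(finest[c("super_unanimous", "unanimous", "consensus")]),
    forced = sum(finest)
  )
  list(finest = c(finest), nested = nested)
}

#' Generate synthetic expert-panel data
#'
#' Emulates a three-panelist retrospective adjudication: each panelist
#' independently returns "ind" with probability `indeterminate_rate` and
#' otherwise a definitive call that contradicts the (hidden) ground truth
#' with probability `panelist_error`. The site diagnosis is always
#' definitive and wrong with probability `site_error`. The hidden truth is
#' retained in the output so that recovered misclassification rates can be
#' validated against the generative model.
#'
#' @param n_neg,n_pos numbers of ground-truth negative/positive patients.
#' @param panelist_error probability a definitive panelist call is wrong.
#' @param indeterminate_rate probability a panelist call is "ind".
#' @param seed integer RNG seed.
#' @param site_error error probability of the site diagnosis (defaults to
#'   `panelist_error`).
#' @return Data frame with columns `id`, `truth` (0/1, hidden ground
#'   truth), `panelist1..3`, `site_dx`.
#' @export
generate_panel_data <- function(n_neg, n_pos, panelist_error = 0.1,
                                indeterminate_rate = 0.1, seed = 1L,
                                site_error = panelist_error) {
  check_count(n_neg, "n_neg"); check_count(n_pos, "n_pos")
  if (n_neg + n_pos < 1L) stop("empty panel cohort", call. = FALSE)
  check_prob(panelist_error, "panelist_error")
  check_prob(indeterminate_rate, "indeterminate_rate")
  check_prob(site_error, "site_error")
  set.seed(seed)
  n <- n_neg + n_pos
  truth <- rep(c(0L, 1L), c(n_neg, n_pos))
  one_panelist <- function() {
    ind <- stats::runif(n) < indeterminate_rate
    wrong <- stats::runif(n) < panelist_error
    call <- ifelse(truth == 1L, "pos", "neg")
    call[wrong] <- ifelse(truth[wrong] == 1L, "neg", "pos")
    call[ind] <- "ind"
    call
  }
  p1 <- one_panelist(); p2 <- one_panelist(); p3 <- one_panelist()
  site_wrong <- stats::runif(n) < site_error
  site <- ifelse(truth == 1L, "pos", "neg")
  site[site_wrong] <- ifelse(truth[site_wrong] == 1L, "neg", "pos")
  data.frame(id = sprintf("p%04d", seq_len(n)), truth = truth,
             panelist1 = p1, panelist2 = p2, panelist3 = p3,
             site_dx = site, stringsAsFactors = FALSE)
}
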