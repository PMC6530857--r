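test_that("panel confidence is the mean of the mapped calls", {
  expect_equal(panel_confidence(c("pos", "pos", "pos")), 1)
  expect_equal(panel_confidence(c("neg", "neg", "neg")), 0)
  expect_equal(panel_confidence(c("pos", "pos", "ind")), 5 / 6)
  expect_equal(panel_confidence(c("pos", "ind", "neg")), 0.5)
  expect_true(panel_confidence(c("neg", "ind", "ind")) %in% ((0:6) / 6))
  expect_error(panel_confidence(c("pos", "pos")), "three")
  expect_error(panel_confidence(c("pos", "yes", "neg")), "'pos'")
})

test_that("classification follows the confidence and agreement rules", {
  r <- classify_patient(c("pos", "pos", "pos"), site_dx = "pos")
  expect_equal(r[c("assigned", "stratum")],
               list(assigned = "pos", stratum = "super_unanimous"))

  r <- classify_patient(c("pos", "pos", "pos"), site_dx = "neg")
  expect_equal(r$stratum, "unanimous")
  r <- classify_patient(c("pos", "pos", "pos"))
  expect_equal(r$stratum, "unanimous")

  r <- classify_patient(c("pos", "pos", "neg"))
  expect_equal(r[c("assigned", "stratum")],
               list(assigned = "pos", stratum = "consensus"))

  r <- classify_patient(c("pos", "ind", "neg"))
  expect_equal(r$confidence, 0.5)
  expect_equal(r$assigned, "ind")
  expect_equal(r$stratum, "indeterminate")
  expect_equal(r$forced, "pos") # tie rule: forced positive

  # all-indeterminate panel
  r <- classify_patient(c("ind", "ind", "ind"))
  expect_equal(r$assigned, "ind")
  expect_equal(r$stratum, "indeterminate")
})

test_that("all 27 call triples obey the stated invariants", {
  opts <- c("pos", "neg", "ind")
  grid <- expand.grid(opts, opts, opts, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    calls <- unlist(grid[i, ])
    r <- classify_patient(calls)
    conf <- r$confidence
    # assigned label tracks the confidence
    expect_equal(r$assigned,
                 if (conf > 0.5) "pos" else if (conf < 0.5) "neg" else "ind")
    expect_equal(r$forced, if (conf >= 0.5) "pos" else "neg")
    # positive<->negative swap symmetry
    swapped <- ifelse(calls == "pos", "neg", ifelse(calls == "neg", "pos", "ind"))
    rs <- classify_patient(swapped)
    expect_equal(rs$confidence, 1 - conf)
    expect_equal(rs$stratum, r$stratum)
    if (r$assigned != "ind") {
      expect_equal(rs$assigned, setdiff(c("pos", "neg"), r$assigned))
    }
  }
})

test_that("residual uncertainty and rates follow the worked example", {
  # two assigned positives (confidence 1 and 2/3), one assigned negative
  # (confidence 1/6)
  panel <- data.frame(
    panelist1 = c("pos", "pos", "neg"),
    panelist2 = c("pos", "pos", "neg"),
    panelist3 = c("pos", "neg", "ind")
  )
  a <- assess_panel(panel)
  expect_equal(a$confidence, c(1, 2 / 3, 1 / 6))
  expect_equal(a$p_wrong, c(0, 1 / 3, 1 / 6))
  r <- misclassification_rates(a)
  expect_equal(r$fn_rate, (0 + 1 / 3) / 2)
  expect_equal(r$fp_rate, 1 / 6)
  expect_equal(r$overall, (1 / 6 * 1 + 1 / 6 * 2) / 3)
  # overall is the prevalence-weighted mean, so lies between the rates
  expect_gte(r$overall, min(r$fp_rate, r$fn_rate))
  expect_lte(r$overall, max(r$fp_rate, r$fn_rate))

  # all-definitive unanimous panels carry no residual uncertainty
  sure <- assess_panel(data.frame(panelist1 = c("pos", "neg"),
                                  panelist2 = c("pos", "neg"),
                                  panelist3 = c("pos", "neg")))
  rs <- misclassification_rates(sure)
  expect_equal(c(rs$fp_rate, rs$fn_rate, rs$overall), c(0, 0, 0))
})

test_that("p_wrong is bounded by 1/2 and strata partition the cohort", {
  panel <- generate_panel_data(150, 100, panelist_error = 0.15,
                               indeterminate_rate = 0.2, seed = 8)
  a <- assess_panel(panel)
  expect_true(all(a$p_wrong >= 0 & a$p_wrong <= 0.5))
  expect_true(all(a$p_wrong[a$assigned == "ind"] == 0.5))
  cnt <- strata_counts(a)
  expect_equal(sum(cnt$finest), nrow(a))
  expect_equal(unname(cnt$nested["forced"]), nrow(a))
  expect_true(cnt$nested["super_unanimous"] <= cnt$nested["unanimous"])
  expect_true(cnt$nested["unanimous"] <= cnt$nested["consensus"])
})

test_that("an error-free panel is entirely super-unanimous and certain", {
  panel <- generate_panel_data(40, 40, panelist_error = 0,
                               indeterminate_rate = 0, seed = 2)
  a <- assess_panel(panel)
  expect_true(all(a$stratum == "super_unanimous"))
  expect_true(all(a$confidence %in% c(0, 1)))
  r <- misclassification_rates(a)
  expect_equal(c(r$fp_rate, r$fn_rate, r$overall), c(0, 0, 0))
  # assignments recover the hidden truth exactly
  expect_identical(a$assigned, ifelse(a$truth == 1, "pos", "neg"))
})

test_that("panelists emit indeterminate calls at the configured rate", {
  panel <- generate_panel_data(1700, 1700, panelist_error = 0.1,
                               indeterminate_rate = 0.12, seed = 4)
  calls <- c(panel$panelist1, panel$panelist2, panel$panelist3)
  n <- length(calls) # 10200 single-panelist calls
  phat <- mean(calls == "ind")
  expect_lt(abs(phat - 0.12), 3 * sqrt(0.12 * 0.88 / n))
})

test_that("the panel pipeline recovers the enumeration-oracle rates", {
  n_neg <- 2500; n_pos <- 2500
  panel <- generate_panel_data(n_neg, n_pos, panelist_error = 0.1,
                               indeterminate_rate = 0.1, seed = 12)
  a <- assess_panel(panel)
  r <- misclassification_rates(a)
  for (label in c("pos", "neg")) {
    target <- enumeration_mean_p_wrong(label, n_neg, n_pos,
                                       error = 0.1, ind_rate = 0.1)
    sel <- a$assigned == label
    se <- stats::sd(a$p_wrong[sel]) / sqrt(sum(sel))
    est <- if (label == "pos") r$fn_rate else r$fp_rate
    expect_lt(abs(est - target), 3 * se)
  }
})
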