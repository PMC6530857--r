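test_that("rank AUC matches hand-worked and degenerate cases", {
  expect_equal(auc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_true(is.na(auc(1:4, c(1, 1, 1, 1)))) # single class: flagged missing
  expect_error(auc(1:3, c(0, 1)), "lengths")
})

test_that("rank AUC equals the O(n^2) pairwise oracle exactly", {
  set.seed(1)
  for (case in 1:25) {
    n_pos <- sample(1:25, 1)
    n_neg <- sample(1:25, 1)
    labels <- rep(c(0L, 1L), c(n_neg, n_pos))
    # mix continuous and heavily tied scores
    scores <- if (case %% 2 == 0) rnorm(n_neg + n_pos)
              else sample(1:4, n_neg + n_pos, replace = TRUE)
    expect_identical(auc(scores, labels), auc_pairwise(scores, labels))
  }
})

test_that("AUC complements under score negation when tie-free", {
  set.seed(2)
  for (i in 1:10) {
    labels <- rep(c(0L, 1L), c(15, 10))
    scores <- rnorm(25)
    expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
  }
})

test_that("confusion metrics follow the 2x2 identities", {
  calls <- rep(c(1, 0, 0, 1), c(97, 3, 85, 15))
  labels <- rep(c(1, 0), c(100, 100))
  m <- confusion_metrics(calls, labels)
  expect_equal(m$ppa, 0.970)
  expect_equal(m$npa, 0.850)
  expect_equal(round(m$ppv, 3), 0.866)
  expect_equal(round(m$npv, 3), 0.966)

  m2 <- confusion_metrics(c(1, 1, 1, 0), c(1, 1, 0, 0))
  expect_equal(m2$ppa, 1)
  expect_equal(m2$npa, 0.5)
  expect_equal(m2$ppv, 2 / 3)
  expect_equal(m2$npv, 1)

  ident <- confusion_metrics(labels, labels)
  expect_equal(unlist(ident[c("ppa", "npa", "ppv", "npv")]),
               c(ppa = 1, npa = 1, ppv = 1, npv = 1))
})

test_that("confusion metrics are order-invariant and role-symmetric", {
  set.seed(3)
  calls <- rbinom(60, 1, 0.4)
  labels <- rbinom(60, 1, 0.5)
  m <- confusion_metrics(calls, labels)
  perm <- sample(60)
  mp <- confusion_metrics(calls[perm], labels[perm])
  expect_equal(m, mp)
  # swapping calls and labels swaps PPA<->PPV, NPA<->NPV
  ms <- confusion_metrics(labels, calls)
  expect_equal(ms$ppa, m$ppv)
  expect_equal(ms$ppv, m$ppa)
  expect_equal(ms$npa, m$npv)
  expect_equal(ms$npv, m$npa)
})

test_that("empty denominators yield NA, never zero", {
  m <- confusion_metrics(c(1, 1, 0), c(1, 1, 1))
  expect_true(is.na(m$npa))
  expect_equal(m$ppa, 2 / 3)
  expect_equal(m$npv, 0) # defined (tn = 0, fn = 1), genuinely zero
  m2 <- confusion_metrics(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(m2$npa))
  expect_true(is.na(m2$npv))
})

test_that("bootstrap interval degenerates for a constant metric", {
  co <- make_perfect_cohort(30, 30, seed = 1)
  ci <- bootstrap_ci(co, metric = "ppa", n_boot = 200, seed = 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  expect_identical(ci$n_undefined, 0L)
})

test_that("bootstrap percentile interval has near-nominal coverage", {
  # Bernoulli(0.8) proportion as a PPA problem: truth all positive,
  # calls hit at rate 0.8; scaled-down coverage study
  set.seed(10)
  n <- 100
  covered <- 0
  n_outer <- 200
  for (i in seq_len(n_outer)) {
    call <- rbinom(n, 1, 0.8)
    co <- cohort(truth = rep(1L, n), score = ifelse(call == 1, 0.8, 0.2),
                 call = call)
    ci <- bootstrap_ci(co, metric = "ppa", n_boot = 400, seed = 1000 + i)
    if (ci$lower <= 0.8 && 0.8 <= ci$upper) covered <- covered + 1
  }
  expect_gt(covered / n_outer, 0.85)
  expect_lte(covered / n_outer, 1)
})

test_that("worked-example intervals match the printed exact-binomial bounds", {
  # 97/100 -> 0.970 (0.915-0.994); 85/88 -> 0.966 (0.904-0.993)
  ci <- binomial_ci(97, 100)
  expect_equal(round(ci$lower, 3), 0.915)
  expect_equal(round(ci$upper, 3), 0.994)
  ci2 <- binomial_ci(85, 88)
  expect_equal(round(ci2$lower, 3), 0.904)
  expect_equal(round(ci2$upper, 3), 0.993)

  # the patient-resampling bootstrap is close but not identical
  co <- table1_cohort()
  bs <- bootstrap_ci(co, metric = "ppa", n_boot = 2000, seed = 4)
  expect_lt(bs$lower, 0.97)
  expect_gte(bs$upper, 0.97)
  expect_lt(abs(bs$lower - 0.915), 0.03)
  expect_lt(abs(bs$upper - 0.994), 0.02)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    labels <- rep(c(0L, 1L), c(40, 30))
    scores <- round(rnorm(70), 1) # introduces ties
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(scores, labels), ref)
  }
})

test_that("evaluate_test combines AUC and agreement metrics", {
  co <- table1_cohort()
  m <- evaluate_test(co)
  expect_equal(m$ppa, 0.97)
  expect_false(is.na(m$auc))
  cl <- inject_uniform(co$truth, 0.05, seed = 1)
  m2 <- evaluate_test(co, cl)
  expect_identical(m2$tp + m2$fn, sum(cl$comparator == 1L))
})
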