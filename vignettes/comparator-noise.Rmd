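---
title: "Comparator noise and apparent diagnostic performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparator noise and apparent diagnostic performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comparatornoise)
```

## The problem

A diagnostic evaluation trial judges a new test against a comparator — an
established reference assumed to reflect each patient's true state. Real
comparators contain *classification noise*: random, non-systematic
divergence from ground truth, arising from measurement variability,
incomplete information, or disagreement between adjudicating clinicians.
Every disagreement between a good test and a noisy comparator is booked
against the test, so apparent performance measures systematically
underestimate true performance. This package provides the two complementary
ways of quantifying that effect — Monte-Carlo simulation of noise injection,
and closed-form expectations — plus a model of expert-panel comparators
whose noise level can be estimated from panelist discordance.

Only *random* noise is modelled. Systematic reference bias — the comparator
being wrong in a correlated way for particular kinds of patients, possibly
shared with the test under evaluation — can inflate rather than deflate
apparent performance and is explicitly out of scope: it cannot be estimated
from label data alone.

## Cohort models

A cohort is a data frame of patients with a binary ground truth, a
continuous test score (higher = more positive) and a binary test call;
calls relate to scores through a threshold with ties called positive.
Three generators cover the canonical scenarios:

* `make_perfect_cohort()`: negative scores uniform on [0, 0.4], positive on
  [0.6, 1]. Any disjoint pair of bands satisfies the contract (AUC exactly
  1, calls equal truth); uniform bands keep score plots legible.
* `make_binormal_cohort()`: the equal-variance binormal ROC model. Negatives
  are N(0, 1), positives N(δ, 1) with δ = √2 · Φ⁻¹(AUC), the standard
  biostatistical convention for "slightly overlapping" score distributions
  with a prescribed population AUC. The threshold defaults to δ/2.
* `make_called_cohort()`: fixes the test's margins exactly —
  `round_half_up(se · n_pos)` positives and `round_half_up(sp · n_neg)`
  negatives receive correct calls, the particular patients chosen at
  random. This makes worked-example confusion tables (e.g. TP = 97, FN = 3,
  TN = 85, FP = 15 for a 0.97/0.85 test on 100/100 patients) bit-stable
  across platforms and seeds.

All count targets use round-half-away-from-zero rather than base R's
round-half-to-even, so 2.5 expected flips become 3 deterministically; the
realized proportions therefore differ from nominal ones by up to 1/(2n),
which matters when validating simulations against closed forms (see below).

## Noise injection

Comparator labels start from ground truth and are degraded by one of three
schemes, all flipping an **exact count** of labels:

* *uniform*: `round_half_up(rate · N)` patients drawn uniformly from the
  pooled cohort — positives and negatives equally likely, so the realized
  FP/FN split is hypergeometric and contributes to interval width;
* *class rates*: exact per-class counts at the FP rate (true negatives
  labelled positive) and FN rate (true positives labelled negative);
* *weighted*: patients drawn without replacement with probability
  proportional to a per-patient weight, intended to be the residual
  uncertainty of an expert-panel classification — patients classified with
  more certainty are less likely to be mislabelled. Sampling uses base R's
  sequential weighted draw with renormalization, which is seed-stable
  across platforms. Without-replacement is the only sensible choice here: a
  patient has one label, flipped or not.

Exact-count flipping makes the x-axis of a noise sweep exact: a "5% noise"
column really contains 5% flipped labels in every iteration, and the flip
count is deterministic given (N, rate) — only the identity of the flipped
patients varies. A per-patient Bernoulli variant
(`noise_uniform(rate, exact = FALSE)`) is also provided; under it the
realized total varies binomially, which widens the iteration-to-iteration
spread of apparent metrics by a visible margin at n = 200. Both mechanisms
give the same medians; the Bernoulli spread at 10% noise on the perfect
100/100 cohort reproduces the wider empirical intervals seen in
evaluations that treat "5% noise" as a per-patient probability. Injections
are never silently chained: applying ε twice is *not* 2ε, because flips
can cancel.

## Metrics

AUC is the Mann–Whitney rank statistic — the mean over all
positive–negative pairs of 1 (test orders the pair correctly), ½ (tied
scores), 0 — computed in O(n log n) via midranks. The O(n²) pairwise loop
is kept in the test suite as an oracle and checked for exact equality, and
the implementation is additionally cross-checked against an established
ROC package on tied data.

The four ratio metrics are reported as *agreement* measures — positive and
negative percent agreement (computed identically to sensitivity and
specificity), PPV and NPV — because against a noisy comparator they measure
agreement with the comparator, not accuracy against truth. Empty
denominators yield `NA` with a recorded count, never a silent zero: a
resampled or heavily flipped cohort can genuinely lack comparator
positives.

Two interval methods are provided. `bootstrap_ci()` resamples whole
patients with replacement and takes the percentile interval (default 2000
replicates — a conventional choice; the replicate count is a parameter).
`binomial_ci()` is the exact Clopper–Pearson interval of a single
proportion; it is the method that reproduces printed worked-example
intervals such as 0.970 (0.915–0.994) for 97/100, which a percentile
bootstrap approximates but does not match at the third decimal.

## The Monte-Carlo engine

`run_iterations()` redraws comparator labels and re-scores the test
`n_iter` times (default 100, the conventional reporting choice for these
sweeps; acceptance-grade comparisons in the test suite use 1000–10000).
Aggregation is the median with the empirical 2.5th–97.5th percentile
interval across iterations — not mean ± SD — because apparent-metric
distributions are skewed near performance ceilings. At zero noise every
iteration is identical and the interval has width exactly zero; the
bootstrap interval of the noise-free estimate is available separately and
answers a different question (sampling uncertainty rather than
injection uncertainty).

Seeding is counter-based: each level (or trial size) of a sweep derives
its own seed from the master seed and level index, and all iterations
within a level consume that single stream. Two properties follow, both
tested: the same master seed reproduces a sweep bit-for-bit, and extending
the level grid or iteration count does not perturb existing results. A
design worth recording: iterations do *not* get one fresh seed each,
because reseeding a Mersenne–Twister with closely spaced seeds correlates
the first draws across iterations — measured on this code, it biased
10,000-iteration means by tens of Monte-Carlo standard errors.

## Closed-form expectations

Because flip selection is independent of the test result, each apparent
metric is a mixture over the composition of its denominator margin. The
expected apparent PPA, for example, mixes unflipped true positives
(test-positive at rate se) with flipped true negatives (test-positive at
rate 1 − sp):

$$\mathrm{PPA}_{app} = \frac{(1-fn)\,n_{pos}\,se + fp\,n_{neg}\,(1-sp)}
{(1-fn)\,n_{pos} + fp\,n_{neg}}$$

and analogously for NPA, PPV, NPV. For AUC, with contaminated fractions
*a* (of comparator positives) and *b* (of comparator negatives), pairs
from the same true class contribute ½ in expectation (within-class scores
are exchangeable with respect to flip selection) and reversed pairs
contribute 1 − A:

$$\mathrm{AUC}_{app} = (1-a)(1-b)A + \left[(1-a)b + a(1-b)\right]\tfrac12 + ab(1-A)$$

Under exact-count class-rate injection the comparator margins are
constants, so these are *exact* expectations of the simulated metrics —
the simulator and the closed forms are dual implementations that
cross-validate each other to within three Monte-Carlo standard errors at
10,000 iterations (tested over a grid of margins, rates and prevalences).
Two subtleties make that agreement exact rather than approximate: the
closed forms must be evaluated at the *realized* (rounded) proportions,
and finite-cohort AUC comparisons must anchor at the cohort's empirical
noise-free AUC rather than the population target.

For a perfect test on a balanced cohort with symmetric rate ε both
families collapse to 1 − ε — the performance ceiling no test can exceed.
`relative_error()` re-expresses degradation as (1 − AUC)/(1 − AUC₀); at
low prevalence the comparator-positive margin is contaminated quickly, so
relative error rises very steeply at small ε and then saturates —
markedly non-linear, which defeats linear extrapolation from a
low-noise measurement.

`rejection_probability()` addresses very-high-performance requirements:
for a perfect test, agreement with the comparator among n labelled
patients is Binomial(n, per-label accuracy), so the probability that the
observed point estimate falls below a required level is an exact binomial
tail. The class size n is a parameter (it is trial-specific), and the
requirement is applied to the point estimate, not a confidence bound —
the simpler and stricter reading; a CI-bound version would only lower the
rejection probability further at these magnitudes.

## Expert-panel comparators

The panel model mirrors three-clinician retrospective adjudication: calls
in {positive, indeterminate, negative} map to probabilities {1, ½, 0} and
average to a per-patient confidence on the 0–1 scale (seven attainable
values, k/6). The assigned label follows the confidence (indeterminate at
exactly ½); the agreement stratum is nested — super-unanimous (all three
panelists agree definitively and the site diagnosis concurs), unanimous,
consensus (two-of-three), indeterminate — and the finest strata partition
the cohort.

Residual uncertainty is `p_wrong = 1 − max(c, 1 − c)`: the probability,
under the panel's own confidence model, that the assigned label is wrong.
It is probability-scaled (entropy-style alternatives are not), bounded by
½, and reaches ½ exactly for indeterminate patients. Mean `p_wrong` over
assigned positives estimates the comparator's FN rate (those labels flip
to negative when wrong), over assigned negatives the FP rate, and the
prevalence-weighted combination gives the overall expected
misclassification rate. These per-patient values are exactly the weights
meant for `inject_weighted()`, closing the loop from observed panel
discordance to simulated performance degradation.

Decisions where the underlying convention is genuinely open, each isolated
behind one predicate:

* patients at confidence exactly ½ receive a *forced* label of positive
  (the clinical err-on-the-side-of-caution convention for serious
  treatable conditions); all analyses can use either the assigned labels
  (indeterminates excluded) or the forced labels (everyone classified);
* confidence averages the three mapped calls per patient (rather than
  aggregating per panelist first) — with three equally weighted panelists
  the distinction only matters for absent calls, which the data model
  does not allow.

`generate_panel_data()` emulates the adjudication generatively: each
panelist is independently indeterminate with rate q and otherwise wrong
with probability e; the site diagnosis is always definitive with its own
error rate. The generator retains the hidden truth, and the pipeline's
rate estimates are validated against exact enumeration over the 27
call-triple probabilities (5000-patient panels, three-standard-error
agreement). Two things the generator deliberately does not emulate:
panelist non-independence (real clinicians share information sources, so
real panels are likely *overconfident* — residual uncertainty
underestimates the true error rate), and case-difficulty structure
(indeterminacy concentrated in particular patient subsets). Passing tests
therefore show the pipeline recovers the rates of the stated generative
model, not that three-clinician panels are well calibrated in the field.
Relatedly, mean residual uncertainty equals the true wrong-assignment
probability only when the confidence model is calibrated; under this
generator the two are close but not identical, and the package estimates
the former — the quantity a trial can actually compute from its own
panel data.

## Numerical and interface conventions

* Thresholded calls: score ≥ threshold is positive (ties positive).
* Count rounding: half away from zero, everywhere, documented above.
* Percentile intervals use the default empirical quantile; at 100
  iterations the 2.5th/97.5th percentiles interpolate adjacent order
  statistics.
* Level grids parse as `start:stop:step`, inclusive of both ends within
  1e-9.
* CSV dialect: comma-separated, UTF-8, `.` decimal, mandatory header.
  Malformed panel rows are reported with line numbers; nothing is dropped
  silently. JSON manifests sort keys recursively for diff-stability.
* All stochastic entry points take an explicit integer seed; equal seeds
  give identical output.

## Problem sizes

The default study conditions are balanced 100/100 cohorts with 100
iterations per noise level, matching the scale at which these effects are
typically reported. The test suite uses 1000–2000 iterations where a
median must be located to ±0.01, 10,000 where simulation means are
compared to closed forms at three-standard-error precision, 5000-patient
panels for rate recovery, and trial sizes 50–800 for the
interval-shrinkage law (width ∝ n^(−1/2) for agreement metrics, verified
as a log–log slope of −0.5 ± 0.15).

## Limitations

* Binary states only; no covariate-dependent scores, no time-to-event
  outcomes, no multiclass adjudication.
* Noise is non-differential by construction (flip probability independent
  of the score); differential or correlated misclassification, including
  reference bias shared with the test, is out of scope.
* The package quantifies distortion; it does not invert it. Deconvolving
  true performance from apparent performance (latent-class or Bayesian
  correction) is deliberately not attempted.
* Panelist independence is assumed in the generator and the enumeration
  oracle; correlated panels make recovered rates optimistic.
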