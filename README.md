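# comparatornoise

When a new diagnostic test is evaluated, its output is compared against an
established reference — a "gold standard" that is, in practice, an imperfect
**comparator**. If the comparator misclassifies even a few percent of
patients, every apparent performance measure of the new test (ROC AUC,
sensitivity/PPA, specificity/NPA, PPV, NPV) is dragged down, no matter how
good the test really is. `comparatornoise` quantifies that distortion, for
trial statisticians and diagnostic developers who need to know whether an
observed performance shortfall is a property of their test or of their
comparator.

## What it computes

**Simulation.** Synthetic cohorts (perfectly separated scores, equal-variance
binormal scores with a target AUC, or fixed sensitivity/specificity calls)
are evaluated against comparator labels into which misclassification is
injected — uniformly over the cohort, at class-specific FP/FN rates, or
weighted by per-patient uncertainty. Each noise level is injected repeatedly
(default 100 iterations) and summarised as the median with an empirical 95%
interval, the spread a single trial would fall in.

**Closed forms.** Because flips are independent of the test result, apparent
metrics have mixture expectations. With a fraction *a* of comparator
positives that are truly negative and *b* of comparator negatives that are
truly positive, a test of true AUC *A* has expected apparent AUC

    (1 − a)(1 − b)·A + [(1 − a)b + a(1 − b)]·½ + ab·(1 − A)

which for a perfect test on a balanced cohort under symmetric
misclassification rate ε reduces to **1 − ε**: a 10% comparator error caps
any test's apparent AUC at 0.90. Expected apparent PPA/NPA/PPV/NPV follow
from the analogous 2×2 mixtures (`expected_apparent_metrics()`), and the
probability that a *perfect* test fails a performance requirement (e.g. 99%
PPA) under a given per-label comparator accuracy is an exact binomial tail
(`rejection_probability()`).

**Expert panels.** For comparators built from three blinded expert
adjudications, `panel_confidence()` maps calls (positive → 1,
indeterminate → ½, negative → 0) to a per-patient probability of disease,
`classify_patient()` derives the assigned label and the agreement stratum
(super-unanimous ⊆ unanimous ⊆ consensus; indeterminate otherwise), and
`misclassification_rates()` turns residual uncertainty into the comparator's
expected FP/FN rates, ready to feed back into weighted noise injection
(`inject_weighted()`). `generate_panel_data()` simulates such panels so the
whole pipeline is testable without trial data.

## Worked example

A test with true sensitivity 0.97 and specificity 0.85 on 100 diseased and
100 healthy patients, evaluated first against ground truth and then against
a comparator that misclassifies a random 5% of patients:

```r
library(comparatornoise)
co <- make_called_cohort(n_neg = 100, n_pos = 100, se = 0.97, sp = 0.85, seed = 1)
evaluate_test(co)
#> TP 97  FP 15  TN 85  FN 3
#>    auc    ppa    npa    ppv    npv
#> 0.9030 0.9700 0.8500 0.8661 0.9659

run_iterations(co, noise_uniform(0.05), n_iter = 1000, seed = 42)
#> Noise run: 1000 iterations, seed 42
#>   metric    median  ci_lower  ci_upper n_missing unstable
#> 1    auc 0.8623123 0.8402361 0.8913608         0    FALSE
#> 2    ppa 0.9285714 0.9038462 0.9583333         0    FALSE
#> 3    npa 0.8100000 0.7830189 0.8404255         0    FALSE
#> 4    ppv 0.8303571 0.7946429 0.8660714         0    FALSE
#> 5    npv 0.9204545 0.8863636 0.9545455         0    FALSE
```

Five percent comparator noise makes the 97%-sensitive test *appear* 92.9%
sensitive (median PPA 0.929, matching the closed form
`expected_apparent_metrics(0.97, 0.85, 100, 100, 0.05, 0.05)$ppa`), with
every other metric degraded similarly. The ceiling imposed on *any* test:

```r
analytic_table(c(0, 0.05, 0.10, 0.20))
#>    eps  auc  ppa  npa  ppv  npv
#> 1 0.00 1.00 1.00 1.00 1.00 1.00
#> 2 0.05 0.95 0.95 0.95 0.95 0.95
#> 3 0.10 0.90 0.90 0.90 0.90 0.90
#> 4 0.20 0.80 0.80 0.80 0.80 0.80
```

And a 99% PPA requirement judged against 1000 comparator-positive patients
whose labels are each 95% reliable rejects a *perfect* test almost surely:

```r
rejection_probability(n_labelled = 1000, required = 0.99, per_label_accuracy = 0.95)
#> 0.9999999999972  (i.e. > 99.999%)
```

## Command line

A thin CLI wraps the same functions (installed to `exec/`):

```sh
comparatornoise sweep --n-neg 100 --n-pos 100 --shape perfect \
    --levels 0:0.2:0.01 --iters 100 --seed 42 --out sweep.csv
comparatornoise analytic --levels 0:0.2:0.01 --require 0.99 --accuracy 0.95
comparatornoise simulate-panel --n-neg 200 --n-pos 200 --error 0.1 --out panel.csv
comparatornoise panel --input panel.csv --out assessed.csv
```

Every run writes a JSON manifest from which its outputs reproduce
bit-for-bit.

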