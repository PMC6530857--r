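# Independent oracles used across the suite. Each reimplements a quantity
# by brute force or enumeration, deliberately avoiding the package's own
# computation path.

# O(n^2) pairwise AUC: mean over all positive-negative pairs of
# 1/0.5/0 for win/tie/loss.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exact rejection probability by explicit summation over all binomial
# outcomes (feasible for small n).
rejection_bruteforce <- function(n, required, accuracy) {
  k_needed <- ceiling(required * n)
  prob_pass <- 0
  for (k in 0:n) {
    if (k >= k_needed) {
      prob_pass <- prob_pass + choose(n, k) * accuracy^k * (1 - accuracy)^(n - k)
    }
  }
  1 - prob_pass
}

# The Table-1 worked-example cohort: 100 ground-truth positives of which
# 97 test positive, 100 negatives of which 85 test negative.
table1_cohort <- function(seed = 3L) {
  make_called_cohort(100, 100, se = 0.97, sp = 0.85, seed = seed)
}

# Exact enumeration over the 27 panelist call triples for one patient of
# known truth: per-triple probability, confidence, assigned label and
# residual uncertainty, under independent panelists that emit "ind" with
# probability q and otherwise err with probability e.
panel_triple_enumeration <- function(truth, error, ind_rate) {
  correct <- if (truth == 1) "pos" else "neg"
  wrong <- if (truth == 1) "neg" else "pos"
  call_prob <- function(call) {
    if (call == "ind") ind_rate
    else if (call == correct) (1 - ind_rate) * (1 - error)
    else (1 - ind_rate) * error
  }
  opts <- c("pos", "neg", "ind")
  grid <- expand.grid(p1 = opts, p2 = opts, p3 = opts,
                      stringsAsFactors = FALSE)
  val <- c(pos = 1, neg = 0, ind = 0.5)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    calls <- unlist(grid[i, ])
    prob <- prod(vapply(calls, call_prob, numeric(1)))
    conf <- mean(val[calls])
    assigned <- if (conf > 0.5) "pos" else if (conf < 0.5) "neg" else "ind"
    data.frame(prob = prob, confidence = conf, assigned = assigned,
               p_wrong = 1 - max(conf, 1 - conf))
  })
  do.call(rbind, out)
}

# Population mean residual uncertainty among patients assigned to `label`,
# mixing true-positive and true-negative patients.
enumeration_mean_p_wrong <- function(label, n_neg, n_pos, error, ind_rate) {
  en_pos <- panel_triple_enumeration(1, error, ind_rate)
  en_neg <- panel_triple_enumeration(0, error, ind_rate)
  w_pos <- n_pos / (n_pos + n_neg)
  num <- w_pos * sum(en_pos$prob * en_pos$p_wrong * (en_pos$assigned == label)) +
    (1 - w_pos) * sum(en_neg$prob * en_neg$p_wrong * (en_neg$assigned == label))
  den <- w_pos * sum(en_pos$prob * (en_pos$assigned == label)) +
    (1 - w_pos) * sum(en_neg$prob * (en_neg$assigned == label))
  num / den
}
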