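# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths they check.

# One-sided (over-representation) Fisher p-value by direct hypergeometric
# enumeration: sum of dhyper over all tables at least as extreme.
oracle_fisher_one_sided <- function(k_set, n_set, k_rest, n_rest) {
  total_on <- k_set + k_rest
  n_total <- n_set + n_rest
  ks <- k_set:min(n_set, total_on)
  sum(stats::dhyper(ks, total_on, n_total - total_on, n_set))
}

# Two-sided rank-sum p-value by complete enumeration of all C(m+n, m)
# assignments of the pooled ranks to the first group (no ties assumed).
oracle_ranksum_exact <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2L, function(idx) sum(r[idx])) - m * (m + 1) / 2
  mu <- m * n / 2
  # two-sided: doubled smaller tail, capped at 1 (matches the exact test)
  if (w_obs > mu) {
    p <- 2 * mean(ws >= w_obs)
  } else if (w_obs < mu) {
    p <- 2 * mean(ws <= w_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# Benjamini-Hochberg by the direct definition q_(i) = min_{k>=i} m p_(k)/k.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * ps[i:m] / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Weighted Tanimoto by explicit per-bit loops.
oracle_weighted_tanimoto <- function(a, b, w, idx = seq_along(a)) {
  num <- 0
  den <- 0
  for (i in idx) {
    if (a[i] == 1 && b[i] == 1) num <- num + w[i]
    if (a[i] == 1 || b[i] == 1) den <- den + w[i]
  }
  if (den == 0) 0 else num / den
}

# ROC AUC by O(n^2) pair counting with half-credit ties.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (a in sp) {
    for (b in sn) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(sp) * length(sn))
}

# Confusion metrics by independent arithmetic.
oracle_metrics <- function(tp, tn, fp, fn) {
  pre <- tp / (tp + fp)
  sen <- tp / (tp + fn)
  list(
    ACC = (tp + tn) / (tp + tn + fp + fn),
    SEN = sen,
    SPE = tn / (tn + fp),
    PRE = pre,
    F1 = 2 * pre * sen / (pre + sen)
  )
}

# Best-F1 threshold by direct double loop over candidates.
oracle_f1_best <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(c(min(scores) - 1, scores)))
  best_f1 <- -1
  best_t <- NA
  for (t in cand) {
    call <- scores > t
    tp <- sum(call & labels)
    fp <- sum(call & !labels)
    fn <- sum(!call & labels)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1) {
      best_f1 <- f1
      best_t <- t
    }
  }
  list(threshold = best_t, f1 = best_f1)
}
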