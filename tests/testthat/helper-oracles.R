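# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) pairwise Mann-Whitney statistic: P(score_pos > score_neg) + ties/2
pairwise_auc_oracle <- function(scores, truth, positive_label = 0) {
  sp <- scores[truth == positive_label]
  sn <- scores[truth != positive_label]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# exhaustive-threshold ROC enumeration: every distinct score as a cutoff,
# predicted positive means score >= cutoff
roc_enumeration_oracle <- function(scores, truth, positive_label = 0) {
  pos <- truth == positive_label
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    pts <- rbind(pts, data.frame(fpr = sum(pred & !pos) / sum(!pos),
                                 tpr = sum(pred & pos) / sum(pos)))
  }
  pts
}

# closed-form mean and sd of a normal truncated to [lo, hi]
truncnorm_moments <- function(mean, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- if (is.finite(a)) dnorm(a) else 0
  db <- if (is.finite(b)) dnorm(b) else 0
  m <- mean + sd * (da - db) / Z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# asymptotic standard error of a sample quantile at probability p
quantile_se <- function(p, n, density_at_q) {
  sqrt(p * (1 - p) / n) / density_at_q
}
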