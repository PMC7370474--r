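#!/usr/bin/env Rscript
# Stage 3 — the classifier x validation-scheme benchmark grid.
#
# Runs all seven baseline classifiers over the nine validation schemes
# (hold-out 80/20, 70/30, 60/40; 5/10/15-fold CV; bootstrap subsets of
# 50/100/200), once with the dual variables treated as numerical and once
# as categorical, on the simulated cohort restricted to its Relief-F top
# 10 features. Writes the two wide accuracy/AUC tables.

library(ihdforest)

seed <- 20203L
co <- read_cohort("results/cohort.csv")
w <- relief_f_weights(co, relief_config(k = 10, seed = seed))
selected <- top_k(w, 10)
if (!any(c("asa", "hypertension") %in% selected)) {
  cat("note: neither dual-encoded variable (asa, hypertension) survived\n",
      "Relief-F selection on this cohort, so the two encodings coincide\n")
}

for (enc in c("numerical", "categorical")) {
  rep <- run_benchmark(co, default_schemes(), default_classifiers(),
                       encoding = enc, features = selected, seed = seed)
  stopifnot(!any(rep$grid$failed))
  out <- sprintf("results/benchmark_%s.csv", enc)
  write.csv(benchmark_table(rep), out, row.names = FALSE)
  best <- rep$grid[which.max(rep$grid$auc), ]
  cat(sprintf("%s encoding: best AUC %.4f (%s, %s); wrote %s\n",
              enc, best$auc, best$classifier, best$scheme, out))
}
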