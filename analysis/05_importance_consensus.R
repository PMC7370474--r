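#!/usr/bin/env Rscript
# Stage 5 — variable importance and the consensus risk-factor set.
#
# Computes MDA (out-of-bag permutation) and MDG (Gini) importance from the
# balanced random forest retrained on the full simulated cohort, joins the
# Relief-F weights, applies the top-5 / >= 2-lists consensus rule, and —
# as the reference result — applies the same rule to the published score
# tables, which recovers the study's five risk factors.

library(ihdforest)

seed <- 20205L
co <- read_cohort("results/cohort.csv")
w <- relief_f_weights(co, relief_config(k = 10, seed = seed))
selected <- top_k(w, 10)

model <- train_brf(co, brf_config(m = 21, trees_per_forest = 100,
                                  seed = seed), features = selected)
mda_s <- mda(model, permutations = 10, seed = seed)
mdg_s <- mdg(model)
relief_s <- setNames(w$weight, w$feature)[names(mda_s)]

tab <- importance_table(mda_s, mdg_s, relief_s)
write.csv(tab, "results/importance_synthetic.csv", row.names = FALSE)
sel_syn <- consensus_select(mda_s, mdg_s, relief_s, k = 5, min_lists = 2)
cat("synthetic-cohort consensus set:", paste(sel_syn, collapse = ", "), "\n")

t5 <- load_table5_scores()
sel_pub <- consensus_select(t5$mda, t5$mdg, t5$relief, k = 5, min_lists = 2)
write.csv(data.frame(rank = seq_along(sel_pub), feature = sel_pub),
          "results/consensus_published.csv", row.names = FALSE)
cat("published-scores consensus set:", paste(sel_pub, collapse = ", "), "\n")
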