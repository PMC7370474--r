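test_that("confusion matrix tallies every pair once, under the y=0-positive convention", {
  cm <- confusion(c(0, 0, 0), c(0, 0, 0), positive_label = 0)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(3, 0, 0, 0))

  # reconstruct the published hold-out test set from its marginals:
  # 114 patients, 85 TP / 2 FP / 15 FN / 12 TN with positive = no-IHD (0)
  truth <- rep(c(0, 1, 0, 1), c(85, 2, 15, 12))
  predicted <- rep(c(0, 0, 1, 1), c(85, 2, 15, 12))
  cm4 <- confusion(truth, predicted, positive_label = 0)
  expect_equal(c(cm4$tp, cm4$fp, cm4$fn, cm4$tn), c(85, 2, 15, 12))

  # flipping the positive class transposes TP<->TN and FP<->FN
  cm_flip <- confusion(truth, predicted, positive_label = 1)
  expect_equal(c(cm_flip$tp, cm_flip$fp, cm_flip$fn, cm_flip$tn),
               c(cm4$tn, cm4$fn, cm4$fp, cm4$tp))

  expect_error(confusion(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(confusion(c(0, 1, 2), c(0, 1, 2)), "binary")
})

test_that("metric formulas match their definitions, with flagged undefined values", {
  ms <- metric_set(confusion_from_counts(85, 2, 15, 12))
  expect_equal(ms$total, 114)
  expect_equal(ms$accuracy, 97 / 114)
  expect_equal(round(ms$accuracy, 4), 0.8509)
  expect_equal(ms$tpr, 85 / 100)
  expect_equal(ms$tnr, 12 / 14)
  expect_equal(ms$ppv, 85 / 87)
  expect_equal(ms$fpr, 2 / 14)

  expect_equal(round(f1_score(0.8557, 0.954), 4), 0.9022)

  und <- metric_set(confusion_from_counts(0, 3, 0, 5))
  expect_true(is.na(und$tpr))
  expect_true("tpr" %in% attr(und, "undefined"))
  expect_false("accuracy" %in% attr(und, "undefined"))
})

test_that("ROC curves match exhaustive threshold enumeration", {
  # perfectly separating scores pass through (0, 1)
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1), positive_label = 0)
  expect_true(any(r$fpr == 0 & r$tpr == 1))

  # all scores tied: the two-point diagonal
  r2 <- roc_curve(rep(0.5, 6), c(0, 1, 0, 1, 0, 1), positive_label = 0)
  expect_equal(r2$fpr, c(0, 1))
  expect_equal(r2$tpr, c(0, 1))

  # hand case against the enumeration oracle
  sc <- c(0.9, 0.8, 0.7, 0.6)
  tr <- c(0, 0, 1, 0)
  got <- roc_curve(sc, tr, positive_label = 0)
  want <- roc_enumeration_oracle(sc, tr, positive_label = 0)
  expect_equal(got$fpr, want$fpr)
  expect_equal(got$tpr, want$tpr)

  # monotone, exact endpoints
  set.seed(1)
  r3 <- roc_curve(runif(30), rbinom(30, 1, 0.4), positive_label = 0)
  expect_true(all(diff(r3$fpr) >= 0))
  expect_true(all(diff(r3$tpr) >= 0))
  expect_equal(c(r3$fpr[1], r3$tpr[1]), c(0, 0))
  expect_equal(c(r3$fpr[nrow(r3)], r3$tpr[nrow(r3)]), c(1, 1))

  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(auc_scores(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1), 0), 1)
  expect_equal(auc_scores(rep(0.3, 8), rep(c(0, 1), 4), 0), 0.5)

  set.seed(99)
  for (rep_i in 1:60) {
    n <- sample(3:12, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # coarse rounding forces ties
    a_trap <- auc_scores(scores, truth, positive_label = 0)
    a_pair <- pairwise_auc_oracle(scores, truth, positive_label = 0)
    a_rank <- ihdforest:::auc_mw(scores, truth, positive_label = 0)
    expect_equal(a_trap, a_pair, tolerance = 1e-12)
    expect_equal(a_rank, a_pair, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- rnorm(40)
  truth <- rbinom(40, 1, 0.3)
  a <- auc_scores(scores, truth, 0)
  expect_equal(auc_scores(exp(scores), truth, 0), a)
  expect_equal(auc_scores(qnorm(pnorm(scores))^3 + scores * 10, truth, 0), a)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(80)
  truth <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c(1, 0),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_scores(scores, truth, positive_label = 0), ref,
               tolerance = 1e-12)
})

test_that("bootstrap intervals behave: degenerate case, nesting, coverage", {
  # constant correct predictions: interval (1, 1)
  ci <- metric_ci(c(1, 1, 0, 0, 1, 0), c(0, 0, 1, 1, 0, 1),
                  metric = "accuracy", replicates = 200, seed = 1,
                  positive_label = 0)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))

  set.seed(5)
  scores <- rnorm(80, mean = ifelse(rbinom(80, 1, 0.4) == 1, 1, 0))
  truth <- as.integer(scores > 0.5) # imperfectly related labels
  truth[1:5] <- 1 - truth[1:5]
  ci95 <- metric_ci(scores, truth, "auc", level = 0.95, replicates = 400,
                    seed = 2, positive_label = 0)
  ci99 <- metric_ci(scores, truth, "auc", level = 0.99, replicates = 400,
                    seed = 2, positive_label = 0)
  expect_gte(ci95$lower, ci99$lower)
  expect_lte(ci95$upper, ci99$upper)
  expect_gte(ci95$point, ci95$lower)
  expect_lte(ci95$point, ci95$upper)

  # coverage of the known true AUC of a binormal generator
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  covered <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    y <- rep(c(0, 1), each = 50)
    s <- rnorm(100, mean = ifelse(y == 0, delta, 0))  # positives score higher
    ci <- metric_ci(s, y, "auc", level = 0.95, replicates = 500,
                    seed = seed + 1000, positive_label = 0)
    covered <- covered + (ci$lower <= true_auc && true_auc <= ci$upper)
  }
  expect_gte(covered / 200, 0.91)
  expect_lte(covered / 200, 0.99)
})
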