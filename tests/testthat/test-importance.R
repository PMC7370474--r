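test_that("permuting a constant column scores exactly zero MDA", {
  set.seed(1)
  y <- rep(c(0L, 1L), c(40, 20))
  df <- data.frame(a = y + rnorm(60, sd = 0.2), const = rep(3, 60))
  co <- toy_cohort(df, y)
  model <- train_brf(co, brf_config(m = 3, trees_per_forest = 20, seed = 2))
  scores <- mda(model, permutations = 3, seed = 4)
  expect_equal(unname(scores["const"]), 0)
})

test_that("a label-copy feature dominates MDA on a separable cohort", {
  set.seed(2)
  y <- rep(c(0L, 1L), c(60, 30))
  df <- data.frame(copy = as.numeric(y), n1 = rnorm(90), n2 = rnorm(90),
                   n3 = rnorm(90))
  co <- toy_cohort(df, y)
  model <- train_brf(co, brf_config(m = 5, trees_per_forest = 30, seed = 3))
  scores <- mda(model, permutations = 5, seed = 5)
  expect_identical(names(which.max(scores)), "copy")
  expect_gt(scores["copy"], 10)  # percentage points
})

test_that("MDA of a pure-noise feature is centred at zero (null simulation)", {
  vals <- numeric(25)
  for (seed in 1:25) {
    co <- make_signal_cohort(n = 120, prevalence = 0.3, seed = seed,
                             deltas = c(s = 1.5), n_noise = 3)
    model <- train_brf(co, brf_config(m = 3, trees_per_forest = 20,
                                      seed = seed))
    vals[seed] <- mda(model, permutations = 3, seed = seed)["noise1"]
  }
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 1e-9)
})

test_that("Gini routing reproduces hand-computed stump arithmetic", {
  # stump on a perfectly separating binary feature, balanced classes:
  # root impurity 0.5 -> 0, node weight 1, decrease exactly 0.5
  tree <- matrix(c(2L, 3L, 1L, 0L, 1L, 0L,
                   0L, 0L, 0L, 0L, -1L, 0L,
                   0L, 0L, 0L, 0L, -1L, 1L),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("left daughter", "right daughter",
                                         "split var", "split point",
                                         "status", "prediction")))
  tree[1, "split point"] <- 0.5
  x <- matrix(rep(c(0, 1), each = 10), ncol = 1)
  y01 <- rep(c(0, 1), each = 10)
  dec <- ihdforest:::tree_gini_decrease(tree, x, y01, w = rep(1, 20))
  expect_equal(dec, 0.5)
})

test_that("MDG is nonnegative, ignores unsplit features, and conserves impurity decrease", {
  set.seed(4)
  y <- rep(c(0L, 1L), c(50, 25))
  df <- data.frame(s = y + rnorm(75, sd = 0.5), n1 = rnorm(75),
                   const = rep(1, 75))
  co <- toy_cohort(df, y)
  model <- train_brf(co, brf_config(m = 3, trees_per_forest = 15, seed = 5))
  g <- mdg(model)
  expect_true(all(g >= 0))
  expect_equal(unname(g["const"]), 0)   # constant feature is never split on
  expect_gt(g["s"], g["n1"])

  # conservation per forest: feature sums equal root-minus-leaves impurity
  f <- model$forests[[1]]
  rs <- model$resamples[[1]]
  xr <- as.matrix(model$train_x[rs$idx, ])
  y01 <- as.numeric(model$train_y[rs$idx])
  total_dec <- 0
  for (t in seq_len(f$ntree)) {
    tr <- randomForest::getTree(f, t)
    w <- f$inbag[, t]
    # independent leaf routing
    leaf_gini <- function(node, rows) {
      if (tr[node, "status"] == -1L) {
        wt <- sum(w[rows])
        if (wt == 0) return(0)
        p1 <- sum(w[rows] * y01[rows]) / wt
        return(wt * 2 * p1 * (1 - p1))
      }
      left <- rows[xr[rows, tr[node, "split var"]] <= tr[node, "split point"]]
      leaf_gini(tr[node, "left daughter"], left) +
        leaf_gini(tr[node, "right daughter"], setdiff(rows, left))
    }
    rows <- which(w > 0)
    wt <- sum(w[rows])
    p1 <- sum(w[rows] * y01[rows]) / wt
    root <- 2 * p1 * (1 - p1)
    total_dec <- total_dec + (root - leaf_gini(1L, rows) / wt)
  }
  per_forest <- ihdforest:::forest_gini_importance(
    f, model$train_x[rs$idx, ], factor(y01, levels = c(0, 1)))
  expect_equal(sum(per_forest), total_dec / f$ntree, tolerance = 1e-10)
})

test_that("authored MDG agrees in ranking with the reference forest importance", {
  set.seed(6)
  y <- rep(c(0L, 1L), c(80, 40))
  df <- data.frame(s1 = y * 1.5 + rnorm(120), s2 = y + rnorm(120),
                   n1 = rnorm(120), n2 = rnorm(120), n3 = rnorm(120))
  yfac <- factor(y, levels = c(0, 1))
  set.seed(7)
  f <- randomForest::randomForest(df, yfac, ntree = 100, keep.inbag = TRUE)
  ours <- mdg(f, x = df, y = yfac)
  ref <- randomForest::importance(f, type = 2)[, 1]
  expect_gt(cor(ours[names(ref)], ref, method = "spearman"), 0.9)
})

test_that("consensus selection follows the top-k cross-ranking rule", {
  t5 <- load_table5_scores()
  sel <- consensus_select(t5$mda, t5$mdg, t5$relief, k = 5, min_lists = 2)
  expect_setequal(sel, c("bmi", "size", "ctvalue", "prevma", "age"))
  expect_identical(sel[1], "bmi")   # only feature in all three top-5 lists

  # disjoint lists yield nothing at min_lists = 2
  a <- setNames(3:1, c("a", "b", "c"))
  b <- setNames(3:1, c("d", "e", "f"))
  c3 <- setNames(3:1, c("g", "h", "i"))
  expect_length(consensus_select(a, b, c3, k = 3, min_lists = 2), 0L)
  # identical lists at min_lists = 3 return exactly the top-k
  expect_setequal(consensus_select(a, a, a, k = 2, min_lists = 3), c("a", "b"))

  expect_error(consensus_select(a, b, c3, k = 4, min_lists = 2), "exceeds")
})

test_that("importance table carries per-list scores and ranks", {
  t5 <- load_table5_scores()
  tab <- importance_table(t5$mda, t5$mdg, t5$relief)
  expect_setequal(tab$feature, names(t5$mda))
  expect_identical(tab$feature[tab$rank_mda == 1], "bmi")
  expect_identical(tab$feature[tab$rank_relief == 1], "ctvalue")
  expect_equal(tab$mdg[tab$feature == "bmi"], 16.688)
})

test_that("planted Table-1-direction effects reach the top consensus ranks", {
  # three planted effects in the published directions (lower BMI, larger
  # tumor, higher metabolite ratio in the IHD class), amplified to 1 SD so
  # the check measures ranking, not raw power at desk scale
  hits <- 0L
  for (seed in 1:25) {
    specs <- list(
      bmi = feature_spec("bmi", "continuous-normal",
                         list("0" = list(mean = 24, sd = 3),
                              "1" = list(mean = 21, sd = 3))),
      size = feature_spec("size", "continuous-normal",
                          list("0" = list(mean = 5.2, sd = 2.5),
                               "1" = list(mean = 7.7, sd = 2.5))),
      prevma = feature_spec("prevma", "continuous-lognormal",
                            list("0" = lognormal_from_quantiles(1.4, 0.9, 2.2),
                                 "1" = lognormal_from_quantiles(2.8, 1.8, 4.4))),
      n1 = feature_spec("n1", "continuous-normal",
                        list("0" = list(mean = 0, sd = 1),
                             "1" = list(mean = 0, sd = 1))),
      n2 = feature_spec("n2", "continuous-normal",
                        list("0" = list(mean = 10, sd = 2),
                             "1" = list(mean = 10, sd = 2))),
      n3 = feature_spec("n3", "bernoulli",
                        list("0" = list(p = 0.4), "1" = list(p = 0.4))),
      n4 = feature_spec("n4", "continuous-normal",
                        list("0" = list(mean = -3, sd = 5),
                             "1" = list(mean = -3, sd = 5)))
    )
    co <- sample_cohort(cohort_config(400, 0.26, specs = specs, seed = seed))
    w <- relief_f_weights(co, relief_config(k = 10, seed = seed))
    model <- train_brf(co, brf_config(m = 5, trees_per_forest = 30,
                                      seed = seed))
    mda_s <- mda(model, permutations = 3, seed = seed)
    mdg_s <- mdg(model)
    relief_s <- setNames(w$weight, w$feature)[names(mda_s)]
    sel <- consensus_select(mda_s, mdg_s, relief_s, k = 4, min_lists = 2)
    hits <- hits + all(c("bmi", "size", "prevma") %in% sel[1:3])
  }
  expect_gte(hits, 20L)  # >= 80% of 25 seeded runs
})
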