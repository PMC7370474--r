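#' The seven-classifier roster of the benchmark
#'
#' Baseline learners are delegated to established implementations behind a
#' uniform `fit(x, y)` / `prob(model, x)` contract (`prob` returns the
#' estimated probability of the IHD class, label 1):
#'
#' * `logistic` — [stats::glm()] with a binomial link;
#' * `naive_bayes` — [e1071::naiveBayes()];
#' * `cart` — [rpart::rpart()] with Gini splitting;
#' * `c45_like` — [rpart::rpart()] with information-gain splitting
#'   (a CART-family approximation of C4.5);
#' * `c50_like` — information-gain [rpart::rpart()] with a finer complexity
#'   penalty (approximation of C5.0; C5.0 proper is not reimplemented);
#' * `c50_boosted_like` — gradient-boosted trees via [xgboost::xgboost()]
#'   (approximation of boosted C5.0);
#' * `random_forest` — [randomForest::randomForest()].
#'
#' @param ntree_rf trees for the random forest (default 200).
#' @param nrounds_boost boosting rounds (default 40).
#' @return named list of classifiers, each `list(fit, prob)`.
#' @export
default_classifiers <- function(ntree_rf = 200L, nrounds_boost = 40L) {
  as_xmat <- function(x) {
    stats::model.matrix(~ . - 1, data = x)
  }
  list(
    logistic = list(
      fit = function(x, y) stats::glm(.y ~ ., data = cbind(x, .y = y),
                                      family = stats::binomial()),
      prob = function(m, x) unname(stats::predict(m, newdata = x,
                                                  type = "response"))
    ),
    naive_bayes = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      prob = function(m, x) unname(stats::predict(m, x, type = "raw")[, "1"])
    ),
    cart = list(
      fit = function(x, y) rpart::rpart(.y ~ ., data = cbind(x, .y = y),
                                        method = "class",
                                        parms = list(split = "gini")),
      prob = function(m, x) unname(stats::predict(m, newdata = x)[, "1"])
    ),
    c45_like = list(
      fit = function(x, y) rpart::rpart(.y ~ ., data = cbind(x, .y = y),
                                        method = "class",
                                        parms = list(split = "information")),
      prob = function(m, x) unname(stats::predict(m, newdata = x)[, "1"])
    ),
    c50_like = list(
      fit = function(x, y) rpart::rpart(.y ~ ., data = cbind(x, .y = y),
                                        method = "class",
                                        parms = list(split = "information"),
                                        control = rpart::rpart.control(
                                          cp = 0.005, minsplit = 10)),
      prob = function(m, x) unname(stats::predict(m, newdata = x)[, "1"])
    ),
    c50_boosted_like = list(
      fit = function(x, y) {
        xm <- as_xmat(x)
        m <- xgboost::xgboost(xm, y, nrounds = nrounds_boost, max_depth = 3,
                              learning_rate = 0.3, nthread = 1, verbosity = 0)
        list(model = m, cols = colnames(xm))
      },
      prob = function(m, x) {
        xm <- as_xmat(x)
        p <- stats::predict(m$model, xm[, m$cols, drop = FALSE],
                            type = "response")
        if (is.matrix(p)) p[, "1"] else unname(p)
      }
    ),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree_rf),
      prob = function(m, x) unname(stats::predict(m, x, type = "prob")[, "1"])
    )
  )
}

#' Run the classifier-by-validation-scheme benchmark grid
#'
#' For every (classifier, scheme) cell, fits on each training part of the
#' scheme's split plan, evaluates on the corresponding test part, and
#' averages accuracy and AUC over parts (the AUC of a single-class test
#' part is undefined and excluded from the average). A classifier failure
#' marks the cell failed with its diagnostic; the grid continues. Per-cell
#' seeds are derived deterministically from the global seed and logged.
#'
#' @param cohort an `ihd_cohort`.
#' @param schemes named list of `split_scheme`s (default: the study's nine).
#' @param classifiers named list of classifiers (default: the seven-model
#'   roster).
#' @param encoding model-frame encoding for the dual variables (the study
#'   ran both `"numerical"` and `"categorical"`).
#' @param features optional retained feature subset.
#' @param positive_label label treated as positive for AUC orientation
#'   (default 0, the study convention).
#' @param seed global seed.
#' @return a `benchmark_report`: `grid` (long data.frame: classifier,
#'   scheme, accuracy, auc, n_parts, n_auc_parts, failed, diagnostic,
#'   seed), `confusions` (pooled per-cell `confusion_matrix`), `encoding`.
#' @export
run_benchmark <- function(cohort, schemes = default_schemes(),
                          classifiers = default_classifiers(),
                          encoding = "numerical", features = NULL,
                          positive_label = 0, seed = 1L) {
  stopifnot(inherits(cohort, "ihd_cohort"),
            length(schemes) >= 1, length(classifiers) >= 1)
  if (is.null(names(schemes)) || is.null(names(classifiers))) {
    stop("schemes and classifiers must be named lists")
  }
  x <- cohort_model_frame(cohort, encoding, features)
  yfac <- factor(cohort$labels, levels = c(0, 1))
  n <- nrow(x)
  grid <- list()
  confusions <- list()
  for (sname in names(schemes)) {
    plan_seed <- derive_seed(seed, paste0("plan:", sname))
    plan <- make_split_plan(schemes[[sname]], n, cohort$labels, plan_seed)
    for (cname in names(classifiers)) {
      clf <- classifiers[[cname]]
      cell_seed <- derive_seed(seed, paste(sname, cname, sep = ":"))
      accs <- numeric(0); aucs <- numeric(0)
      cm_tot <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      fail_msg <- NULL
      for (p in seq_along(plan$pairs)) {
        pr <- plan$pairs[[p]]
        res <- tryCatch({
          set.seed(derive_seed(cell_seed, p))
          m <- clf$fit(x[pr$train, , drop = FALSE], yfac[pr$train])
          p1 <- clf$prob(m, x[pr$test, , drop = FALSE])
          truth <- cohort$labels[pr$test]
          pred <- as.integer(p1 > 0.5)
          score_pos <- if (identical(as.numeric(positive_label), 0)) 1 - p1 else p1
          cm <- confusion(truth, pred, positive_label)
          list(acc = metric_set(cm)$accuracy,
               auc = if (length(unique(truth)) == 2L)
                       auc_scores(score_pos, truth, positive_label)
                     else NA_real_,
               cm = cm)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          fail_msg <- conditionMessage(res)
          break
        }
        accs <- c(accs, res$acc)
        aucs <- c(aucs, res$auc)
        cm_tot <- cm_tot + c(res$cm$tp, res$cm$fp, res$cm$fn, res$cm$tn)
      }
      failed <- !is.null(fail_msg)
      grid[[length(grid) + 1L]] <- data.frame(
        classifier = cname, scheme = sname,
        accuracy = if (failed) NA_real_ else mean(accs),
        auc = if (failed) NA_real_ else mean(aucs, na.rm = TRUE),
        n_parts = length(plan$pairs),
        n_auc_parts = if (failed) 0L else sum(!is.na(aucs)),
        failed = failed,
        diagnostic = fail_msg %||% "",
        seed = cell_seed)
      if (!failed) {
        confusions[[paste(cname, sname, sep = ".")]] <-
          confusion_from_counts(cm_tot["tp"], cm_tot["fp"], cm_tot["fn"],
                                cm_tot["tn"], positive_label)
      }
    }
  }
  structure(list(grid = do.call(rbind, grid), confusions = confusions,
                 encoding = encoding),
            class = "benchmark_report")
}

#' Reshape a benchmark grid to the wide accuracy/AUC table layout
#'
#' @param report a `benchmark_report`.
#' @return data.frame: one row per classifier x metric, one column per
#'   scheme.
#' @export
benchmark_table <- function(report) {
  g <- report$grid
  schemes <- unique(g$scheme)
  rows <- list()
  for (cl in unique(g$classifier)) {
    for (metric in c("accuracy", "auc")) {
      vals <- vapply(schemes, function(s) {
        v <- g[g$classifier == cl & g$scheme == s, metric]
        if (length(v)) v else NA_real_
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, metric = metric, t(vals))
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("classifier", "metric", schemes)
  out
}
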