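#' Balanced random forest configuration
#'
#' The balanced random forest (BRF) trains `m` base random forests, each on
#' a class-balanced bootstrap of the training data (`n` rows drawn with
#' replacement from each class), and combines them by sign voting. The
#' study states the scheme but not `m` or `n`; the defaults here are
#' `m = 21` (odd, reduces vote ties), `n = "auto"` (the minority-class size
#' of the training data, the classic balanced-bagging choice), 100 trees
#' per forest and sqrt-of-p candidate features per split.
#'
#' @param m number of base random-forest voters.
#' @param n per-class bootstrap size, or `"auto"`.
#' @param trees_per_forest trees in each base forest.
#' @param features_per_split `"sqrt"` or an integer mtry.
#' @param seed global seed; per-forest seeds are derived from it.
#' @return object of class `brf_config`.
#' @export
brf_config <- function(m = 21L, n = "auto", trees_per_forest = 100L,
                       features_per_split = "sqrt", seed = 1L) {
  stopifnot(m >= 1, trees_per_forest >= 1)
  if (!identical(n, "auto")) stopifnot(is.numeric(n), n >= 1)
  structure(list(m = as.integer(m), n = n,
                 trees_per_forest = as.integer(trees_per_forest),
                 features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "brf_config")
}

#' Partition a cohort into majority and minority class rows
#'
#' @param labels binary label vector (an `ihd_cohort` is also accepted).
#' @return list: `majority` and `minority` row indices, and the
#'   corresponding labels. Equal class sizes assign the majority role to
#'   label 0 with a note; a single-class input is an error.
#' @export
split_by_class <- function(labels) {
  if (inherits(labels, "ihd_cohort")) labels <- labels$labels
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present, got only: ",
                             names(tab))
  if (length(tab) > 2L) stop("labels must be binary")
  lv <- names(tab)
  if (tab[[1]] == tab[[2]]) {
    message("equal class sizes; assigning majority role to label ", lv[1])
    maj <- lv[1]
  } else {
    maj <- lv[which.max(tab)]
  }
  mino <- setdiff(lv, maj)
  list(majority = which(as.character(labels) == maj),
       minority = which(as.character(labels) == mino),
       majority_label = type.convert(maj, as.is = TRUE),
       minority_label = type.convert(mino, as.is = TRUE))
}

#' Class-balanced bootstrap resample
#'
#' Draws exactly `n` rows with replacement from each class subset; the
#' result has `2n` rows, `n` per class.
#'
#' @param majority,minority row index vectors of the two classes.
#' @param n per-class sample size.
#' @param seed RNG seed.
#' @return list with `majority` and `minority` index multisets and `idx`
#'   (their concatenation).
#' @export
balanced_resample <- function(majority, minority, n, seed = 1L) {
  stopifnot(length(majority) >= 1, length(minority) >= 1, n >= 1)
  set.seed(seed)
  maj <- majority[sample.int(length(majority), n, replace = TRUE)]
  mino <- minority[sample.int(length(minority), n, replace = TRUE)]
  list(majority = maj, minority = mino, idx = c(maj, mino))
}

#' Train a balanced random forest
#'
#' Stage 1 splits the training rows by class; each of the `m` iterations
#' draws an independent class-balanced bootstrap (Stage 2) and fits a
#' random forest on it (Stage 3); prediction is the sign of the summed
#' per-forest votes (Stage 4, see [predict_brf()]). Train on the training
#' portion of a held-out split only: the global test set must never enter
#' any resample. The per-forest training multisets are retained for balance
#' audit and out-of-bag importance.
#'
#' @param cohort an `ihd_cohort` (the training portion).
#' @param config a [brf_config()].
#' @param features optional retained feature subset.
#' @param encoding model-frame encoding; the BRF stage treats all
#'   predictors as continuous (`"all-numeric"`) by default.
#' @return a `brf_model`: `forests`, `resamples` (audit multisets),
#'   `label_encoding` (minority -> +1, majority -> -1), `features`,
#'   training frame/labels, `config`.
#' @export
train_brf <- function(cohort, config = brf_config(), features = NULL,
                      encoding = "all-numeric") {
  stopifnot(inherits(cohort, "ihd_cohort"), inherits(config, "brf_config"))
  x <- cohort_model_frame(cohort, encoding, features)
  y <- cohort$labels
  cls <- split_by_class(y)
  n_per_class <- if (identical(config$n, "auto")) length(cls$minority)
                 else as.integer(config$n)
  p <- ncol(x)
  mtry <- if (identical(config$features_per_split, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else as.integer(config$features_per_split)
  yfac <- factor(y, levels = sort(unique(y)))
  forests <- vector("list", config$m)
  resamples <- vector("list", config$m)
  for (i in seq_len(config$m)) {
    forest_seed <- derive_seed(config$seed, paste0("forest:", i))
    rs <- tryCatch(
      balanced_resample(cls$majority, cls$minority, n_per_class, forest_seed),
      error = function(e) stop("forest ", i, ": ", conditionMessage(e)))
    set.seed(derive_seed(forest_seed, "fit"))
    forests[[i]] <- tryCatch(
      randomForest::randomForest(x[rs$idx, , drop = FALSE], yfac[rs$idx],
                                 ntree = config$trees_per_forest,
                                 mtry = mtry, keep.inbag = TRUE),
      error = function(e) stop("forest ", i, ": ", conditionMessage(e)))
    resamples[[i]] <- rs
  }
  structure(list(
    forests = forests, resamples = resamples,
    label_encoding = stats::setNames(c(1, -1),
                                     c(cls$minority_label, cls$majority_label)),
    minority_label = cls$minority_label,
    majority_label = cls$majority_label,
    features = names(x), encoding = encoding,
    train_x = x, train_y = y, n_per_class = n_per_class,
    config = config), class = "brf_model")
}

#' @export
print.brf_model <- function(x, ...) {
  cat("<brf_model>", length(x$forests), "balanced forests x",
      x$config$trees_per_forest, "trees;", x$n_per_class,
      "rows per class per resample;", length(x$features), "features\n")
  invisible(x)
}

check_brf_rows <- function(model, rows) {
  stopifnot(is.data.frame(rows))
  missing <- setdiff(model$features, names(rows))
  if (length(missing)) {
    stop("rows lack model feature column(s): ", paste(missing, collapse = ", "))
  }
  rows[model$features]
}

brf_forest_votes <- function(model, rows) {
  # each base forest votes hard +/-1 (its own majority-of-trees class,
  # mapped through the minority -> +1 encoding)
  vapply(model$forests, function(f) {
    cl <- as.character(stats::predict(f, rows, type = "response"))
    unname(model$label_encoding[cl])
  }, numeric(nrow(rows)))
}

#' Predict classes with a balanced random forest
#'
#' Each base forest casts a hard vote mapped to +1 (minority, the IHD
#' class) or -1 (majority); the ensemble label is the sign of the vote sum.
#' A zero sum resolves to the minority class — conservative toward the
#' clinically dangerous rare class.
#'
#' @param model a `brf_model`.
#' @param rows data.frame conforming to the training schema.
#' @return predicted labels on the original label coding.
#' @export
predict_brf <- function(model, rows) {
  rows <- check_brf_rows(model, rows)
  votes <- brf_forest_votes(model, rows)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  sign_vote(rowSums(votes), model$minority_label, model$majority_label)
}

# sign of the summed +/-1 forest votes; a zero sum resolves to the minority
# (rare, clinically dangerous) class
sign_vote <- function(vote_sums, minority_label, majority_label) {
  ifelse(vote_sums >= 0, minority_label, majority_label)
}

#' Minority-class probability score of a balanced random forest
#'
#' The mean over base forests of each forest's estimated minority-class
#' probability; used to draw the ensemble ROC curve. Thresholding at 0.5
#' agrees with [predict_brf()] up to each forest's internal vote/probability
#' consistency.
#'
#' @inheritParams predict_brf
#' @return numeric scores in \[0, 1\] (probability of the IHD class).
#' @export
predict_score <- function(model, rows) {
  rows <- check_brf_rows(model, rows)
  probs <- vapply(model$forests, function(f) {
    stats::predict(f, rows, type = "prob")[, as.character(model$minority_label)]
  }, numeric(nrow(rows)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  unname(rowMeans(probs))
}
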