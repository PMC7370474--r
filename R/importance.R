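#' Permutation importance (mean decrease in accuracy, MDA)
#'
#' For each base forest of a balanced random forest, accuracy on that
#' forest's out-of-bag rows (training rows never drawn into its balanced
#' resample) is compared with accuracy after permuting one feature column
#' among those rows; the drop, averaged over `permutations` seeded
#' permutations and then over forests, is the feature's MDA, reported in
#' percentage points. A forest with no out-of-bag rows is skipped with a
#' warning. Alternatively a held-out evaluation set (`x`, `y`) disjoint
#' from training may be supplied and is then used for every forest.
#'
#' @param model a `brf_model` (or a single `randomForest`, in which case
#'   `x` and `y` are required).
#' @param x,y optional evaluation rows and labels.
#' @param permutations permutations per feature (default 10).
#' @param seed RNG seed.
#' @return named numeric vector of MDA scores (percentage points).
#' @export
mda <- function(model, x = NULL, y = NULL, permutations = 10L, seed = 1L) {
  stopifnot(permutations >= 1)
  if (inherits(model, "randomForest")) {
    if (is.null(x) || is.null(y)) {
      stop("a plain random forest needs explicit evaluation rows x, y")
    }
    forests <- list(model)
    eval_sets <- list(list(x = x, y = y))
  } else {
    stopifnot(inherits(model, "brf_model"))
    forests <- model$forests
    eval_sets <- if (!is.null(x)) {
      rep(list(list(x = check_brf_rows(model, x), y = y)), length(forests))
    } else {
      lapply(model$resamples, function(rs) {
        oob <- setdiff(seq_len(nrow(model$train_x)), unique(rs$idx))
        list(x = model$train_x[oob, , drop = FALSE], y = model$train_y[oob])
      })
    }
  }
  feat <- colnames(eval_sets[[1]]$x)
  acc <- function(f, xe, ye) {
    mean(as.character(stats::predict(f, xe, type = "response")) ==
           as.character(ye))
  }
  set.seed(seed)
  drops <- matrix(NA_real_, length(forests), length(feat),
                  dimnames = list(NULL, feat))
  for (i in seq_along(forests)) {
    xe <- eval_sets[[i]]$x
    ye <- eval_sets[[i]]$y
    if (nrow(xe) == 0L) {
      warning("forest ", i, " has no out-of-bag rows; skipped")
      next
    }
    base <- acc(forests[[i]], xe, ye)
    for (f in feat) {
      permed <- vapply(seq_len(permutations), function(p) {
        xp <- xe
        xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
        acc(forests[[i]], xp, ye)
      }, numeric(1))
      drops[i, f] <- base - mean(permed)
    }
  }
  if (all(is.na(drops))) stop("no forest had evaluation rows")
  100 * colMeans(drops, na.rm = TRUE)
}

# per-tree sum of node-weighted Gini impurity decreases, obtained by
# routing the tree's in-bag rows (bootstrap counts as weights) through the
# recorded splits; weights are node fractions of the root, so a perfectly
# separating stump on balanced classes scores 0.5
tree_gini_decrease <- function(tree, xmat, y01, w) {
  p <- ncol(xmat)
  dec <- numeric(p)
  w_root <- sum(w)
  gini <- function(rows) {
    wt <- sum(w[rows])
    if (wt == 0) return(c(0, 0))
    p1 <- sum(w[rows] * y01[rows]) / wt
    c(2 * p1 * (1 - p1), wt)
  }
  stack <- list(list(node = 1L, rows = which(w > 0)))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (tree[fr$node, "status"] == -1L) next
    j <- tree[fr$node, "split var"]
    pt <- tree[fr$node, "split point"]
    left <- fr$rows[xmat[fr$rows, j] <= pt]
    right <- setdiff(fr$rows, left)
    g <- gini(fr$rows); gl <- gini(left); gr <- gini(right)
    if (g[2] > 0) {
      dec[j] <- dec[j] +
        (g[2] / w_root) * (g[1] - (gl[2] / g[2]) * gl[1] - (gr[2] / g[2]) * gr[1])
    }
    stack[[length(stack) + 1L]] <- list(node = tree[fr$node, "left daughter"],
                                        rows = left)
    stack[[length(stack) + 1L]] <- list(node = tree[fr$node, "right daughter"],
                                        rows = right)
  }
  dec
}

forest_gini_importance <- function(forest, x, y) {
  if (is.null(forest$inbag)) {
    stop("forest must be trained with keep.inbag = TRUE")
  }
  xmat <- as.matrix(x)
  y01 <- as.numeric(as.character(y) == levels(factor(y))[2])
  ntree <- forest$ntree
  tot <- numeric(ncol(xmat))
  for (t in seq_len(ntree)) {
    tr <- randomForest::getTree(forest, t)
    tot <- tot + tree_gini_decrease(tr, xmat, y01, forest$inbag[, t])
  }
  stats::setNames(tot / ntree, colnames(xmat))
}

#' Gini importance (mean decrease in Gini, MDG)
#'
#' Sum over all splits on a feature of the node-weighted Gini impurity
#' decrease (node weight = fraction of in-bag rows reaching the node),
#' averaged over trees and, for a balanced random forest, over base
#' forests. Nonnegative by construction; the per-tree feature sums conserve
#' the tree's total impurity decrease.
#'
#' @param model a `brf_model`, or a single `randomForest` trained with
#'   `keep.inbag = TRUE` (then `x` and `y`, its training data, are
#'   required).
#' @param x,y training rows/labels for a plain forest.
#' @return named numeric vector of MDG scores.
#' @export
mdg <- function(model, x = NULL, y = NULL) {
  if (inherits(model, "randomForest")) {
    if (is.null(x) || is.null(y)) {
      stop("a plain random forest needs its training rows x, y")
    }
    return(forest_gini_importance(model, x, y))
  }
  stopifnot(inherits(model, "brf_model"))
  per_forest <- mapply(function(f, rs) {
    forest_gini_importance(f, model$train_x[rs$idx, , drop = FALSE],
                           factor(model$train_y[rs$idx], levels = c(0, 1)))
  }, model$forests, model$resamples)
  rowMeans(per_forest)
}

as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    val_col <- intersect(c("score", "weight", "mda", "mdg", "relief"),
                         names(scores))[1]
    if (is.na(val_col)) stop("cannot find a score column")
    stats::setNames(scores[[val_col]], scores$feature)
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    scores
  }
}

top_of_list <- function(scores, k) {
  s <- as_score_vector(scores)
  if (k > length(s)) {
    stop("k = ", k, " exceeds the ", length(s), " features in a score list")
  }
  ord <- order(-s, names(s))
  names(s)[ord][seq_len(k)]
}

#' Assemble the three importance score lists into one table
#'
#' @param mda_scores,mdg_scores,relief_scores named numeric vectors (or
#'   data.frames with `feature` and a score column).
#' @return data.frame: `feature`, the three scores, and per-list ranks
#'   (`NA` where a feature is absent from a list).
#' @export
importance_table <- function(mda_scores, mdg_scores, relief_scores) {
  lists <- list(mda = as_score_vector(mda_scores),
                mdg = as_score_vector(mdg_scores),
                relief = as_score_vector(relief_scores))
  feat <- unique(unlist(lapply(lists, names)))
  out <- data.frame(feature = feat)
  for (nm in names(lists)) {
    s <- lists[[nm]]
    out[[nm]] <- unname(s[feat])
    rk <- rank(-s, ties.method = "min")
    out[[paste0("rank_", nm)]] <- unname(rk[feat])
  }
  out[order(out$rank_mda, out$feature), ]
}

#' Cross-ranking consensus selection of risk factors
#'
#' Takes the top-k features of each of the three importance lists (MDA,
#' MDG, Relief-F, each descending) and retains the features present in at
#' least `min_lists` of them, ordered by number of supporting lists, then
#' best rank, then name. With k = 5 and `min_lists = 2` on the published
#' score tables this yields the study's five risk factors.
#'
#' @inheritParams importance_table
#' @param k top-list depth (default 5).
#' @param min_lists minimum number of lists a feature must appear in
#'   (1 to 3; default 2).
#' @return character vector of selected features.
#' @export
consensus_select <- function(mda_scores, mdg_scores, relief_scores,
                             k = 5L, min_lists = 2L) {
  stopifnot(k >= 1, min_lists >= 1, min_lists <= 3)
  k <- as.integer(k)
  tops <- list(top_of_list(mda_scores, k),
               top_of_list(mdg_scores, k),
               top_of_list(relief_scores, k))
  feat <- unique(unlist(tops))
  n_lists <- vapply(feat, function(f) {
    sum(vapply(tops, function(tl) f %in% tl, logical(1)))
  }, integer(1))
  best_rank <- vapply(feat, function(f) {
    min(vapply(tops, function(tl) {
      m <- match(f, tl)
      if (is.na(m)) k + 1L else m
    }, integer(1)))
  }, integer(1))
  sel <- feat[n_lists >= min_lists]
  sel[order(-n_lists[match(sel, feat)], best_rank[match(sel, feat)], sel)]
}

#' Published importance score blocks of the improved random forest
#'
#' The printed top-10 MDA, top-10 MDG and top-10 Relief-F score blocks,
#' shipped as a fixture (the real patient data are unavailable; these are
#' consensus inputs, not recomputation targets).
#'
#' @return list with named numeric vectors `mda`, `mdg`, `relief`.
#' @export
load_table5_scores <- function() {
  path <- system.file("extdata", "table5_importance_scores.csv",
                      package = "ihdforest")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$measure)[c("mda", "mdg", "relief")],
         function(d) stats::setNames(d$score, d$feature))
}
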