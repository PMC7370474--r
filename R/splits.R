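#' Validation scheme descriptors
#'
#' One constructor per validation family used in the benchmark: a single
#' stratified hold-out split (80/20, 70/30, 60/40 in the study grid), k-fold
#' cross-validation (5, 10, 15 folds) and bootstrap subsets (train multisets
#' of 50, 100 or 200 drawn with replacement, tested on never-drawn rows).
#'
#' @param train_frac hold-out training fraction in (0, 1).
#' @param k number of folds.
#' @param subset_size bootstrap train (and maximum test) size.
#' @param stratified preserve label proportions (hold-out and k-fold).
#' @param repeats number of bootstrap repetitions.
#' @return a `split_scheme` object with a `name` used in report columns.
#' @export
scheme_holdout <- function(train_frac, stratified = TRUE) {
  stopifnot(train_frac > 0, train_frac < 1)
  structure(list(family = "holdout", train_frac = train_frac,
                 stratified = stratified,
                 name = sprintf("holdout_%d_%d", round(100 * train_frac),
                                round(100 * (1 - train_frac)))),
            class = "split_scheme")
}

#' @rdname scheme_holdout
#' @export
scheme_kfold <- function(k, stratified = TRUE) {
  stopifnot(k >= 2)
  structure(list(family = "kfold", k = as.integer(k), stratified = stratified,
                 name = sprintf("cv_%dfold", k)),
            class = "split_scheme")
}

#' @rdname scheme_holdout
#' @export
scheme_bootstrap <- function(subset_size, repeats = 10L) {
  stopifnot(subset_size >= 1, repeats >= 1)
  structure(list(family = "bootstrap", subset_size = as.integer(subset_size),
                 repeats = as.integer(repeats),
                 name = sprintf("bootstrap_%d", subset_size)),
            class = "split_scheme")
}

#' The study's nine validation settings
#'
#' @return named list of nine `split_scheme`s: hold-out 80/20, 70/30, 60/40;
#'   5-, 10-, 15-fold CV; bootstrap subsets of 50, 100, 200.
#' @export
default_schemes <- function() {
  s <- list(scheme_holdout(0.8), scheme_holdout(0.7), scheme_holdout(0.6),
            scheme_kfold(5), scheme_kfold(10), scheme_kfold(15),
            scheme_bootstrap(50), scheme_bootstrap(100), scheme_bootstrap(200))
  stats::setNames(s, vapply(s, `[[`, character(1), "name"))
}

new_split_plan <- function(pairs, n) {
  for (p in pairs) {
    if (length(intersect(unique(p$train), p$test)) > 0L) {
      stop("internal: train/test overlap in split plan")
    }
    if (length(p$test) == 0L) stop("internal: empty test set in split plan")
  }
  structure(list(pairs = pairs, n = as.integer(n)), class = "split_plan")
}

# largest-remainder allocation of a total across strata, clamped so every
# stratum of size >= 2 keeps at least one row on each side of the split
allocate_stratified <- function(strata_n, total) {
  exact <- strata_n * total / sum(strata_n)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  lb <- ifelse(strata_n >= 2, 1L, 0L)
  ub <- ifelse(strata_n >= 2, strata_n - 1L, strata_n)
  base <- pmin(pmax(base, lb), ub)
  # re-balance after clamping, respecting the same bounds
  diff <- total - sum(base)
  while (diff != 0) {
    if (diff > 0) {
      room <- which(base < ub)
      if (!length(room)) break
      s <- room[which.max(ub[room] - base[room])]
      base[s] <- base[s] + 1L; diff <- diff - 1L
    } else {
      room <- which(base > lb)
      if (!length(room)) break
      s <- room[which.max(base[room])]
      base[s] <- base[s] - 1L; diff <- diff + 1L
    }
  }
  base
}

#' Hold-out split plan
#'
#' Single train/test pair with `floor(n * train_frac)` training rows (the
#' floor rule reproduces the 114-row test set of a 60/40 split on 283
#' patients). Stratified mode allocates training rows per label stratum by
#' largest remainder; a stratum too small to appear on both sides degrades
#' to unconstrained allocation with a warning.
#'
#' @param n cohort size.
#' @param train_frac training fraction in (0, 1).
#' @param stratified logical.
#' @param labels label vector (required when stratified).
#' @param seed RNG seed.
#' @return a `split_plan` with one pair.
#' @export
make_holdout <- function(n, train_frac, stratified = TRUE, labels = NULL,
                         seed = 1L) {
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  n_train <- floor(n * train_frac)
  set.seed(seed)
  if (stratified) {
    if (is.null(labels) || length(labels) != n) {
      stop("stratified hold-out requires labels of length n")
    }
    strata <- split(seq_len(n), labels)
    sizes <- lengths(strata)
    if (any(sizes < 2)) {
      warning("stratum too small to appear in both sets; ",
              "unconstrained allocation for: ",
              paste(names(strata)[sizes < 2], collapse = ", "))
    }
    alloc <- allocate_stratified(sizes, n_train)
    train <- unlist(mapply(function(idx, a) {
      if (a == 0L) integer(0) else sample(idx, a)
    }, strata, alloc, SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    train <- sample.int(n, n_train)
  }
  train <- sort(train)
  new_split_plan(list(list(train = train, test = setdiff(seq_len(n), train))), n)
}

#' k-fold cross-validation split plan
#'
#' The k test folds partition the index set; fold sizes differ by at most
#' one. Stratified mode deals each (shuffled) label stratum round-robin
#' across folds so that class proportions are approximately preserved.
#'
#' @inheritParams make_holdout
#' @param k number of folds, `2 <= k <= n`.
#' @return a `split_plan` with k pairs.
#' @export
make_kfold <- function(n, k, stratified = TRUE, labels = NULL, seed = 1L) {
  if (k > n) stop("k = ", k, " exceeds n = ", n)
  stopifnot(k >= 2)
  set.seed(seed)
  ord <- if (stratified) {
    if (is.null(labels) || length(labels) != n) {
      stop("stratified k-fold requires labels of length n")
    }
    unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
  } else {
    sample.int(n)
  }
  fold <- rep_len(seq_len(k), n)
  pairs <- lapply(seq_len(k), function(f) {
    test <- sort(ord[fold == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
  new_split_plan(pairs, n)
}

#' Bootstrap-subset split plan
#'
#' Each repetition draws a training multiset of `subset_size` rows with
#' replacement; the test set is drawn without replacement from the rows
#' never sampled into that training multiset (at most `subset_size` of
#' them), guaranteeing train/test disjointness.
#'
#' @inheritParams make_holdout
#' @param subset_size training multiset size, `1 <= subset_size <= n`.
#' @param repeats number of repetitions.
#' @return a `split_plan` with `repeats` pairs; each pair's `train` is a
#'   multiset (duplicates retained).
#' @export
make_bootstrap <- function(n, subset_size, repeats = 10L, seed = 1L) {
  stopifnot(subset_size >= 1, subset_size <= n, repeats >= 1)
  set.seed(seed)
  pairs <- lapply(seq_len(repeats), function(r) {
    train <- sample.int(n, subset_size, replace = TRUE)
    pool <- setdiff(seq_len(n), train)
    if (length(pool) == 0L) {
      stop("empty out-of-sample pool in bootstrap repetition ", r,
           "; use a smaller subset_size")
    }
    test <- if (length(pool) > subset_size) sort(sample(pool, subset_size))
            else sort(pool)
    list(train = train, test = test)
  })
  new_split_plan(pairs, n)
}

#' Realize a split scheme on a cohort of size n
#'
#' @param scheme a `split_scheme`.
#' @param n cohort size.
#' @param labels label vector (needed for stratified families).
#' @param seed RNG seed.
#' @return a `split_plan`.
#' @export
make_split_plan <- function(scheme, n, labels = NULL, seed = 1L) {
  stopifnot(inherits(scheme, "split_scheme"))
  switch(scheme$family,
    holdout = make_holdout(n, scheme$train_frac, scheme$stratified, labels, seed),
    kfold = make_kfold(n, scheme$k, scheme$stratified, labels, seed),
    bootstrap = make_bootstrap(n, scheme$subset_size, scheme$repeats, seed))
}
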