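#' Relief-F configuration
#'
#' @param m number of sampled reference instances, or `"all"` (default) to
#'   use every row once.
#' @param k neighbors per class (default 10). With `cap_k = TRUE` (default)
#'   `k` is reduced to one less than the smallest class size when that class
#'   is too small; with `cap_k = FALSE` an over-large `k` is an error.
#' @param seed RNG seed governing reference sampling and the tie-break
#'   shuffle.
#' @param range_epsilon denominator guard for constant continuous features.
#' @param cap_k see `k`.
#' @return object of class `relief_config`.
#' @export
relief_config <- function(m = "all", k = 10L, seed = 1L,
                          range_epsilon = 1e-12, cap_k = TRUE) {
  if (!identical(m, "all")) stopifnot(is.numeric(m), m >= 1)
  stopifnot(k >= 1, range_epsilon > 0)
  structure(list(m = m, k = as.integer(k), seed = as.integer(seed),
                 range_epsilon = range_epsilon, cap_k = isTRUE(cap_k)),
            class = "relief_config")
}

#' Per-feature Relief distance contribution
#'
#' The elementary distance between two values of one feature: 0/1 agreement
#' for nominal features, absolute difference scaled by the observed range
#' for numeric (continuous or ordinal) features, so every contribution lies
#' in \[0, 1\].
#'
#' @param type `"nominal"` or `"numeric"`.
#' @param a,b feature values.
#' @param observed_range range of the feature column (numeric type only).
#' @param epsilon denominator guard.
#' @return numeric in \[0, 1\] (vectorized over `a`, `b`).
#' @export
relief_diff <- function(type = c("numeric", "nominal"), a, b,
                        observed_range = NULL, epsilon = 1e-12) {
  type <- match.arg(type)
  if (type == "nominal") return(as.numeric(a != b))
  stopifnot(!is.null(observed_range), observed_range >= 0)
  abs(a - b) / max(observed_range, epsilon)
}

relief_feature_type <- function(spec, encoding) {
  switch(spec$kind,
    "bernoulli" = "nominal",
    "multinomial" = ,
    "ordinal" = {
      cat_mode <- if (spec$dual) encoding == "categorical"
                  else spec$encoding == "categorical"
      if (cat_mode) "nominal" else "numeric"
    },
    "numeric")
}

#' Relief-F feature weights
#'
#' Kononenko's multi-class Relief-F: for each sampled reference instance the
#' k nearest same-class neighbors (hits) pull each feature's weight down by
#' their per-feature distance, and the k nearest neighbors of every other
#' class (misses) push it up, weighted by the class prior odds
#' P(C)/(1 - P(class of R)). Nearness is the Manhattan sum of per-feature
#' [relief_diff()] contributions; ties are broken by a seeded shuffle, so
#' the result is deterministic given the seed. Weights are reported both
#' normalized by m*k (bounded in \[-1, 1\]) and as the raw accumulated sum.
#'
#' @param cohort an `ihd_cohort` (or a data.frame of features via `x` /
#'   `labels` in [relief_weights_matrix()]).
#' @param config a [relief_config()].
#' @param encoding encoding mode for dual variables (see
#'   [cohort_model_frame()]); `"numerical"` by default.
#' @return a `relief_weights` data.frame with columns `feature`, `weight`
#'   (normalized), `raw`, ordered by weight descending, ties by name.
#' @export
relief_f_weights <- function(cohort, config = relief_config(),
                             encoding = c("numerical", "categorical")) {
  stopifnot(inherits(cohort, "ihd_cohort"))
  encoding <- match.arg(encoding)
  types <- vapply(cohort$schema, relief_feature_type, character(1),
                  encoding = encoding)
  relief_weights_matrix(cohort$features, cohort$labels, types, config)
}

#' @param x data.frame of feature columns.
#' @param labels class label vector (any discrete coding; two or more
#'   classes must be present).
#' @param types character vector (`"numeric"`/`"nominal"`) per column.
#' @rdname relief_f_weights
#' @export
relief_weights_matrix <- function(x, labels, types, config = relief_config()) {
  stopifnot(is.data.frame(x), nrow(x) == length(labels),
            length(types) == ncol(x))
  n <- nrow(x)
  y <- as.character(labels)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("at least two classes required")
  class_n <- table(y)
  k <- config$k
  k_max <- min(class_n) - 1L
  if (k > k_max) {
    if (config$cap_k && k_max >= 1L) {
      k <- as.integer(k_max)
    } else {
      smallest <- names(class_n)[which.min(class_n)]
      stop("k = ", config$k, " exceeds size of smallest class ('", smallest,
           "', n = ", min(class_n), ") minus one")
    }
  }
  priors <- as.numeric(class_n[cls]) / n
  names(priors) <- cls
  eps <- config$range_epsilon
  # per-feature pairwise diff matrices, each entry in [0, 1]
  dl <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- as.numeric(x[[j]])
    dl[[j]] <- if (types[j] == "nominal") {
      outer(v, v, FUN = function(a, b) as.numeric(a != b))
    } else {
      abs(outer(v, v, "-")) / max(max(v) - min(v), eps)
    }
  }
  D <- Reduce(`+`, dl)
  set.seed(config$seed)
  tie <- sample.int(n)
  refs <- if (identical(config$m, "all")) seq_len(n)
          else sort(sample.int(n, min(as.integer(config$m), n)))
  m_used <- length(refs)
  W <- numeric(ncol(x))
  for (i in refs) {
    ci <- y[i]
    for (cl in cls) {
      cand <- which(y == cl)
      cand <- cand[cand != i]
      nb <- cand[order(D[i, cand], tie[cand])][seq_len(k)]
      contrib <- vapply(dl, function(dm) sum(dm[i, nb]), numeric(1))
      if (cl == ci) {
        W <- W - contrib
      } else {
        W <- W + (priors[[cl]] / (1 - priors[[ci]])) * contrib
      }
    }
  }
  out <- data.frame(feature = names(x), weight = W / (m_used * k), raw = W,
                    row.names = NULL)
  out <- out[order(-out$weight, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("relief_weights", "data.frame")
  out
}

order_weight_table <- function(weights) {
  stopifnot(is.data.frame(weights), all(c("feature", "weight") %in% names(weights)))
  out <- weights[order(-weights$weight, weights$feature), ]
  rownames(out) <- NULL
  out
}

#' Threshold-based feature retention
#'
#' Keeps the features whose Relief-F weight is strictly greater than the
#' cutoff (the study retained the 10 of 18 predictors with weight above
#' -24), in descending weight order.
#'
#' @param weights a weight table (`feature`, `weight` columns).
#' @param cutoff retention threshold.
#' @return character vector of retained feature names, best first.
#' @export
select_above <- function(weights, cutoff) {
  w <- order_weight_table(weights)
  as.character(w$feature[w$weight > cutoff])
}

#' Top-k features by Relief-F weight
#'
#' @param weights a weight table (`feature`, `weight` columns).
#' @param k number of features to keep, `1 <= k <= nrow(weights)`.
#' @return character vector of the k best features.
#' @export
top_k <- function(weights, k) {
  w <- order_weight_table(weights)
  if (k < 1 || k > nrow(w)) {
    stop("k must lie in [1, ", nrow(w), "], got ", k)
  }
  as.character(w$feature[seq_len(k)])
}

#' Published Relief-F weight table of the study cohort
#'
#' The printed 18-attribute weight table, shipped as a fixture: the real
#' patient data are unavailable, so these weights are inputs for the
#' retention and consensus steps, not recomputation targets.
#'
#' @return a `relief_weights`-shaped data.frame (`feature`, `weight`).
#' @export
load_table2_weights <- function() {
  path <- system.file("extdata", "table2_relieff_weights.csv",
                      package = "ihdforest")
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  order_weight_table(w)
}
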