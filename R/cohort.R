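#' Cohort generation configuration
#'
#' @param n_total number of patients to draw (study size: 283).
#' @param prevalence probability of the IHD outcome (study prevalence:
#'   74/283).
#' @param specs named list of [feature_spec()] objects; defaults to the
#'   shipped study parameters.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param copula_cor optional feature-by-feature correlation matrix for a
#'   Gaussian-copula dependence hook. `NULL` (the default) samples features
#'   independently given class.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 283, prevalence = 74 / 283,
                          specs = default_specs(), seed = 1L,
                          copula_cor = NULL) {
  stopifnot(n_total >= 1, length(prevalence) == 1L)
  if (prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1], got ", prevalence)
  }
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("feature names must be unique")
  names(specs) <- nm
  if (!is.null(copula_cor)) {
    stopifnot(is.matrix(copula_cor),
              nrow(copula_cor) == length(specs),
              ncol(copula_cor) == length(specs))
  }
  structure(list(n_total = as.integer(n_total), prevalence = prevalence,
                 specs = specs, seed = as.integer(seed),
                 copula_cor = copula_cor),
            class = "cohort_config")
}

new_cohort <- function(features, labels, schema) {
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(features = features, labels = as.integer(labels),
                 schema = schema),
            class = "ihd_cohort")
}

#' @export
print.ihd_cohort <- function(x, ...) {
  cat("<ihd_cohort>", nrow(x$features), "patients x",
      ncol(x$features), "features;",
      sum(x$labels == 1L), "IHD /", sum(x$labels == 0L), "no-IHD\n")
  invisible(x)
}

spec_bounds <- function(spec) {
  c(spec$support$lower %||% -Inf, spec$support$upper %||% Inf)
}

draw_class_values <- function(spec, params, n, max_rounds = 1000L) {
  if (n == 0L) return(numeric(0))
  draw <- switch(spec$kind,
    "continuous-normal" = function(k) stats::rnorm(k, params$mean, params$sd),
    "continuous-lognormal" = function(k) stats::rlnorm(k, params$meanlog, params$sdlog),
    "bernoulli" = function(k) stats::rbinom(k, 1L, params$p),
    function(k) sample(spec$levels, k, replace = TRUE, prob = params$p)
  )
  out <- draw(n)
  b <- spec_bounds(spec)
  if (is.finite(b[1]) || is.finite(b[2])) {
    bad <- which(out < b[1] | out > b[2])
    rounds <- 0L
    while (length(bad) > 0L) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("feature ", spec$name, ": truncation support appears to carry ",
             "no probability mass (", max_rounds, " redraw rounds exhausted)")
      }
      out[bad] <- draw(length(bad))
      bad <- bad[out[bad] < b[1] | out[bad] > b[2]]
    }
  }
  out
}

# inverse-CDF transform of a uniform draw, used by the Gaussian-copula hook;
# truncation is handled by mapping u into the CDF mass of the support
quantile_transform <- function(spec, params, u) {
  b <- spec_bounds(spec)
  switch(spec$kind,
    "continuous-normal" = {
      lo <- stats::pnorm(b[1], params$mean, params$sd)
      hi <- stats::pnorm(b[2], params$mean, params$sd)
      stats::qnorm(lo + u * (hi - lo), params$mean, params$sd)
    },
    "continuous-lognormal" = {
      lo <- stats::plnorm(max(b[1], 0), params$meanlog, params$sdlog)
      hi <- stats::plnorm(b[2], params$meanlog, params$sdlog)
      stats::qlnorm(lo + u * (hi - lo), params$meanlog, params$sdlog)
    },
    "bernoulli" = as.numeric(u > 1 - params$p),
    {
      cum <- cumsum(params$p)
      spec$levels[findInterval(u, cum, left.open = TRUE) + 1L]
    }
  )
}

#' Sample a synthetic patient cohort
#'
#' Labels are drawn Bernoulli(prevalence); each feature is then drawn from
#' its class-conditional distribution (independently given class unless a
#' copula correlation is configured). Values outside a feature's support are
#' redrawn; the draw is fully reproducible from the config seed.
#'
#' @param config a [cohort_config()].
#' @return an `ihd_cohort`: `features` (data.frame), `labels` (0/1 integer
#'   vector, 1 = IHD), `schema` (the specs used).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_total
  labels <- stats::rbinom(n, 1L, config$prevalence)
  specs <- config$specs
  cols <- vector("list", length(specs))
  names(cols) <- names(specs)
  if (is.null(config$copula_cor)) {
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      v <- numeric(n)
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        v[idx] <- draw_class_values(sp, sp$params_by_class[[as.character(cl)]],
                                    length(idx))
      }
      cols[[j]] <- v
    }
  } else {
    R <- config$copula_cor
    L <- chol(R)
    z <- matrix(stats::rnorm(n * length(specs)), n) %*% L
    u <- stats::pnorm(z)
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      v <- numeric(n)
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        v[idx] <- quantile_transform(sp, sp$params_by_class[[as.character(cl)]],
                                     u[idx, j])
      }
      cols[[j]] <- v
    }
  }
  new_cohort(as.data.frame(cols), labels, specs)
}

#' Per-class cohort summary in the layout of a population table
#'
#' Mean and SD for normal features, median and quartiles for lognormal
#' features, category proportions for categorical features, computed per
#' class. A class absent from the cohort is flagged rather than silently
#' producing NaN.
#'
#' @param cohort an `ihd_cohort`.
#' @return data.frame with columns `feature`, `class`, `n`, `parameter`,
#'   `value`, `absent`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ihd_cohort"))
  if (nrow(cohort$features) == 0L) stop("empty cohort")
  rows <- list()
  for (sp in cohort$schema) {
    x <- cohort$features[[sp$name]]
    for (cl in c(0L, 1L)) {
      xi <- x[cohort$labels == cl]
      absent <- length(xi) == 0L
      params <- switch(sp$kind,
        "continuous-normal" = c(mean = if (!absent) mean(xi) else NA_real_,
                                sd = if (!absent) stats::sd(xi) else NA_real_),
        "continuous-lognormal" = {
          q <- if (!absent) stats::quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
               else rep(NA_real_, 3)
          c(q1 = q[1], median = q[2], q3 = q[3])
        },
        "bernoulli" = c(p = if (!absent) mean(xi) else NA_real_),
        {
          p <- if (!absent) {
            vapply(sp$levels, function(l) mean(xi == l), numeric(1))
          } else rep(NA_real_, length(sp$levels))
          stats::setNames(p, paste0("p_", sp$levels))
        }
      )
      rows[[length(rows) + 1L]] <- data.frame(
        feature = sp$name, class = cl, n = length(xi),
        parameter = names(params), value = unname(params),
        absent = absent, row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}

#' Write / read a cohort as CSV plus a JSON schema sidecar
#'
#' The CSV carries one row per patient, all feature columns, and the binary
#' outcome in column `ihd`; the sidecar (`<path>.schema.json`) mirrors the
#' feature specs so a round trip preserves typing.
#'
#' @param cohort an `ihd_cohort`.
#' @param path CSV path.
#' @return `write_cohort` the path, invisibly; `read_cohort` an `ihd_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ihd_cohort"))
  df <- cohort$features
  df$ihd <- cohort$labels
  utils::write.csv(df, path, row.names = FALSE)
  schema <- lapply(cohort$schema, function(sp) {
    sp[!vapply(sp, is.null, logical(1))]
  })
  jsonlite::write_json(unname(schema), paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  if (!"ihd" %in% names(df)) stop("cohort CSV must contain an `ihd` column")
  schema_path <- paste0(path, ".schema.json")
  if (!file.exists(schema_path)) stop("schema sidecar not found: ", schema_path)
  raw <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  schema <- lapply(raw, function(s) {
    feature_spec(s$name, s$kind,
                 lapply(s$params_by_class, function(p) lapply(p, unlist)),
                 encoding = s$encoding, dual = isTRUE(s$dual),
                 levels = if (!is.null(s$levels)) unlist(s$levels),
                 support = s$support)
  })
  names(schema) <- vapply(schema, `[[`, character(1), "name")
  labels <- df$ihd
  new_cohort(df[setdiff(names(df), "ihd")], labels, schema[setdiff(names(df), "ihd")])
}

#' Model frame of a cohort under an encoding mode
#'
#' The dual-encoded ordinal variables (ASA score 1-3 and hypertension grade
#' 0-2) enter as numeric in `"numerical"` mode and as factors in
#' `"categorical"` mode; binary nominal variables are factors in both. In
#' `"all-numeric"` mode every predictor is numeric, the representation used
#' for the balanced random forest.
#'
#' @param cohort an `ihd_cohort`.
#' @param encoding `"numerical"`, `"categorical"` or `"all-numeric"`.
#' @param features optional character vector restricting the columns (the
#'   retained feature subset after selection).
#' @return data.frame of predictors (no outcome column).
#' @export
cohort_model_frame <- function(cohort,
                               encoding = c("numerical", "categorical",
                                            "all-numeric"),
                               features = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(cohort, "ihd_cohort"))
  keep <- features %||% names(cohort$features)
  missing <- setdiff(keep, names(cohort$features))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  df <- cohort$features[keep]
  if (encoding == "all-numeric") {
    for (nm in keep) df[[nm]] <- as.numeric(df[[nm]])
    return(df)
  }
  for (nm in keep) {
    sp <- cohort$schema[[nm]]
    as_factor <- switch(sp$kind,
      "bernoulli" = TRUE,
      "multinomial" = ,
      "ordinal" = if (sp$dual) encoding == "categorical" else sp$encoding == "categorical",
      FALSE)
    df[[nm]] <- if (as_factor) {
      lev <- if (sp$kind == "bernoulli") c(0, 1) else sp$levels
      factor(df[[nm]], levels = lev)
    } else as.numeric(df[[nm]])
  }
  df
}
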