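#' Construct a class-conditional feature specification
#'
#' A `feature_spec` describes one clinical variable of the cohort as a pair of
#' class-conditional distributions (class 0 = no intraoperative hemodynamic
#' instability, class 1 = IHD). Supported kinds:
#'
#' * `"continuous-normal"` — per-class `mean` and `sd`;
#' * `"continuous-lognormal"` — per-class `meanlog` and `sdlog` (usually
#'   obtained from a published median and quartiles via
#'   [lognormal_from_quantiles()]);
#' * `"bernoulli"` — per-class success probability `p`;
#' * `"multinomial"` — `levels` plus per-class probability vector `p`;
#' * `"ordinal"` — as multinomial but treated as numeric distance-wise.
#'
#' @param name feature name (unique identifier within a cohort).
#' @param kind one of `"continuous-normal"`, `"continuous-lognormal"`,
#'   `"bernoulli"`, `"multinomial"`, `"ordinal"`.
#' @param params_by_class named list with elements `"0"` and `"1"`, each a
#'   list of distribution parameters for that class (see above).
#' @param encoding `"numerical"` or `"categorical"`: how the variable enters
#'   a model frame by default.
#' @param dual logical; `TRUE` for variables (ASA score, hypertension grade)
#'   that the analysis runs in both numerical and categorical mode.
#' @param levels category values for multinomial/ordinal kinds.
#' @param support optional list with `lower` and/or `upper` truncation bounds
#'   for continuous kinds; sampled values outside the bounds are redrawn.
#'
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind, params_by_class,
                         encoding = c("numerical", "categorical"),
                         dual = FALSE, levels = NULL, support = NULL) {
  kind <- match.arg(kind, c("continuous-normal", "continuous-lognormal",
                            "bernoulli", "multinomial", "ordinal"))
  encoding <- match.arg(encoding)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!all(c("0", "1") %in% names(params_by_class))) {
    stop("params_by_class must have entries for classes \"0\" and \"1\"")
  }
  for (cl in c("0", "1")) {
    p <- params_by_class[[cl]]
    switch(kind,
      "continuous-normal" = {
        stopifnot(is.numeric(p$mean), is.numeric(p$sd))
        if (p$sd < 0) stop("sd must be nonnegative for feature ", name)
      },
      "continuous-lognormal" = {
        stopifnot(is.numeric(p$meanlog), is.numeric(p$sdlog))
        if (p$sdlog < 0) stop("sdlog must be nonnegative for feature ", name)
      },
      "bernoulli" = {
        if (p$p < 0 || p$p > 1) stop("p out of [0,1] for feature ", name)
      },
      {
        if (is.null(levels)) stop("levels required for ", kind, " feature ", name)
        if (length(p$p) != length(levels)) {
          stop("probability vector length mismatch for feature ", name)
        }
        if (any(p$p < 0)) stop("negative category probability for feature ", name)
        if (abs(sum(p$p) - 1) > 1e-9) {
          stop("category probabilities for feature ", name, " class ", cl,
               " sum to ", format(sum(p$p), digits = 12), ", not 1")
        }
      }
    )
  }
  if (!is.null(support)) {
    lo <- support$lower %||% -Inf
    hi <- support$upper %||% Inf
    if (lo >= hi) stop("truncation bounds mis-ordered for feature ", name)
  }
  structure(
    list(name = name, kind = kind, params_by_class = params_by_class,
         encoding = encoding, dual = isTRUE(dual), levels = levels,
         support = support),
    class = "feature_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lognormal parameters from a published median and quartiles
#'
#' Skewed laboratory values (here the 24-h urine catecholamine-metabolite
#' ratio to its upper normal limit) are published as median (Q1–Q3). A
#' lognormal with `meanlog = log(median)` and
#' `sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75))` has exactly that median
#' and those quartiles.
#'
#' @param median,q1,q3 positive reals with `q1 <= median <= q3`.
#' @return list with `meanlog` and `sdlog`.
#' @examples
#' lognormal_from_quantiles(1.4, 0.9, 2.2)
#' @export
lognormal_from_quantiles <- function(median, q1, q3) {
  if (any(!is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0)) {
    stop("median and quartiles must be positive finite numbers")
  }
  if (!(q1 <= median && median <= q3)) {
    stop("quantiles mis-ordered: need q1 <= median <= q3")
  }
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Default feature specifications of the study cohort
#'
#' Loads the versioned fixture of per-class population parameters (18
#' predictors of the 283-patient pheochromocytoma cohort) and returns one
#' [feature_spec()] per predictor. Categorical parameters are stored in the
#' fixture as per-class counts and converted to probabilities here; the
#' skewed urine-metabolite ratio is converted from median/quartiles via
#' [lognormal_from_quantiles()].
#'
#' @param path path to the fixture JSON; defaults to the copy shipped with
#'   the package.
#' @return named list of `feature_spec` objects (18 by default).
#' @export
default_specs <- function(path = system.file("extdata", "table1_specs.json",
                                             package = "ihdforest")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw$specs, function(s) {
    pbc <- lapply(s$params_by_class, function(p) {
      if (s$kind == "bernoulli") {
        list(p = p$count / p$n)
      } else if (s$kind %in% c("multinomial", "ordinal")) {
        list(p = unlist(p$counts) / p$n)
      } else if (s$kind == "continuous-lognormal") {
        lognormal_from_quantiles(p$median, p$q1, p$q3)
      } else {
        list(mean = p$mean, sd = p$sd)
      }
    })
    feature_spec(
      name = s$name, kind = s$kind, params_by_class = pbc,
      encoding = s$encoding, dual = isTRUE(s$dual),
      levels = if (!is.null(s$levels)) unlist(s$levels),
      support = s$support
    )
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) stop("duplicate feature names in fixture")
  specs
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec>", x$name, "—", x$kind, "(", x$encoding,
      if (x$dual) ", dual-encoded" else "", ")\n")
  invisible(x)
}
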