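# Programmatic fixture cohorts.

# cohort with one or more informative Gaussian features (named class-mean
# gaps in pooled-SD units) plus pure-noise Gaussian features
make_signal_specs <- function(deltas = c(signal = 2), n_noise = 9) {
  specs <- list()
  for (nm in names(deltas)) {
    specs[[nm]] <- feature_spec(
      nm, "continuous-normal",
      list("0" = list(mean = 0, sd = 1),
           "1" = list(mean = deltas[[nm]], sd = 1)))
  }
  for (j in seq_len(n_noise)) {
    nm <- paste0("noise", j)
    specs[[nm]] <- feature_spec(
      nm, "continuous-normal",
      list("0" = list(mean = 0, sd = 1), "1" = list(mean = 0, sd = 1)))
  }
  specs
}

make_signal_cohort <- function(n = 283, prevalence = 74 / 283, seed = 1,
                               deltas = c(signal = 2), n_noise = 9) {
  sample_cohort(cohort_config(n, prevalence,
                              specs = make_signal_specs(deltas, n_noise),
                              seed = seed))
}

# cohort built directly from a feature frame and labels (toy exact cases)
toy_cohort <- function(features, labels, kinds = NULL) {
  specs <- lapply(names(features), function(nm) {
    kind <- if (!is.null(kinds)) kinds[[nm]] else "continuous-normal"
    params <- if (kind == "bernoulli") {
      list("0" = list(p = 0.5), "1" = list(p = 0.5))
    } else {
      list("0" = list(mean = 0, sd = 1), "1" = list(mean = 0, sd = 1))
    }
    feature_spec(nm, kind, params)
  })
  names(specs) <- names(features)
  ihdforest:::new_cohort(features, labels, specs)
}
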