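default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    encoding = "numerical",
    log_level = "info",
    cohort = list(source = "synthetic", path = NULL, n_total = 283L,
                  prevalence = 74 / 283),
    relief = list(m = "all", k = 10L, cutoff = NULL, n_keep = 10L),
    benchmark = list(enabled = TRUE, ntree_rf = 200L, nrounds_boost = 40L),
    brf = list(m = 21L, n = "auto", trees_per_forest = 100L,
               train_frac = 0.6),
    importance = list(k = 5L, min_lists = 2L, permutations = 10L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: `", full, "`")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration key `", full, "` must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML or JSON file path, a plain list, or `NULL`; fills
#' defaults, rejects unknown keys (naming their location) and checks value
#' ranges. An empty file yields the all-defaults configuration.
#'
#' @param raw config file path, list, or `NULL`.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(raw = NULL) {
  user <- if (is.null(raw)) {
    list()
  } else if (is.character(raw)) {
    if (!file.exists(raw)) stop("config file not found: ", raw)
    parsed <- if (grepl("\\.json$", raw, ignore.case = TRUE)) {
      jsonlite::fromJSON(raw, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(raw)
    }
    parsed %||% list()
  } else if (is.list(raw)) {
    raw
  } else {
    stop("config must be a file path, a list, or NULL")
  }
  cfg <- merge_config(default_pipeline_config(), user)
  with(cfg$cohort, {
    if (prevalence < 0 || prevalence > 1) {
      stop("`cohort.prevalence` must lie in [0, 1], got ", prevalence)
    }
    if (n_total < 1) stop("`cohort.n_total` must be >= 1")
    if (!source %in% c("synthetic", "csv")) {
      stop("`cohort.source` must be 'synthetic' or 'csv'")
    }
    if (source == "csv" && (is.null(path) || !file.exists(path))) {
      stop("`cohort.path` must point to an existing CSV when source = 'csv'")
    }
  })
  if (cfg$brf$train_frac <= 0 || cfg$brf$train_frac >= 1) {
    stop("`brf.train_frac` must lie in (0, 1), got ", cfg$brf$train_frac)
  }
  if (!cfg$encoding %in% c("numerical", "categorical")) {
    stop("`encoding` must be 'numerical' or 'categorical'")
  }
  if (cfg$importance$min_lists < 1 || cfg$importance$min_lists > 3) {
    stop("`importance.min_lists` must lie in 1..3")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full IHD-prediction analysis pipeline
#'
#' Executes the stages in analysis order — cohort synthesis (or CSV load),
#' Relief-F weighting and feature retention, the classifier benchmark grid,
#' balanced-random-forest training and held-out evaluation, and the
#' three-list importance consensus — writing each stage's artifact (CSV /
#' JSON, with MD5 checksums) under `out_dir`. A single global seed is
#' fanned out deterministically per stage, so a rerun with the same config
#' reproduces identical artifacts. An empty retained feature set, or a
#' stage failure, skips the downstream stages with an explicit reason.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @return a `run_report` list: per-stage status/artifacts/timings, the
#'   resolved config, the seed ledger, and artifact checksums.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out_dir <- cfg$out_dir %||% file.path(tempdir(),
                                        paste0("ihdforest_run_", cfg$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!identical(cfg$log_level, "quiet")) message(...)
  report <- list(stages = list(), config = cfg, out_dir = out_dir,
                 seed_ledger = list())
  halted <- FALSE
  skip_reason <- NULL
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (halted) {
      report$stages[[name]] <<- list(status = "skipped", reason = skip_reason)
      return(invisible(NULL))
    }
    stage_seed <- derive_seed(cfg$seed, name)
    report$seed_ledger[[name]] <<- stage_seed
    say("[", name, "] running (seed ", stage_seed, ")")
    t0 <- Sys.time()
    res <- tryCatch(fun(stage_seed), error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      halted <<- TRUE
      skip_reason <<- paste0("upstream stage '", name, "' failed")
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     elapsed = elapsed)
      say("[", name, "] FAILED: ", conditionMessage(res))
    } else if (identical(res$status, "skip-downstream")) {
      halted <<- TRUE
      skip_reason <<- res$reason
      report$stages[[name]] <<- c(res["artifacts"],
                                  list(status = "complete", elapsed = elapsed,
                                       note = res$reason))
    } else {
      report$stages[[name]] <<- c(res, list(status = "complete",
                                            elapsed = elapsed))
    }
    invisible(NULL)
  }

  run_stage("cohort", function(s) {
    state$cohort <- if (cfg$cohort$source == "csv") {
      read_cohort(cfg$cohort$path)
    } else {
      sample_cohort(cohort_config(cfg$cohort$n_total, cfg$cohort$prevalence,
                                  seed = s))
    }
    path <- file.path(out_dir, "cohort.csv")
    write_cohort(state$cohort, path)
    list(artifacts = c(path, paste0(path, ".schema.json")),
         n = nrow(state$cohort$features),
         n_ihd = sum(state$cohort$labels == 1L))
  })

  run_stage("relief", function(s) {
    rc <- relief_config(m = cfg$relief$m, k = cfg$relief$k, seed = s)
    w <- relief_f_weights(state$cohort, rc, cfg$encoding)
    path <- file.path(out_dir, "relief_weights.csv")
    utils::write.csv(w, path, row.names = FALSE)
    state$weights <- w
    state$selected <- if (!is.null(cfg$relief$cutoff)) {
      select_above(w, cfg$relief$cutoff)
    } else {
      top_k(w, min(cfg$relief$n_keep, nrow(w)))
    }
    if (length(state$selected) == 0L) {
      return(list(status = "skip-downstream",
                  reason = "empty feature set after Relief-F cutoff",
                  artifacts = path))
    }
    list(artifacts = path, selected = state$selected)
  })

  run_stage("benchmark", function(s) {
    if (!isTRUE(cfg$benchmark$enabled)) {
      return(list(note = "disabled in config"))
    }
    rep <- run_benchmark(
      state$cohort,
      classifiers = default_classifiers(cfg$benchmark$ntree_rf,
                                        cfg$benchmark$nrounds_boost),
      encoding = cfg$encoding, features = state$selected, seed = s)
    path <- file.path(out_dir, "benchmark_grid.csv")
    utils::write.csv(rep$grid, path, row.names = FALSE)
    state$benchmark <- rep
    list(artifacts = path, n_cells = nrow(rep$grid))
  })

  run_stage("brf", function(s) {
    n <- nrow(state$cohort$features)
    plan <- make_holdout(n, cfg$brf$train_frac, stratified = TRUE,
                         labels = state$cohort$labels, seed = s)
    tr <- plan$pairs[[1]]$train
    te <- plan$pairs[[1]]$test
    train_cohort <- new_cohort(state$cohort$features[tr, , drop = FALSE],
                               state$cohort$labels[tr], state$cohort$schema)
    model <- train_brf(train_cohort,
                       brf_config(m = cfg$brf$m, n = cfg$brf$n,
                                  trees_per_forest = cfg$brf$trees_per_forest,
                                  seed = derive_seed(s, "brf-train")),
                       features = state$selected)
    test_x <- cohort_model_frame(state$cohort, "all-numeric",
                                 state$selected)[te, , drop = FALSE]
    truth <- state$cohort$labels[te]
    pred <- predict_brf(model, test_x)
    score <- predict_score(model, test_x)
    cm <- confusion(truth, pred, positive_label = 0)
    ms <- metric_set(cm)
    curve <- roc_curve(1 - score, truth, positive_label = 0)
    ms$auc <- auc(curve)
    roc_path <- file.path(out_dir, "brf_roc.csv")
    write_roc(curve, roc_path)
    metrics_path <- file.path(out_dir, "brf_metrics.json")
    jsonlite::write_json(
      c(ms, list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)),
      metrics_path, auto_unbox = TRUE, digits = NA)
    state$brf_model <- model
    state$brf_metrics <- ms
    list(artifacts = c(roc_path, metrics_path), metrics = ms,
         n_train = length(tr), n_test = length(te))
  })

  run_stage("importance", function(s) {
    model <- state$brf_model
    mda_s <- mda(model, permutations = cfg$importance$permutations, seed = s)
    mdg_s <- mdg(model)
    relief_s <- stats::setNames(state$weights$weight, state$weights$feature)
    relief_s <- relief_s[names(mda_s)]
    k <- min(cfg$importance$k, length(mda_s))
    consensus <- consensus_select(mda_s, mdg_s, relief_s, k = k,
                                  min_lists = cfg$importance$min_lists)
    tab <- importance_table(mda_s, mdg_s, relief_s)
    path <- file.path(out_dir, "importance_table.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    cons_path <- file.path(out_dir, "consensus_features.csv")
    utils::write.csv(data.frame(rank = seq_along(consensus),
                                feature = consensus),
                     cons_path, row.names = FALSE)
    state$consensus <- consensus
    list(artifacts = c(path, cons_path), consensus = consensus)
  })

  artifact_paths <- unlist(lapply(report$stages, `[[`, "artifacts"))
  report$checksums <- if (length(artifact_paths)) {
    as.list(tools::md5sum(artifact_paths))
  } else list()
  report_path <- file.path(out_dir, "run_report.json")
  writable <- report
  writable$config <- unclass(writable$config)
  jsonlite::write_json(
    list(stages = lapply(writable$stages, function(st) {
           st[setdiff(names(st), "metrics")]
         }),
         seed_ledger = writable$seed_ledger,
         checksums = writable$checksums),
    report_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  report$report_path <- report_path
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> out_dir:", x$out_dir, "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-11s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")")
                else if (!is.null(st$error)) paste0(" (", st$error, ")")
                else ""))
  }
  invisible(x)
}
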