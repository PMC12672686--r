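#' Pipeline orchestration
#'
#' Ties simulate -> detect -> curate -> phenotype -> enumerate -> stats ->
#' predict into one reproducible, seed-driven run with a structured report:
#' per-stage event counts (the detection funnel), parameter echo, seeds and
#' artifact checksums.
#'
#' @name pipeline
NULL

.known_config_keys <- c("seed", "out_dir", "cohort", "stages", "detection",
                        "curation", "phenotype", "prediction")

#' Build a run configuration
#'
#' @param seed master seed.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @param cohort list of [cohort_config()] arguments.
#' @param stages named logical toggles: `detect`, `curate`, `stats`,
#'   `predict` (simulate/phenotype/enumerate always run).
#' @param detection list of [detection_params()] arguments.
#' @param curation list: `n_train`, `artifact_fraction`, `threshold`.
#' @param phenotype list: `contrast_ratio`.
#' @param prediction list: `task`, `k`, `repeats`.
#' @return validated `raredrop_run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       cohort = list(),
                       stages = list(),
                       detection = list(),
                       curation = list(),
                       phenotype = list(),
                       prediction = list()) {
  stages_def <- list(detect = TRUE, curate = TRUE, stats = TRUE,
                     predict = TRUE)
  unknown <- setdiff(names(stages), names(stages_def))
  if (length(unknown)) stop("unknown stage toggle(s): ",
                            paste(unknown, collapse = ", "))
  stages_def[names(stages)] <- stages
  curation_def <- list(n_train = 2000, artifact_fraction = 0.3,
                       threshold = 0.90)
  unknown <- setdiff(names(curation), names(curation_def))
  if (length(unknown)) stop("unknown curation key(s): ",
                            paste(unknown, collapse = ", "))
  curation_def[names(curation)] <- curation
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, stages = stages_def,
                 detection = detection, curation = curation_def,
                 phenotype = phenotype, prediction = prediction,
                 user_keys = list(curation = names(curation),
                                  detection = names(detection),
                                  phenotype = names(phenotype),
                                  prediction = names(prediction))),
            class = "raredrop_run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file; unknown top-level keys are rejected.
#' @return `raredrop_run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Execute a full pipeline run
#'
#' Stages in order: simulate the cohort; rare-event detection per sample;
#' curation-model training on a generated labeled set and confidence
#' filtering of the detected events; phenotyping; cells/mL enumeration;
#' cohort statistics; patient-level prediction.  When `detect` is off, all
#' events are phenotyped; when `curate` is off, the phenotyped count equals
#' the detected count.
#'
#' @param config a [run_config()].
#' @return `raredrop_run_report`: list with per-stage outputs (`cohort`,
#'   `detection`, `curation`, `phenotyped`, `enumeration`, `state_tests`,
#'   `correlations`, `prediction`), a `funnel` of event counts per stage, the
#'   echoed config, and `checksums` of written artifacts when `out_dir` is
#'   set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "raredrop_run_config"))
  t0 <- Sys.time()
  cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
  cohort <- generate_cohort(cc)

  funnel <- list()
  dpar <- do.call(detection_params, config$detection)

  curation_model <- NULL
  if (config$stages$curate) {
    cur <- generate_curation_set(n = config$curation$n_train,
                                 artifact_fraction = config$curation$artifact_fraction,
                                 seed = config$seed + 7L)
    curation_model <- train_curation_model(cur$events, cur$label,
                                           seed = config$seed + 7L,
                                           confidence_threshold = config$curation$threshold)
  }

  per_sample <- lapply(names(cohort$samples), function(id) {
    ev <- cohort$samples[[id]]$events
    n_total <- nrow(ev)
    detected <- ev
    if (config$stages$detect && n_total >= 50) {
      det <- detect_rare_events(ev, dpar)
      detected <- ev[det$flag == "rare", , drop = FALSE]
    }
    curated <- detected
    if (config$stages$curate && nrow(detected) > 0) {
      flt <- apply_confidence_filter(curation_model, detected)
      curated <- flt$kept
    }
    list(id = id, n_total = n_total, n_detected = nrow(detected),
         n_curated = nrow(curated), curated = curated)
  })
  names(per_sample) <- names(cohort$samples)

  # phenotype thresholds estimated once from the pooled common population
  pooled <- do.call(rbind, lapply(cohort$samples, `[[`, "events"))
  thresholds <- estimate_positivity_thresholds(pooled)
  ppar <- config$phenotype
  contrast <- ppar$contrast_ratio %||% 1.2

  enums <- list()
  phenotyped <- list()
  for (ps in per_sample) {
    spec <- cohort$specs[[ps$id]]
    ph <- phenotype_events(ps$curated, thresholds, contrast_ratio = contrast)
    phenotyped[[ps$id]] <- ph$events
    enums[[ps$id]] <- enumerate_sample(ph$events, sample_metadata(spec),
                                       sample_id = ps$id,
                                       disease_state = spec$disease_state)
  }
  enums <- do.call(rbind, enums)
  rownames(enums) <- NULL

  funnel <- data.frame(
    sample_id = names(per_sample),
    events = vapply(per_sample, `[[`, numeric(1), "n_total"),
    detected = vapply(per_sample, `[[`, numeric(1), "n_detected"),
    curated = vapply(per_sample, `[[`, numeric(1), "n_curated"),
    phenotyped = vapply(phenotyped, nrow, numeric(1)),
    row.names = NULL)

  state_tests <- correlations <- NULL
  if (config$stages$stats) {
    state_tests <- pairwise_state_tests(enums)
    correlations <- clinical_correlations(enums, cohort$clinical)
  }
  prediction <- NULL
  if (config$stages$predict) {
    pp <- config$prediction
    prediction <- predict_disease_state(
      enums, task = pp$task %||% "precursor_vs_overt",
      k = pp$k %||% 5, repeats = pp$repeats %||% 5, seed = config$seed)
  }

  report <- structure(list(
    config = config, seed = config$seed, funnel = funnel,
    clinical = cohort$clinical, enumeration = enums,
    phenotype_thresholds = thresholds,
    curation_model = curation_model,
    state_tests = state_tests, correlations = correlations,
    prediction = prediction,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "raredrop_run_report")

  if (!is.null(config$out_dir)) {
    report$checksums <- write_run_outputs(report, phenotyped, config$out_dir)
  }
  report
}

#' Echo the effective configuration with provenance annotations
#'
#' Expands a run configuration to the full set of effective parameter values;
#' every default records whether it is a repo choice (`repo-default`), a
#' published study value (`literature`), or was set by the user (`user`).
#'
#' @param config a [run_config()].
#' @return nested list suitable for YAML serialization.
#' @export
config_echo <- function(config) {
  stopifnot(inherits(config, "raredrop_run_config"))
  dpar <- do.call(detection_params, config$detection)
  prov <- function(value, block, key, default_prov = "repo-default") {
    list(value = value,
         provenance = if (key %in% config$user_keys[[block]]) "user"
                      else default_prov)
  }
  list(
    seed = list(value = config$seed, provenance = "user"),
    stages = config$stages,
    detection = list(
      variance_retained = prov(dpar$variance_retained, "detection",
                               "variance_retained"),
      linkage = prov(dpar$linkage, "detection", "linkage"),
      distance_quantile = prov(dpar$distance_quantile, "detection",
                               "distance_quantile"),
      cluster_cut_scale = prov(dpar$cluster_cut_scale, "detection",
                               "cluster_cut_scale")),
    curation = list(
      n_train = prov(config$curation$n_train, "curation", "n_train"),
      artifact_fraction = prov(config$curation$artifact_fraction, "curation",
                               "artifact_fraction"),
      threshold = prov(config$curation$threshold, "curation", "threshold",
                       default_prov = "literature")),
    phenotype = list(
      contrast_ratio = prov(config$phenotype$contrast_ratio %||% 1.2,
                            "phenotype", "contrast_ratio")),
    prediction = list(
      task = prov(config$prediction$task %||% "precursor_vs_overt",
                  "prediction", "task"),
      k = prov(config$prediction$k %||% 5, "prediction", "k"),
      repeats = prov(config$prediction$repeats %||% 5, "prediction",
                     "repeats"))
  )
}

# write tabular artifacts and return their md5 checksums
write_run_outputs <- function(report, phenotyped, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (is.null(x)) return(NULL)
    write_table(x, file.path(out_dir, name))
  }
  w(report$funnel, "funnel.csv")
  w(report$enumeration, "enumeration.csv")
  w(report$clinical, "clinical.csv")
  w(do.call(rbind, c(phenotyped, list(make.row.names = FALSE))),
    "phenotyped_events.csv")
  w(report$state_tests, "table2_style.csv")
  w(report$correlations, "table3_style.csv")
  yaml::write_yaml(config_echo(report$config),
                   file.path(out_dir, "config_echo.yaml"))
  summary <- list(
    seed = report$seed,
    n_samples = nrow(report$funnel),
    funnel_totals = as.list(colSums(report$funnel[, -1])),
    prediction_accuracy = if (!is.null(report$prediction))
      list(random_forest = report$prediction$random_forest$accuracy,
           decision_tree = report$prediction$decision_tree$accuracy,
           best_univariate = report$prediction$univariate$accuracy[1],
           majority_rate = report$prediction$majority_rate) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- list.files(out_dir, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  sums
}

#' @export
print.raredrop_run_report <- function(x, ...) {
  cat("raredrop run (seed", x$seed, "):", nrow(x$funnel), "samples;",
      sum(x$funnel$events), "events ->", sum(x$funnel$detected),
      "detected ->", sum(x$funnel$curated), "curated ->",
      sum(x$funnel$phenotyped), "phenotyped\n")
  if (!is.null(x$prediction))
    cat(sprintf("  %s prediction: RF %.2f / tree %.2f (majority %.2f)\n",
                x$prediction$task, x$prediction$random_forest$accuracy,
                x$prediction$decision_tree$accuracy,
                x$prediction$majority_rate))
  invisible(x)
}
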