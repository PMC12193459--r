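# Workflow orchestration: configuration-driven simulate -> preprocess ->
# train -> predict -> evaluate stages with on-disk artifacts. Every stage
# writes its resolved configuration and seed next to its outputs, and a
# single global seed fans out deterministically to per-stage seeds through
# derive_seed().

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; the extension selects the parser.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

resolved_config <- function(config, out_dir, stage) {
  jsonlite::write_json(config, file.path(out_dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

cohort_spec_from_config <- function(config, seed) {
  args <- config[intersect(names(config),
                           names(formals(cohort_spec)))]
  args$seed <- derive_seed(seed, "datagen")
  do.call(cohort_spec, args)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `events.csv`, `demographics.csv`, `truth_patients.csv` (v0,
#' threshold, growth, label per subject), `truth_volumes.csv` (long-format
#' true mean, variance and realized volume per subject-hour) and
#' `manifest.json` (spec and seed) into `out_dir`.
#'
#' @param config named list; recognised fields mirror [cohort_spec()]
#'   arguments plus `seed`.
#' @param out_dir output directory (created if needed).
#' @return the cohort, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir) {
  if (missing(out_dir) || is.null(out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  spec <- cohort_spec_from_config(config, seed)
  cohort <- simulate_cohort(spec)
  utils::write.csv(cohort$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  tr <- cohort$truth
  utils::write.csv(data.frame(subject_id = cohort$demographics$subject_id,
                              v0 = tr$v0, threshold = tr$threshold,
                              growth = tr$growth, label = tr$label),
                   file.path(out_dir, "truth_patients.csv"), row.names = FALSE)
  n <- nrow(tr$M)
  utils::write.csv(data.frame(
    subject_id = rep(cohort$demographics$subject_id, each = length(tr$times)),
    time_h = rep(tr$times, n),
    mean_ml = as.vector(t(tr$M)),
    variance_ml2 = as.vector(t(tr$S)),
    volume_ml = as.vector(t(tr$V))),
    file.path(out_dir, "truth_volumes.csv"), row.names = FALSE)
  jsonlite::write_json(c(unclass(spec)[setdiff(names(unclass(spec)), "roster")],
                         list(global_seed = seed, intercept = tr$intercept)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  resolved_config(config, out_dir, "simulate")
  message(sprintf("simulated %d subjects (%d events, prevalence %.3f) -> %s",
                  nrow(cohort$demographics), nrow(cohort$events),
                  mean(tr$label), out_dir))
  invisible(cohort)
}

#' Reload a cohort written by [run_simulate()]
#'
#' @param dir directory holding the cohort files.
#' @return an `mskt_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  spec <- cohort_spec(n_patients = man$n_patients, duration = man$duration,
                      sampling = man$sampling, expansion_rate = man$expansion_rate,
                      horizon = man$horizon,
                      mean_effects = unlist(man$mean_effects),
                      trend_tau = man$trend_tau, var_intercept = man$var_intercept,
                      var_age_coef = man$var_age_coef,
                      var_time_ramp = man$var_time_ramp,
                      growth_intercept = man$growth_intercept, seed = man$seed)
  events <- utils::read.csv(file.path(dir, "events.csv"))
  events$charttime <- as.POSIXct(events$charttime, tz = "UTC")
  demographics <- utils::read.csv(file.path(dir, "demographics.csv"))
  demographics$admittime <- as.POSIXct(demographics$admittime, tz = "UTC")
  pats <- utils::read.csv(file.path(dir, "truth_patients.csv"))
  vols <- utils::read.csv(file.path(dir, "truth_volumes.csv"))
  times <- sort(unique(vols$time_h))
  ord <- order(match(vols$subject_id, pats$subject_id), vols$time_h)
  vols <- vols[ord, ]
  n <- nrow(pats)
  shape <- function(col) matrix(vols[[col]], n, length(times), byrow = TRUE)
  structure(list(events = events, demographics = demographics,
                 truth = list(times = times, M = shape("mean_ml"),
                              S = shape("variance_ml2"), V = shape("volume_ml"),
                              v0 = pats$v0, threshold = pats$threshold,
                              label = pats$label, growth = pats$growth,
                              intercept = man$intercept, horizon = man$horizon),
                 spec = spec),
            class = "mskt_cohort")
}

#' Train a model on a simulated cohort directory
#'
#' Splits subjects 70/15/15, fits the preprocessing pipeline on the
#' training split, trains the model, and writes `checkpoint.rds` (model +
#' pipeline + split + config + seed), `history.csv` and `pipeline.json`.
#'
#' @param config named list; recognised fields mirror [mskt_config()]
#'   arguments, plus `seed`, `fractions`, `whitelist`, `cv` (fold count;
#'   runs [mskt_cv()] on the training split and writes
#'   `cv_metrics.csv`).
#' @param cohort_dir directory from [run_simulate()].
#' @param out_dir output directory.
#' @return list with `model`, `pipeline`, `split`, invisibly.
#' @export
run_train <- function(config = list(), cohort_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  cohort <- read_cohort(cohort_dir)
  split <- split_cohort(cohort, fractions = config$fractions %||% c(0.70, 0.15, 0.15),
                        seed = derive_seed(seed, "split"))
  pipeline <- fit_pipeline(cohort, split$train,
                           whitelist = config$whitelist %||% character())
  cfg_args <- config[intersect(names(config), names(formals(mskt_config)))]
  cfg_args$seed <- derive_seed(seed, "train")
  cfg <- do.call(mskt_config, cfg_args)
  data_tr <- as_mskt_data(cohort, pipeline, split$train)
  model <- mskt_fit(data_tr, cfg)
  saveRDS(list(model = model, pipeline = pipeline, split = split,
               config = config, seed = seed), file.path(out_dir, "checkpoint.rds"))
  utils::write.csv(model$history, file.path(out_dir, "history.csv"), row.names = FALSE)
  write_pipeline_json(pipeline, file.path(out_dir, "pipeline.json"))
  resolved_config(config, out_dir, "train")
  if (!is.null(config$cv)) {
    cv <- mskt_cv(data_tr, cfg, k = as.integer(config$cv))
    utils::write.csv(cv, file.path(out_dir, "cv_metrics.csv"), row.names = FALSE)
  }
  message(sprintf("trained %d epochs (best %d) -> %s", nrow(model$history),
                  model$best_epoch, out_dir))
  invisible(list(model = model, pipeline = pipeline, split = split))
}

#' Predict expansion probabilities for a cohort split
#'
#' @param checkpoint_path path to `checkpoint.rds` from [run_train()].
#' @param cohort_dir cohort directory.
#' @param out_dir output directory; writes `predictions.csv`.
#' @param subset which stored split to score (`"test"`, `"validation"`,
#'   `"train"`).
#' @param horizon prediction window (hours).
#' @return the predictions data.frame, invisibly.
#' @export
run_predict <- function(checkpoint_path, cohort_dir, out_dir,
                        subset = "test", horizon = 24) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ck <- readRDS(checkpoint_path)
  cohort <- read_cohort(cohort_dir)
  ids <- ck$split[[subset]]
  dat <- as_mskt_data(cohort, ck$pipeline, ids)
  pe <- predict_expansion_probability(ck$model, dat, horizon = horizon)
  out <- data.frame(subject_id = ids,
                    v0 = dat$v0,
                    threshold = vapply(dat$v0, function(v) expansion_threshold(v)$c, numeric(1)),
                    point_prediction = vapply(pe$prediction, `[[`, numeric(1), "point_prediction"),
                    expansion_probability = pe$probability,
                    label = dat$labels)
  utils::write.csv(out, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  invisible(out)
}

#' Evaluate a trained checkpoint on a cohort split
#'
#' Computes the full metric suite on the held-out split; when `noise_sd`
#' is positive the cohort features are noise-injected, predictions are
#' recomputed, and the RNH robustness metric is included. Writes
#' `report.json`.
#'
#' @param config named list with optional `subset` (default "test"),
#'   `horizon` (default 24), `noise_sd` (default 0), `threshold` (default
#'   0.5), `seed`.
#' @param checkpoint_path path to `checkpoint.rds`.
#' @param cohort_dir cohort directory.
#' @param out_dir output directory.
#' @return the [evaluation_report()], invisibly.
#' @export
run_evaluate <- function(config = list(), checkpoint_path, cohort_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  ck <- readRDS(checkpoint_path)
  cohort <- read_cohort(cohort_dir)
  ids <- ck$split[[config$subset %||% "test"]]
  horizon <- config$horizon %||% 24
  dat <- as_mskt_data(cohort, ck$pipeline, ids)
  preds <- predict(ck$model, dat, type = "distribution")
  obs_mask <- !is.na(dat$volumes)
  mu <- do.call(rbind, lapply(preds, `[[`, "mean_path"))
  sdv <- sqrt(do.call(rbind, lapply(preds, `[[`, "variance_path")))
  pj <- predict_expansion_probability(ck$model, dat, horizon = horizon)$probability
  noisy_mu <- NULL
  noise_sd <- config$noise_sd %||% 0
  if (noise_sd > 0) {
    noisy <- inject_noise(cohort, noise_sd, seed = derive_seed(seed, "noise"))
    ndat <- as_mskt_data(noisy, ck$pipeline, ids)
    noisy_mu <- predict(ck$model, ndat, type = "mean")
  } else if (!is.null(config$noise_sd)) {
    noisy_mu <- mu  # zero noise: predictions unchanged, RNH = 0 by definition
  }
  report <- evaluation_report(
    pred_mean = mu[obs_mask], pred_sd = sdv[obs_mask],
    truth = dat$volumes[obs_mask],
    scores = pj, labels = dat$labels,
    noisy_mean = if (is.null(noisy_mu)) NULL else noisy_mu[obs_mask],
    threshold = config$threshold %||% 0.5)
  write_evaluation_report(report, file.path(out_dir, "report.json"))
  resolved_config(config, out_dir, "evaluate")
  invisible(report)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `train`, `predict` and `evaluate` subcommands;
#' used by the `inst/cli/mskt` Rscript wrapper. Flags: `--config FILE`
#' (YAML/JSON), `--cohort DIR`, `--checkpoint FILE`, `--out DIR`, `--seed
#' INT`, plus `--subset` and `--horizon` where relevant.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
mskt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    stop("usage: mskt <simulate|train|predict|evaluate> [--config FILE] [--out DIR] ...",
         call. = FALSE)
  }
  cmd <- args[1L]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop(sprintf("flag --%s needs a value", key), call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (is.null(opts$out)) stop("--out DIR is required", call. = FALSE)
  switch(cmd,
    simulate = run_simulate(config, opts$out),
    train = run_train(config, cohort_dir = opts$cohort, out_dir = opts$out),
    predict = run_predict(opts$checkpoint, opts$cohort, opts$out,
                          subset = opts$subset %||% "test",
                          horizon = as.numeric(opts$horizon %||% 24)),
    evaluate = {
      if (!is.null(opts$subset)) config$subset <- opts$subset
      if (!is.null(opts$horizon)) config$horizon <- as.numeric(opts$horizon)
      if (!is.null(opts[["noise-sd"]])) config$noise_sd <- as.numeric(opts[["noise-sd"]])
      run_evaluate(config, opts$checkpoint, opts$cohort, opts$out)
    },
    stop(sprintf("unknown command '%s'", cmd), call. = FALSE))
  invisible(0L)
}
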