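# Stage orchestration: simulate -> preprocess -> extract -> select ->
# train -> predict -> evaluate, each stage writing its artefact
# (CSV/JSON) into a stage directory so runs are resumable and
# reproducible from a single config.

#' Default pipeline configuration
#'
#' All method constants are surfaced here rather than hard-coded in the
#' stages: analysis rates (3 Hz SpO2 / 5 Hz airflow), the 1.2 Hz airflow
#' low-pass, the 4-h duration gate, the OSA spectral bands, the FCBF
#' bootstrap size, the SVR grids and tube width, the binary cut-offs and
#' the evaluation bootstrap size.
#'
#' @param stage_dir Directory receiving stage artefacts.
#' @param seed Master seed used by every stochastic stage.
#' @param n_recordings Cohort size for the `simulate` stage.
#' @param train_fraction Chronological train share.
#' @param sim Simulator settings, merged over [sim_config()] defaults.
#' @param fcbf_B,eval_B Bootstrap replicate counts.
#' @param epsilon SVR tube width.
#' @param grid Hyperparameter grid.
#' @param cutoffs Binary cut-offs (ascending).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(stage_dir = "osascreen_run", seed = 1L,
                            n_recordings = 60, train_fraction = 0.6,
                            sim = list(), fcbf_B = 1000, eval_B = 1000,
                            epsilon = 0.1, grid = hyperparameter_grid(),
                            cutoffs = c(5, 15, 30)) {
  stopifnot(!is.unsorted(cutoffs))
  structure(as.list(environment()), class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config,
                 raw[intersect(names(raw),
                               names(formals(pipeline_config)))])
  cfg
}

stage_path <- function(cfg, ...) file.path(cfg$stage_dir, ...)

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artefact '", path, "': run the '", producer,
         "' stage first")
  }
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic cohort + truth annotations),
#' `preprocess` (cleaning reports), `extract` (feature table CSV),
#' `select` (FCBF selection JSON per channel), `train` (screening models
#' for the SpO2, airflow and dual channels), `predict` (estimated AHI
#' CSV for the test split) and `evaluate` (diagnostic report JSON);
#' `run-all` chains them. Each stage writes into `cfg$stage_dir` and
#' fails with an actionable message when an upstream artefact is
#' missing.
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"extract"`,
#'   `"select"`, `"train"`, `"predict"`, `"evaluate"`, `"run-all"`.
#' @param cfg A [pipeline_config()] or the path of a YAML file with its
#'   fields.
#' @return Invisibly, the path(s) of the artefacts the stage wrote
#'   (for `train`/`run-all`, the fitted models are returned in the
#'   `models` attribute).
#' @export
run_pipeline <- function(stage = c("run-all", "simulate", "preprocess",
                                   "extract", "select", "train",
                                   "predict", "evaluate"),
                         cfg = pipeline_config()) {
  stage <- match.arg(stage)
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!dir.exists(cfg$stage_dir)) dir.create(cfg$stage_dir,
                                             recursive = TRUE)
  if (stage == "run-all") {
    for (s in c("simulate", "preprocess", "extract", "select", "train",
                "predict", "evaluate")) {
      out <- run_pipeline(s, cfg)
    }
    return(invisible(out))
  }
  switch(stage,
    simulate = {
      sims <- simulate_cohort(cfg$n_recordings,
                              cfg = do.call(sim_config, cfg$sim),
                              seed = cfg$seed)
      dir <- stage_path(cfg, "recordings")
      truth <- lapply(sims, function(s) {
        write_recording(s$recording, dir)
        write_events(s$truth_events,
                     file.path(dir, paste0(s$recording$id, "_truth.csv")))
        data.frame(id = s$recording$id, true_ahi = s$true_ahi)
      })
      utils::write.csv(do.call(rbind, truth),
                       stage_path(cfg, "truth_ahi.csv"),
                       row.names = FALSE)
      invisible(dir)
    },
    preprocess = {
      dir <- require_artifact(stage_path(cfg, "recordings"), "simulate")
      metas <- list.files(dir, pattern = "^sim[0-9]+\\.json$",
                          full.names = TRUE)
      reports <- lapply(metas, function(p) {
        rec <- read_recording(p, "csv")
        pp <- preprocess_recording(rec)
        c(list(id = rec$id), unclass(pp$report))
      })
      out <- stage_path(cfg, "preprocess_reports.json")
      jsonlite::write_json(reports, out, auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    extract = {
      dir <- require_artifact(stage_path(cfg, "recordings"), "simulate")
      metas <- list.files(dir, pattern = "^sim[0-9]+\\.json$",
                          full.names = TRUE)
      recs <- lapply(metas, read_recording, format = "csv")
      tab <- extract_feature_table(recs)
      out <- stage_path(cfg, "features.csv")
      write_feature_table(tab, out)
      invisible(out)
    },
    select = {
      tab <- read_feature_table(
        require_artifact(stage_path(cfg, "features.csv"), "extract"))
      train <- split_train_test(tab, cfg$train_fraction)$train
      outs <- vapply(c("spo2", "airflow", "dual"), function(ch) {
        cols <- switch(ch,
                       spo2 = grep("^spo2_", names(train), value = TRUE),
                       airflow = grep("^af_", names(train), value = TRUE),
                       dual = grep("^(spo2|af)_", names(train),
                                   value = TRUE))
        sel <- bootstrap_fcbf(train[, c(cols, "reference_ahi")],
                              B = cfg$fcbf_B, seed = cfg$seed)
        write_selection(sel, stage_path(cfg,
                                        paste0("selection_", ch, ".json")))
      }, character(1))
      invisible(outs)
    },
    train = {
      tab <- read_feature_table(
        require_artifact(stage_path(cfg, "features.csv"), "extract"))
      train <- split_train_test(tab, cfg$train_fraction)$train
      models <- lapply(c(spo2 = "spo2", airflow = "airflow",
                         dual = "dual"), function(ch) {
        sel_path <- require_artifact(
          stage_path(cfg, paste0("selection_", ch, ".json")), "select")
        sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
        screening_model(train, channel = ch, features = sel$selected,
                        grid = cfg$grid, epsilon = cfg$epsilon,
                        seed = cfg$seed)
      })
      out <- stage_path(cfg, "models.rds")
      saveRDS(models, out)
      invisible(structure(out, models = models))
    },
    predict = {
      tab <- read_feature_table(
        require_artifact(stage_path(cfg, "features.csv"), "extract"))
      test <- split_train_test(tab, cfg$train_fraction)$test
      models <- readRDS(require_artifact(stage_path(cfg, "models.rds"),
                                         "train"))
      est <- data.frame(id = test$id,
                        reference_ahi = test$reference_ahi)
      for (ch in names(models)) {
        est[[paste0("ahi_", ch)]] <- predict(models[[ch]], test)
      }
      out <- stage_path(cfg, "estimates.csv")
      utils::write.csv(est, out, row.names = FALSE)
      invisible(out)
    },
    evaluate = {
      est <- utils::read.csv(require_artifact(
        stage_path(cfg, "estimates.csv"), "predict"))
      report <- build_report(
        est$reference_ahi,
        list(spo2 = est$ahi_spo2, airflow = est$ahi_airflow,
             dual = est$ahi_dual),
        cutoffs = cfg$cutoffs, B = cfg$eval_B, seed = cfg$seed)
      out <- stage_path(cfg, "report.json")
      write_report(report, out)
      invisible(structure(out, report = report))
    })
}
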