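# Pipeline orchestration: run the monitoring stages in dependency order
# from a single configuration (R list or YAML file), writing plain-text
# artifacts (CSV/JSON, PNG frames, an RDS model checkpoint) under one
# output root. Used by the command-line script in `inst/cli/`.

#' Run the monitoring pipeline
#'
#' Stages, in dependency order: `simulate` (synthetic session to disk),
#' `spectrometer` (per-cycle trace CSV), `plateau` (onset JSON), `label`
#' (weakly labeled dataset + manifest), `train` (classifier checkpoint +
#' history), `evaluate` (held-out metrics JSON) and `monitor` (consolidated
#' report JSON). Every artifact is a pure function of (inputs, config,
#' seed).
#'
#' @param config Nested list or path to a YAML file. Top-level keys:
#'   `out` (output root), `seed`, `stages` (character vector; default all),
#'   plus optional per-stage lists `simulate` (`preset`, `n_cycles`, ...),
#'   `label` (`store_side`), `train` (`input_side`, `epochs`, ...).
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out %||% stop("config needs an `out` root", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "spectrometer", "plateau", "label", "train", "evaluate",
      "monitor")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  sim <- config$simulate %||% list()
  cfg_args <- sim[setdiff(names(sim), "preset")]
  scfg <- do.call(preset_config,
                  c(list(preset = sim$preset %||% "mini", seed = seed),
                    cfg_args))

  session <- NULL
  session_dir <- file.path(out, "session")
  if ("simulate" %in% stages) {
    session <- simulate_session(scfg, session_id = "session")
    paths$session <- save_session(session, out, overwrite = TRUE)
  } else if (dir.exists(session_dir)) {
    session <- load_session(session_dir)
  } else stop("no session available: run the simulate stage first",
              call. = FALSE)

  trace <- NULL
  if ("spectrometer" %in% stages) {
    trace <- spectrometer_trace(session)
    paths$trace <- file.path(out, "trace.csv")
    utils::write.csv(as.data.frame(trace), paths$trace, row.names = FALSE)
  }

  plateau_cycle <- NULL
  if ("plateau" %in% stages) {
    if (is.null(trace)) stop("plateau stage needs the spectrometer trace",
                             call. = FALSE)
    pr <- detect_plateau(trace$value, trace$time_min)
    plateau_cycle <- pr$onset_index - 1L
    paths$plateau <- file.path(out, "plateau.json")
    jsonlite::write_json(list(onset_cycle = plateau_cycle,
                              onset_time_min = pr$onset_time,
                              threshold_abs = pr$threshold_abs),
                         paths$plateau, auto_unbox = TRUE, digits = NA)
  }

  splits <- NULL
  if ("label" %in% stages) {
    if (is.null(plateau_cycle))
      stop("label stage needs the detected plateau", call. = FALSE)
    lab <- config$label %||% list()
    ds <- build_dataset(session, plateau_cycle,
                        store_side = lab$store_side %||% 32L,
                        frames_per_cycle = lab$frames_per_cycle)
    splits <- make_splits(ds, seed = seed)
    manifest <- ds$source
    manifest$label <- ds$labels
    manifest$split <- "train"
    manifest$split[splits$indices$val] <- "val"
    manifest$split[splits$indices$test] <- "test"
    paths$manifest <- file.path(out, "manifest.csv")
    utils::write.csv(manifest, paths$manifest, row.names = FALSE)
  }

  model <- NULL
  model_path <- file.path(out, "model.rds")
  if ("train" %in% stages) {
    if (is.null(splits)) stop("train stage needs the labeled dataset",
                              call. = FALSE)
    tr <- config$train %||% list()
    ccfg <- do.call(classifier_config,
                    c(list(input_side = tr$input_side %||% 32L,
                           seed = seed),
                      tr[setdiff(names(tr), "input_side")]))
    model <- train_classifier(splits, ccfg)
    saveRDS(model, model_path)
    paths$model <- model_path
    jsonlite::write_json(list(config = unclass(model$config),
                              history = model$history,
                              best_epoch = model$best_epoch),
                         file.path(out, "model.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (any(c("evaluate", "monitor") %in% stages)) {
    if (!file.exists(model_path))
      stop("no trained model found: run the train stage first",
           call. = FALSE)
    model <- readRDS(model_path)
  }

  if ("evaluate" %in% stages) {
    if (is.null(splits)) stop("evaluate stage needs the dataset splits",
                              call. = FALSE)
    ev <- evaluate_classifier(model, splits$test)
    paths$eval <- file.path(out, "eval.json")
    jsonlite::write_json(list(accuracy = ev$accuracy,
                              macro_precision = ev$macro_precision,
                              macro_recall = ev$macro_recall,
                              macro_f1 = ev$macro_f1,
                              confusion = ev$confusion),
                         paths$eval, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }

  if ("monitor" %in% stages) {
    repo <- monitor_session(session, model)
    paths$report <- file.path(out, "report.json")
    jsonlite::write_json(list(
      session_id = repo$session_id,
      plateau_optical_min = repo$plateau_optical$onset_time,
      plateau_dna_min = repo$plateau_dna$onset_time,
      plateau_protein_min = repo$plateau_protein$onset_time,
      consensus_min = repo$consensus_min,
      complete = repo$complete$complete,
      completion_cycle = repo$complete$cycle,
      cor_optical_dna = repo$cor_optical_dna$coefficient,
      cor_completion_dna = repo$cor_completion_dna$coefficient),
      paths$report, auto_unbox = TRUE, digits = NA)
    paths$completion <- file.path(out, "completion.csv")
    utils::write.csv(as.data.frame(repo$completion), paths$completion,
                     row.names = FALSE)
  }

  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
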