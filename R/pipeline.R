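# Stage orchestration: a reproducible run directory per configuration, with
# resolved config, logs, artifact manifest, and seeded stages.

cfg_error <- function(fmt, ...) {
  stop(structure(class = c("chtlm_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

prereq_error <- function(fmt, ...) {
  stop(structure(class = c("chtlm_prereq_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Load and validate a pipeline run configuration
#'
#' The configuration file (JSON, or YAML when the `yaml` package is
#' available) has top-level keys `out_dir`, `seed`, and optional `synth`
#' and `pipeline` blocks whose entries must be arguments of
#' [synth_config()] resp. [pipeline_config()]; unknown keys are rejected.
#'
#' @param path configuration file, or a pre-parsed list.
#' @param overrides named list of `block.key` overrides (CLI flags).
#' @return a validated list of class `run_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) {
           if (!requireNamespace("yaml", quietly = TRUE))
             cfg_error("YAML config requires the 'yaml' package; use JSON")
           yaml::read_yaml(path)
         } else jsonlite::read_json(path, simplifyVector = TRUE)
  for (ov in names(overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) raw[[parts]] <- overrides[[ov]]
    else raw[[parts[1]]][[parts[2]]] <- overrides[[ov]]
  }
  allowed_top <- c("out_dir", "seed", "synth", "pipeline")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown) > 0L)
    cfg_error("invalid config: unknown key(s) %s",
              paste(unknown, collapse = ", "))
  if (is.null(raw$out_dir)) cfg_error("invalid config: 'out_dir' is required")
  if (is.null(raw$seed)) raw$seed <- 1L
  check_block <- function(block, fn, name) {
    if (is.null(block)) return(list())
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad) > 0L)
      cfg_error("invalid config: unknown %s key(s) %s", name,
                paste(bad, collapse = ", "))
    block
  }
  synth_args <- check_block(raw$synth, synth_config, "synth")
  pipe_args <- check_block(raw$pipeline, pipeline_config, "pipeline")
  synth_args$seed <- as.integer(raw$seed)
  pipe_args$seed <- as.integer(raw$seed)
  structure(list(out_dir = raw$out_dir, seed = as.integer(raw$seed),
                 synth = do.call(synth_config, synth_args),
                 pipeline = do.call(pipeline_config, pipe_args)),
            class = "run_config")
}

run_log <- function(run, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  cat(line, "\n", sep = "", file = file.path(run, "run.log"), append = TRUE)
  message(line)
}

update_manifest <- function(run, files) {
  mf <- file.path(run, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  for (f in files) {
    if (file.exists(f))
      man[[basename(f)]] <- unname(tools::md5sum(f))
  }
  jsonlite::write_json(man, mf, auto_unbox = TRUE)
}

stage_dir <- function(run, stage) {
  d <- file.path(run, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    prereq_error("missing prerequisite artifact '%s' (run '%s' first)",
                 path, produced_by)
  path
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages: `simulate` (synthetic study to disk), `preprocess`
#' (time-frequency images), `train-source` (synthetic-EEG source encoder),
#' `transfer` (transfer-train the target encoder on all subjects),
#' `features` (per-kernel deep features + Mann-Whitney filter),
#' `classify` (SBELM fit), `evaluate` (leave-one-subject-out report) and
#' `all`. Each stage writes its artifacts under `<out_dir>/<stage>/`
#' together with the resolved configuration, a log file and an MD5
#' manifest.
#'
#' @param name stage name.
#' @param cfg a `run_config` from [read_pipeline_config()] (or a path /
#'   list accepted by it).
#' @return integer exit status, invisibly: 0 success, 2 configuration
#'   error, 3 missing prerequisite, 4 runtime failure.
#' @export
run_command <- function(name, cfg) {
  status <- tryCatch({
    name <- match.arg(name, c("simulate", "preprocess", "train-source",
                              "transfer", "features", "classify",
                              "evaluate", "all"))
    if (!inherits(cfg, "run_config")) cfg <- read_pipeline_config(cfg)
    run <- cfg$out_dir
    dir.create(run, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(seed = cfg$seed,
                              synth = unclass(cfg$synth),
                              pipeline = unclass(cfg$pipeline)),
                         file.path(run, "config.resolved.json"),
                         auto_unbox = TRUE, digits = NA)
    stages <- if (name == "all")
      c("simulate", "preprocess", "train-source", "transfer", "features",
        "classify", "evaluate")
    else name
    for (st in stages) run_stage(st, cfg, run)
    0L
  },
  chtlm_config_error = function(e) { message("config error: ", e$message); 2L },
  chtlm_prereq_error = function(e) { message(e$message); 3L },
  error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("configuration error", msg)) { message(msg); 2L }
    else { message("runtime failure: ", msg); 4L }
  })
  invisible(status)
}

run_stage <- function(st, cfg, run) {
  sy <- cfg$synth; pc <- cfg$pipeline
  switch(st,
    "simulate" = {
      d <- stage_dir(run, "simulate")
      run_log(run, sprintf("simulate: %d subjects, %d trials/class",
                           sy$n_subjects, sy$trials_per_class))
      study <- generate_fnirs_study(sy)
      for (ts in study) {
        base <- file.path(d, paste0(ts$subject_id, ".rds"))
        saveRDS(ts, base)
        jsonlite::write_json(list(subject = ts$subject_id, fs = ts$fs,
                                  modality = ts$modality,
                                  labels = ts$labels,
                                  channels = ts$channel_names),
                             paste0(base, ".json"), auto_unbox = TRUE)
      }
      update_manifest(run, list.files(d, full.names = TRUE))
    },
    "preprocess" = {
      d0 <- file.path(run, "simulate")
      require_artifact(file.path(d0, "S1.rds"), "simulate")
      d <- stage_dir(run, "preprocess")
      run_log(run, sprintf("preprocess: scalograms %dx%d, %d scales",
                           pc$image_size, pc$image_size, pc$n_scales))
      files <- list.files(d0, pattern = "\\.rds$", full.names = TRUE)
      imgs <- lapply(files, function(f)
        trials_to_images(readRDS(f), out_size = pc$image_size,
                         n_scales = pc$n_scales))
      saveRDS(imgs, file.path(d, "images.rds"))
      update_manifest(run, file.path(d, "images.rds"))
    },
    "train-source" = {
      d <- stage_dir(run, "train-source")
      imf <- require_artifact(file.path(run, "preprocess", "images.rds"),
                              "preprocess")
      n_planes <- dim(readRDS(imf)[[1]]$x)[3]
      run_log(run, sprintf("train-source: %s on synthetic EEG",
                           pc$source_variant))
      src <- train_synthetic_source(sy, pc, n_planes)
      save_encoder(src, file.path(d, "source.rds"))
      update_manifest(run, file.path(d, "source.rds"))
    },
    "transfer" = {
      imf <- require_artifact(file.path(run, "preprocess", "images.rds"),
                              "preprocess")
      srcf <- require_artifact(file.path(run, "train-source", "source.rds"),
                               "train-source")
      d <- stage_dir(run, "transfer")
      imgs <- readRDS(imf)
      src <- load_encoder(srcf)
      x <- abind4(lapply(imgs, `[[`, "x"))
      y <- unlist(lapply(imgs, `[[`, "labels"))
      run_log(run, sprintf("transfer: beta=%g, %d epochs over %d trials",
                           pc$beta, pc$transfer_epochs, length(y)))
      target <- build_encoder(encoder_spec(pc$target_variant, dim(x)[3],
                                           2, seed = cfg$seed))
      th <- transfer_hyper(beta = pc$beta, epochs = pc$transfer_epochs,
                           lr = pc$transfer_lr, batch_size = pc$batch_size,
                           seed = cfg$seed)
      tt <- transfer_train(src, target, NULL, x, y, th)
      save_encoder(tt$target, file.path(d, "target.rds"))
      rep_ <- if (pc$beta > 0) transfer_report(src, tt$nets, x) else list()
      jsonlite::write_json(list(history = tt$history, pair_weights = rep_),
                           file.path(d, "transfer_report.json"),
                           auto_unbox = TRUE, digits = NA)
      update_manifest(run, file.path(d, c("target.rds",
                                          "transfer_report.json")))
    },
    "features" = {
      imf <- require_artifact(file.path(run, "preprocess", "images.rds"),
                              "preprocess")
      tgf <- require_artifact(file.path(run, "transfer", "target.rds"),
                              "transfer")
      d <- stage_dir(run, "features")
      imgs <- readRDS(imf)
      target <- load_encoder(tgf)
      x <- abind4(lapply(imgs, `[[`, "x"))
      y <- unlist(lapply(imgs, `[[`, "labels"))
      ft <- extract_kernel_features(target, x, labels = y)
      flt <- filter_features(ft, alpha = pc$alpha)
      run_log(run, sprintf("features: %d kernels, %d selected (alpha=%g)",
                           ncol(ft$X), sum(flt$selected), pc$alpha))
      write_feature_table(ft, file.path(d, "features.tsv"), flt)
      saveRDS(flt, file.path(d, "filter.rds"))
      update_manifest(run, file.path(d, c("features.tsv", "features.tsv.json")))
    },
    "classify" = {
      ftf <- require_artifact(file.path(run, "features", "features.tsv"),
                              "features")
      fltf <- require_artifact(file.path(run, "features", "filter.rds"),
                               "features")
      d <- stage_dir(run, "classify")
      tab <- utils::read.delim(ftf, check.names = FALSE)
      y <- tab$label
      X <- as.matrix(tab[, -1, drop = FALSE])
      flt <- readRDS(fltf)
      Xs <- X[, flt$selected, drop = FALSE]
      clf <- sbelm(ncol(Xs), L = pc$L, seed = cfg$seed)
      clf <- fit(clf, Xs, y, plain = pc$classifier == "elm")
      run_log(run, sprintf("classify: lambda=%.4g, %d/%d nonzero weights",
                           clf$lambda, sum(clf$beta_out != 0), clf$L))
      save_sbelm(clf, file.path(d, "sbelm.rds"))
      update_manifest(run, file.path(d, "sbelm.rds"))
    },
    "evaluate" = {
      imf <- require_artifact(file.path(run, "preprocess", "images.rds"),
                              "preprocess")
      d <- stage_dir(run, "evaluate")
      imgs <- readRDS(imf)
      srcf <- file.path(run, "train-source", "source.rds")
      src <- if (pc$beta > 0)
        load_encoder(require_artifact(srcf, "train-source")) else NULL
      run_log(run, sprintf("evaluate: leave-one-subject-out over %d subjects",
                           length(imgs)))
      res <- loo_cv(imgs, pc, source = src)
      write_loo_report(res, d)
      run_log(run, sprintf(
        "evaluate: mean acc=%.3f auc=%.3f recall=%.3f precision=%.3f f1=%.3f",
        res$mean$accuracy, res$mean$auc, res$mean$recall,
        res$mean$precision, res$mean$f1))
      update_manifest(run, file.path(d, c("per_subject.tsv", "summary.json")))
    },
    cfg_error("unknown stage '%s'", st))
  invisible(NULL)
}

#' Export a trial set to per-trial CSV files
#'
#' One CSV per trial (samples x channels, header = channel names) plus a
#' JSON sidecar with labels, sampling rate and modality.
#'
#' @param ts a `trial_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_trials_csv <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_trials(ts))) {
    m <- t(ts$data[i, , , drop = TRUE])
    colnames(m) <- ts$channel_names
    utils::write.csv(m, file.path(dir, sprintf("trial_%03d.csv", i)),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(subject = ts$subject_id, fs = ts$fs,
                            modality = ts$modality, labels = ts$labels),
                       file.path(dir, "trials.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a columnar recording plus event table
#'
#' Reads a continuous hemodynamic recording from a CSV/TSV file (one
#' column per channel, header = channel names; HbO2 columns suffixed
#' `_HbO` and HbR columns `_HbR`) and an event table with columns
#' `onset_s` and `label`.
#'
#' @param signal_path CSV/TSV of channel columns.
#' @param events_path CSV/TSV event table.
#' @param fs sampling rate in Hz.
#' @return list with `hemo` ([hemo_recording()]) and `events` (data frame).
#' @export
read_recording_csv <- function(signal_path, events_path, fs) {
  sep <- if (grepl("\\.tsv$", signal_path)) "\t" else ","
  df <- utils::read.table(signal_path, header = TRUE, sep = sep,
                          check.names = FALSE)
  hbo_cols <- grep("_HbO$", names(df), value = TRUE)
  hbr_cols <- grep("_HbR$", names(df), value = TRUE)
  if (length(hbo_cols) == 0L || length(hbo_cols) != length(hbr_cols))
    stop_cfg("read_recording_csv: need matching *_HbO and *_HbR columns")
  hemo <- hemo_recording(t(as.matrix(df[hbo_cols])),
                         t(as.matrix(df[hbr_cols])), fs,
                         channel_names = sub("_HbO$", "", hbo_cols))
  sep2 <- if (grepl("\\.tsv$", events_path)) "\t" else ","
  ev <- utils::read.table(events_path, header = TRUE, sep = sep2)
  if (!all(c("onset_s", "label") %in% names(ev)))
    stop_cfg("read_recording_csv: event table needs onset_s and label")
  list(hemo = hemo, events = ev)
}
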