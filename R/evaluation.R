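#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney rank
#' statistic of the scores; tied scores receive half credit (midranks).
#'
#' @param y_true 0/1 labels (1 = positive).
#' @param scores real decision values.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(y_true, scores) {
  y <- as.integer(y_true)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Binary classification metrics
#'
#' Motor imagery (label 1) is the positive class, rest (label 0) the
#' negative class. Precision is 0 when nothing is predicted positive; F1
#' is 0 when precision + recall is 0; AUC is the Mann-Whitney rank
#' statistic of the scores and is `NA` (with a warning) when the true
#' labels contain a single class.
#'
#' @param y_true 0/1 true labels.
#' @param scores real decision scores.
#' @param y_pred 0/1 predicted labels.
#' @return named list: `accuracy`, `auc`, `recall`, `precision`, `f1`.
#' @export
compute_metrics <- function(y_true, scores, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(scores) || length(y_true) != length(y_pred))
    stop_cfg("compute_metrics: length mismatch")
  tp <- sum(y_pred == 1L & y_true == 1L)
  fp <- sum(y_pred == 1L & y_true == 0L)
  fn <- sum(y_pred == 0L & y_true == 1L)
  accuracy <- mean(y_pred == y_true)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  auc <- auc_rank(y_true, scores)
  if (is.na(auc))
    warning("AUC undefined: test labels contain a single class")
  list(accuracy = accuracy, auc = auc, recall = recall,
       precision = precision, f1 = f1)
}

# concatenate [H x W x C x N_i] arrays along the batch dimension
abind4 <- function(lst) {
  d <- dim(lst[[1]])
  ns <- vapply(lst, function(a) dim(a)[4], integer(1))
  out <- array(0, c(d[1], d[2], d[3], sum(ns)))
  at <- 0L
  for (a in lst) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}

# zero-pad the channel planes of an image batch up to n_planes
pad_planes <- function(x, n_planes) {
  d <- dim(x)
  if (d[3] == n_planes) return(x)
  if (d[3] > n_planes) stop_cfg("pad_planes: cannot shrink %d -> %d planes",
                                d[3], n_planes)
  out <- array(0, c(d[1], d[2], n_planes, d[4]))
  out[, , seq_len(d[3]), ] <- x
  out
}

#' Full-pipeline configuration
#'
#' Defaults are desk-scale: tiny encoder variants on 24x24 images, so a
#' complete leave-one-subject-out run finishes in minutes on one CPU. The
#' full-scale setting (resnet34/resnet18 on 224x224 images) uses the same
#' code path.
#'
#' @param target_variant,source_variant encoder variants.
#' @param image_size time-frequency image side length.
#' @param n_scales wavelet scales for the fNIRS scalograms.
#' @param beta matching-loss coefficient (0 disables transfer).
#' @param alpha Mann-Whitney filter significance level.
#' @param L SBELM hidden width.
#' @param classifier `"sbelm"` or `"elm"` (plain-ELM ablation).
#' @param transfer_epochs,transfer_lr,batch_size transfer-training SGD
#'   settings.
#' @param source_epochs,source_lr source-training SGD settings.
#' @param source_classes EEG class set used when a synthetic source is
#'   trained.
#' @param seed global pipeline seed; per-fold seeds are `seed + fold`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_variant = "tiny18",
                            source_variant = "tiny34",
                            image_size = 24, n_scales = 16,
                            beta = 0.5, alpha = 0.05, L = 200,
                            classifier = c("sbelm", "elm"),
                            transfer_epochs = 12, transfer_lr = 0.02,
                            batch_size = 28,
                            source_epochs = 20, source_lr = 0.02,
                            source_classes = c("left", "right"),
                            seed = 1L) {
  classifier <- match.arg(classifier)
  structure(list(target_variant = target_variant,
                 source_variant = source_variant,
                 image_size = as.integer(image_size),
                 n_scales = as.integer(n_scales),
                 beta = beta, alpha = alpha, L = as.integer(L),
                 classifier = classifier,
                 transfer_epochs = as.integer(transfer_epochs),
                 transfer_lr = transfer_lr,
                 batch_size = as.integer(batch_size),
                 source_epochs = as.integer(source_epochs),
                 source_lr = source_lr,
                 source_classes = source_classes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train a source encoder on synthetic EEG trials
#'
#' Generates a synthetic EEG study, converts it to STFT images padded to
#' `n_planes` image channels (the shared image space of the two domains),
#' and trains the source encoder on the class labels.
#'
#' @param synth a [synth_config()] describing the source study.
#' @param cfg a [pipeline_config()].
#' @param n_planes image channel count of the shared image space.
#' @return frozen source encoder.
#' @export
train_synthetic_source <- function(synth, cfg, n_planes) {
  imgs <- list(); labs <- list()
  for (i in seq_len(synth$n_subjects)) {
    ts <- generate_eeg_subject(synth, paste0("E", i),
                               classes = cfg$source_classes)
    im <- trials_to_images(ts, out_size = cfg$image_size)
    imgs[[i]] <- pad_planes(im$x, n_planes)
    labs[[i]] <- im$labels
  }
  x <- abind4(imgs); y <- unlist(labs)
  enc <- build_encoder(encoder_spec(cfg$source_variant, n_planes,
                                    n_classes = length(cfg$source_classes),
                                    seed = cfg$seed + 7L))
  train_source(enc, x, y,
               train_hyper(epochs = cfg$source_epochs, lr = cfg$source_lr,
                           batch_size = cfg$batch_size, seed = cfg$seed + 7L))
  enc
}

#' Leave-one-subject-out cross-validation of the full pipeline
#'
#' For each held-out subject: transfer-trains a fresh target encoder on
#' the remaining subjects' trials, extracts per-kernel deep features,
#' Mann-Whitney-filters them and fits the SBELM — all on the training
#' subjects only — then scores the held-out subject's trials. The summary
#' row is the unweighted mean over subjects (folds with undefined AUC are
#' excluded from the AUC mean).
#'
#' @param subjects list of per-subject `trial_set`s (modality
#'   `"fnirs-hemo"`), or of precomputed image lists from
#'   [trials_to_images()].
#' @param cfg a [pipeline_config()].
#' @param source optional frozen source encoder; when `NULL` and
#'   `beta > 0`, a synthetic-EEG source is trained via
#'   [train_synthetic_source()] with `source_synth`.
#' @param source_synth [synth_config()] for the synthetic source (defaults
#'   to `synth_config(seed = cfg$seed)`).
#' @return a `loo_result`: list with `per_subject` (data frame, one row
#'   per fold), `mean` (named list of mean metrics), `fold_details`.
#' @export
loo_cv <- function(subjects, cfg = pipeline_config(), source = NULL,
                   source_synth = NULL) {
  if (length(subjects) < 2L)
    stop_cfg("loo_cv: need at least 2 subjects, got %d", length(subjects))
  imgs <- lapply(subjects, function(s) {
    if (inherits(s, "trial_set"))
      trials_to_images(s, out_size = cfg$image_size, n_scales = cfg$n_scales)
    else s
  })
  n_planes <- dim(imgs[[1]]$x)[3]
  if (is.null(source) && cfg$beta > 0) {
    if (is.null(source_synth)) source_synth <- synth_config(seed = cfg$seed)
    source <- train_synthetic_source(source_synth, cfg, n_planes)
  }
  if (cfg$beta > 0 && !isTRUE(source$frozen))
    stop_cfg("loo_cv: source encoder must be frozen")
  ns <- length(imgs)
  rows <- vector("list", ns)
  details <- vector("list", ns)
  for (fold in seq_len(ns)) {
    fold_seed <- cfg$seed + fold
    tr_idx <- setdiff(seq_len(ns), fold)
    x_tr <- abind4(lapply(imgs[tr_idx], `[[`, "x"))
    y_tr <- unlist(lapply(imgs[tr_idx], `[[`, "labels"))
    x_te <- imgs[[fold]]$x
    y_te <- imgs[[fold]]$labels
    target <- build_encoder(encoder_spec(cfg$target_variant, n_planes,
                                         n_classes = 2, seed = fold_seed))
    th <- transfer_hyper(beta = cfg$beta, epochs = cfg$transfer_epochs,
                         lr = cfg$transfer_lr, batch_size = cfg$batch_size,
                         seed = fold_seed)
    if (cfg$beta > 0) {
      tt <- transfer_train(source, target, NULL, x_tr, y_tr, th)
      target <- tt$target
    } else {
      tt <- transfer_train(freeze_dummy(target), target, NULL, x_tr, y_tr, th)
      target <- tt$target
    }
    ftr <- extract_kernel_features(target, x_tr)
    flt <- filter_features(ftr$X, alpha = cfg$alpha, labels = y_tr)
    Xtr <- ftr$X[, flt$selected, drop = FALSE]
    clf <- sbelm(ncol(Xtr), L = cfg$L, seed = fold_seed)
    clf <- fit(clf, Xtr, y_tr, plain = cfg$classifier == "elm")
    fte <- extract_kernel_features(target, x_te)
    pr <- predict(clf, fte$X[, flt$selected, drop = FALSE])
    m <- compute_metrics(y_te, pr$scores, pr$labels)
    rows[[fold]] <- data.frame(subject = as.character(imgs[[fold]]$subject_id),
                               accuracy = m$accuracy, auc = m$auc,
                               recall = m$recall, precision = m$precision,
                               f1 = m$f1)
    details[[fold]] <- list(y_true = y_te, scores = pr$scores,
                            y_pred = pr$labels,
                            n_selected = sum(flt$selected),
                            history = tt$history, nets = tt$nets)
  }
  per_subject <- do.call(rbind, rows)
  mean_row <- lapply(per_subject[, -1], function(v) mean(v, na.rm = TRUE))
  structure(list(per_subject = per_subject, mean = mean_row,
                 fold_details = details, cfg = cfg),
            class = "loo_result")
}

# a frozen zero-impact stand-in so the beta = 0 path can share the
# transfer_train code exactly (the source is never evaluated when beta = 0)
freeze_dummy <- function(enc) {
  d <- new.env(parent = emptyenv())
  class(d) <- "encoder"
  d$spec <- enc$spec; d$vt <- enc$vt; d$frozen <- TRUE
  d$stages <- enc$stages; d$stem_conv <- enc$stem_conv
  d$stem_bn <- enc$stem_bn; d$head <- enc$head
  d
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-subject-out results\n")
  print(x$per_subject, row.names = FALSE, digits = 3)
  cat(sprintf("mean: acc=%.3f auc=%.3f recall=%.3f precision=%.3f f1=%.3f\n",
              x$mean$accuracy, x$mean$auc, x$mean$recall,
              x$mean$precision, x$mean$f1))
  invisible(x)
}

#' Write a LOO evaluation report
#'
#' Per-subject metrics as TSV plus a JSON summary of the mean metrics.
#'
#' @param res a `loo_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_loo_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$per_subject, file.path(dir, "per_subject.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$mean, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
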