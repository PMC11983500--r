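#' Extinction coefficient matrix for HbO2/HbR
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' acquisition wavelengths, in 1/(mM*cm). The default is a standard
#' literature table at 730 and 850 nm; rows are wavelengths, columns the
#' chromophores (HbO2, HbR). Any well-conditioned table can be supplied.
#'
#' @param values 2x2 numeric matrix `[wavelength x chromophore]`.
#' @param wavelengths wavelengths in nm (metadata only).
#' @return a 2x2 matrix of class `extinction_matrix`.
#' @export
extinction_matrix <- function(values = matrix(c(0.390, 1.058,
                                                1.102, 0.691), 2, 2),
                              wavelengths = c(730, 850)) {
  as_extinction(values, wavelengths)
}

as_extinction <- function(eps, wavelengths = c(730, 850)) {
  eps <- as.matrix(eps)
  if (!all(dim(eps) == c(2, 2)) || anyNA(eps))
    stop_cfg("extinction matrix must be a finite 2x2 matrix")
  if (kappa(eps) >= 1e6)
    stop_cfg("extinction matrix is singular or ill-conditioned (kappa >= 1e6)")
  dimnames(eps) <- list(paste0("W", wavelengths), c("HbO2", "HbR"))
  structure(eps, class = c("extinction_matrix", "matrix"),
            wavelengths = wavelengths)
}

#' Raw dual-wavelength optical recording
#'
#' @param intensity numeric array `[n_channels x 2 x n_samples]`: per
#'   channel, intensities at the two wavelengths (arbitrary optical units,
#'   strictly positive).
#' @param fs sampling rate in Hz.
#' @param wavelengths the two wavelengths in nm.
#' @param d source-detector separation in mm.
#' @param dpf per-wavelength differential pathlength factor (length 1 or 2).
#' @param channel_names optional channel names.
#' @return an object of class `optical_recording`.
#' @export
optical_recording <- function(intensity, fs, wavelengths = c(730, 850),
                              d = 30, dpf = c(6, 6), channel_names = NULL) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L ||
      dim(intensity)[2] != 2L)
    stop_cfg("optical_recording: intensity must be [channels x 2 wavelengths x samples]")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop_cfg("optical_recording: intensities must be finite and > 0")
  check_scalar(d, "d", lower = 0, strict_lower = TRUE)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(dim(intensity)[1]))
  structure(list(intensity = intensity, fs = fs, wavelengths = wavelengths,
                 d = d, dpf = rep_len(dpf, 2), channel_names = channel_names),
            class = "optical_recording")
}

#' Hemodynamic recording (concentration changes)
#'
#' @param hbo,hbr numeric matrices `[n_channels x n_samples]` of HbO2 and
#'   HbR concentration changes.
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel names.
#' @return an object of class `hemo_recording`.
#' @export
hemo_recording <- function(hbo, hbr, fs, channel_names = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr)))
    stop_cfg("hemo_recording: hbo/hbr shape mismatch")
  if (anyNA(hbo) || anyNA(hbr))
    stop_cfg("hemo_recording: NaN values")
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(hbo)))
  if (length(channel_names) != nrow(hbo))
    stop_cfg("hemo_recording: channel_names length mismatch")
  rownames(hbo) <- rownames(hbr) <- channel_names
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 channel_names = channel_names),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("hemo_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, ncol(x$hbo) / x$fs))
  invisible(x)
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Converts dual-wavelength optical intensities to oxy-/deoxyhemoglobin
#' concentration changes. Per channel and wavelength the optical-density
#' change is `dA(t) = log10(I0 / I(t))` with `I0` the mean intensity over
#' the baseline window; the concentration changes solve
#' `dC(t) = eps^{-1} %*% (dA(t) / (d_cm * dpf))` with the source-detector
#' distance converted from mm to cm.
#'
#' For a `trial_set` of modality `"fnirs-raw"` (e.g. from
#' [hemo_to_raw_intensity()]) the conversion is applied trial-wise with the
#' stored baseline intensity, making the raw/hemo mapping an exact round
#' trip.
#'
#' @param x an [optical_recording()] or a raw-intensity `trial_set`.
#' @param eps extinction matrix, see [extinction_matrix()].
#' @param ... passed to methods.
#' @return a [hemo_recording()] (for recordings) or a `trial_set` of
#'   modality `"fnirs-hemo"` (for trial sets).
#' @export
beer_lambert <- function(x, eps = extinction_matrix(), ...) {
  UseMethod("beer_lambert")
}

#' @rdname beer_lambert
#' @param baseline_window integer sample range used to estimate the
#'   baseline intensity `I0` (default: the first 10 s of the recording,
#'   matching a 10-s initial rest period).
#' @export
beer_lambert.optical_recording <- function(x, eps = extinction_matrix(),
                                           baseline_window = NULL, ...) {
  eps <- as_extinction(eps)
  ns <- dim(x$intensity)[3]
  if (is.null(baseline_window))
    baseline_window <- seq_len(max(1L, min(ns, floor(10 * x$fs))))
  if (length(baseline_window) < 1L || min(baseline_window) < 1L ||
      max(baseline_window) > ns)
    stop_cfg("beer_lambert: baseline_window outside recording (1..%d)", ns)
  if (any(x$intensity <= 0))
    stop_cfg("beer_lambert: nonpositive intensity")
  K <- dim(x$intensity)[1]
  d_cm <- x$d / 10
  einv <- solve(eps)
  hbo <- matrix(0, K, ns); hbr <- matrix(0, K, ns)
  for (ch in seq_len(K)) {
    dA <- matrix(0, 2, ns)
    for (w in 1:2) {
      i0 <- mean(x$intensity[ch, w, baseline_window])
      dA[w, ] <- log10(i0 / x$intensity[ch, w, ]) / (d_cm * x$dpf[w])
    }
    dC <- einv %*% dA
    hbo[ch, ] <- dC[1, ]; hbr[ch, ] <- dC[2, ]
  }
  hemo_recording(hbo, hbr, x$fs, x$channel_names)
}

#' @rdname beer_lambert
#' @export
beer_lambert.trial_set <- function(x, eps = NULL, ...) {
  if (x$modality != "fnirs-raw")
    stop_cfg("beer_lambert: trial_set must have modality 'fnirs-raw'")
  if (is.null(eps)) eps <- attr(x, "eps")
  if (is.null(eps)) eps <- extinction_matrix()
  eps <- as_extinction(eps)
  i0 <- attr(x, "i0"); if (is.null(i0)) i0 <- 1
  dpf <- attr(x, "dpf"); if (is.null(dpf)) dpf <- c(6, 6)
  d <- attr(x, "d"); if (is.null(d)) d <- 30
  d_cm <- d / 10
  einv <- solve(eps)
  dims <- dim(x$data)
  K <- dims[2] %/% 2L
  out <- array(0, dims)
  for (tr in seq_len(dims[1])) {
    for (ch in seq_len(K)) {
      dA1 <- log10(i0 / x$data[tr, ch, ]) / (d_cm * dpf[1])
      dA2 <- log10(i0 / x$data[tr, K + ch, ]) / (d_cm * dpf[2])
      dC <- einv %*% rbind(dA1, dA2)
      out[tr, ch, ] <- dC[1, ]
      out[tr, K + ch, ] <- dC[2, ]
    }
  }
  trial_set(out, x$labels, x$subject_id, "fnirs-hemo", x$fs,
            channel_names = c(paste0("CH", seq_len(K), "_HbO"),
                              paste0("CH", seq_len(K), "_HbR")))
}

#' Restrict and reorder channels of a hemodynamic recording
#'
#' @param hemo a [hemo_recording()].
#' @param keep character vector of channel names to retain, in the desired
#'   order.
#' @return a [hemo_recording()] with channels restricted to `keep`.
#' @export
select_channels <- function(hemo, keep) {
  stopifnot(inherits(hemo, "hemo_recording"))
  missing_ch <- setdiff(keep, hemo$channel_names)
  if (length(missing_ch) > 0L)
    stop_cfg("select_channels: unknown channel(s): %s",
             paste(missing_ch, collapse = ", "))
  idx <- match(keep, hemo$channel_names)
  hemo_recording(hemo$hbo[idx, , drop = FALSE],
                 hemo$hbr[idx, , drop = FALSE],
                 hemo$fs, channel_names = keep)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase distortion) independently to every
#' channel of both chromophores. The default 0.01-0.2 Hz band retains the
#' hemodynamic response while rejecting baseline drift and
#' high-frequency physiological noise.
#'
#' @param hemo a [hemo_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (of the underlying one-pass filter).
#' @return the filtered [hemo_recording()], same length.
#' @export
bandpass <- function(hemo, low = 0.01, high = 0.2, order = 4) {
  stopifnot(inherits(hemo, "hemo_recording"))
  nyq <- hemo$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_cfg("bandpass: band [%g, %g] Hz invalid for Nyquist %g Hz",
             low, high, nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  sos <- tf_to_sos(bf)
  # the hemodynamic band edges are tiny fractions of Nyquist: the direct
  # 8th-order transfer function is ill-conditioned, so filter as a cascade
  # of zero-phase biquads after removing the (stop-band) mean
  filt1 <- function(x) {
    y <- x - mean(x)
    for (s in sos) y <- signal::filtfilt(s$b, s$a, y)
    y
  }
  filt_mat <- function(m) t(apply(m, 1, filt1))
  hemo_recording(filt_mat(hemo$hbo), filt_mat(hemo$hbr), hemo$fs,
                 hemo$channel_names)
}

# split a designed band-pass filter into second-order sections: conjugate
# pole pairs, each section carrying one zero at z = 1 and one at z = -1
tf_to_sos <- function(bf) {
  zp <- signal::as.Zpg(bf)
  p <- zp$pole
  g <- abs(Re(zp$gain))
  used <- rep(FALSE, length(p))
  secs <- list()
  for (i in seq_along(p)) {
    if (used[i]) next
    used[i] <- TRUE
    rest <- which(!used)
    j <- rest[which.min(abs(p[rest] - Conj(p[i])))]
    used[j] <- TRUE
    a <- Re(c(1, -(p[i] + p[j]), p[i] * p[j]))
    secs[[length(secs) + 1L]] <- list(a = a)
  }
  gs <- g^(1 / length(secs))
  lapply(secs, function(s) list(b = gs * c(1, 0, -1), a = s$a))
}

#' Segment a continuous recording into labeled trials
#'
#' Cuts one window per event: motor-imagery events (label 1) get a
#' `task_window_s` window and rest events (label 0) a `rest_window_s`
#' window, both starting at the event onset. Channels are stacked HbO2
#' then HbR in the output trials.
#'
#' @param hemo a [hemo_recording()].
#' @param events data frame with columns `onset_s` (seconds) and `label`
#'   (1 = motor imagery, 0 = rest).
#' @param task_window_s,rest_window_s window lengths in seconds (default
#'   10 s each, matching the analysis windows of the task paradigm).
#' @param subject_id subject identifier attached to the resulting trial set.
#' @return a `trial_set` of modality `"fnirs-hemo"`; each trial has
#'   `floor(window * fs)` samples. Task and rest windows must have equal
#'   sample counts (all trials in a set share one length).
#' @export
segment_trials <- function(hemo, events, task_window_s = 10,
                           rest_window_s = 10, subject_id = "S?") {
  stopifnot(inherits(hemo, "hemo_recording"))
  if (!is.data.frame(events) || !all(c("onset_s", "label") %in% names(events)))
    stop_cfg("segment_trials: events must have columns onset_s, label")
  ns <- ncol(hemo$hbo)
  fs <- hemo$fs
  n_task <- floor(task_window_s * fs)
  n_rest <- floor(rest_window_s * fs)
  if (nrow(events) == 0L) {
    return(trial_set(array(0, c(0L, 2L * nrow(hemo$hbo), n_task)),
                     integer(0), subject_id, "fnirs-hemo", fs))
  }
  if (n_task != n_rest)
    stop_cfg("segment_trials: task and rest windows must contain equal sample counts")
  K <- nrow(hemo$hbo)
  n_tr <- nrow(events)
  dat <- array(0, c(n_tr, 2L * K, n_task))
  labels <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    lab <- as.integer(events$label[i])
    w <- if (lab == 1L) n_task else n_rest
    start <- floor(events$onset_s[i] * fs) + 1L
    if (start < 1L || start + w - 1L > ns)
      stop_cfg("segment_trials: event %d (onset %g s) window exceeds recording",
               i, events$onset_s[i])
    idx <- start:(start + w - 1L)
    dat[i, seq_len(K), ] <- hemo$hbo[, idx]
    dat[i, K + seq_len(K), ] <- hemo$hbr[, idx]
    labels[i] <- lab
  }
  trial_set(dat, labels, subject_id, "fnirs-hemo", fs,
            channel_names = c(paste0(hemo$channel_names, "_HbO"),
                              paste0(hemo$channel_names, "_HbR")))
}
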