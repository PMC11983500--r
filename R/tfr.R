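#' Time-frequency image of a trial
#'
#' Container for the 2-D time-frequency magnitude representation of one
#' trial: one image plane per signal channel, each plane min-max normalized
#' to `[0, 1]`.
#'
#' @param pixels numeric array `[image_channels x height x width]`.
#' @param freq_axis frequencies (Hz) of the image rows.
#' @param time_axis times (s) of the image columns (after resizing, the
#'   original frame times rescaled to the output grid).
#' @param source_modality `"eeg"` or `"fnirs"`.
#' @return an object of class `time_freq_image`.
#' @export
time_freq_image <- function(pixels, freq_axis, time_axis, source_modality) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop_cfg("time_freq_image: pixels must be [channels x height x width]")
  if (any(pixels < 0) || anyNA(pixels))
    stop_cfg("time_freq_image: pixels must be nonnegative magnitudes")
  structure(list(pixels = pixels, freq_axis = freq_axis,
                 time_axis = time_axis,
                 source_modality = match.arg(source_modality,
                                             c("eeg", "fnirs"))),
            class = "time_freq_image")
}

#' @export
print.time_freq_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("time_freq_image [%s]: %d planes x %d x %d, %g-%g Hz\n",
              x$source_modality, d[1], d[2], d[3],
              min(x$freq_axis), max(x$freq_axis)))
  invisible(x)
}

# Complex Morlet CWT (frequency-domain implementation) of one signal.
# Returns |W| as a matrix [length(freqs) x length(x)]; pseudo-frequency of
# scale a is fc * fs / a with fc = omega0 / (2*pi).
cwt_morlet <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  M <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, M - n)))
  w <- 2 * pi * (0:(M - 1)) / M          # angular frequency per sample
  w[w > pi] <- w[w > pi] - 2 * pi        # wrap to (-pi, pi]
  fc <- omega0 / (2 * pi)
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    a <- fc * fs / freqs[i]              # scale in samples
    # unit-peak normalization: every scale responds identically at its own
    # pseudo-frequency, so the scalogram ridge sits at the signal frequency
    psi_hat <- exp(-0.5 * (a * w - omega0)^2) * (w > 0)
    conv <- stats::fft(X * psi_hat, inverse = TRUE) / M
    out[i, ] <- Mod(conv[seq_len(n)])
  }
  out
}

#' Wavelet scalogram image of an fNIRS trial
#'
#' Computes the complex-Morlet continuous wavelet transform magnitude of
#' every channel of a single trial over logarithmically spaced
#' pseudo-frequencies covering the hemodynamic band, min-max normalizes
#' each channel plane, and bilinearly resizes the planes to a square
#' image. The channel planes are stacked as image channels (32 planes for
#' the default 16-channel HbO2+HbR trial).
#'
#' @param trial numeric matrix `[n_channels x n_samples]` (one trial).
#' @param fs sampling rate in Hz.
#' @param n_scales number of wavelet scales (>= 4).
#' @param out_size output image side length in pixels.
#' @param freq_range pseudo-frequency span in Hz (default 0.01-0.2, the
#'   hemodynamic pass band).
#' @param omega0 Morlet centre frequency parameter.
#' @return a [time_freq_image()] with `source_modality = "fnirs"`; rows of
#'   each plane run from high to low frequency before resizing, and
#'   `freq_axis` records the pseudo-frequency of each image row.
#' @export
cwt_image <- function(trial, fs, n_scales = 16, out_size = 64,
                      freq_range = c(0.01, 0.2), omega0 = 6) {
  trial <- as.matrix(trial)
  ns <- ncol(trial)
  if (ns < 8) stop_cfg("cwt_image: need at least 8 samples, got %d", ns)
  if (n_scales < 4) stop_cfg("cwt_image: n_scales must be >= 4")
  if (freq_range[1] <= 0 || freq_range[2] >= fs / 2)
    stop_cfg("cwt_image: frequency range [%g, %g] outside (0, %g)",
             freq_range[1], freq_range[2], fs / 2)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]),
                   length.out = n_scales))   # high -> low
  K <- nrow(trial)
  pix <- array(0, c(K, out_size, out_size))
  for (ch in seq_len(K)) {
    plane <- cwt_morlet(trial[ch, ], fs, freqs, omega0)
    pix[ch, , ] <- bilinear_resize(minmax01(plane), out_size, out_size)
  }
  # pixel-row frequencies after resizing (nearest original scale row)
  row_map <- pmin(pmax(ceiling((seq_len(out_size) - 0.5) *
                                 n_scales / out_size), 1), n_scales)
  time_freq_image(pix, freqs[row_map],
                  seq(0, (ns - 1) / fs, length.out = out_size), "fnirs")
}

#' STFT spectrogram image of an EEG trial
#'
#' Short-time Fourier transform magnitude of every channel, restricted to
#' a frequency band, min-max normalized per channel plane and resized to a
#' square image.
#'
#' @param trial numeric matrix `[n_channels x n_samples]` (one trial).
#' @param fs sampling rate in Hz.
#' @param window_s Hann analysis window length in seconds.
#' @param overlap_frac fractional overlap between windows in `[0, 1)`.
#' @param band frequency band in Hz retained in the image (default
#'   4-40 Hz, the classical sensorimotor range).
#' @param out_size output image side length in pixels.
#' @return a [time_freq_image()] with `source_modality = "eeg"`.
#' @export
stft_image <- function(trial, fs, window_s = 0.5, overlap_frac = 0.5,
                       band = c(4, 40), out_size = 64) {
  trial <- as.matrix(trial)
  win_n <- floor(window_s * fs)
  if (win_n < 8) stop_cfg("stft_image: window of %d samples too short", win_n)
  if (band[2] > fs / 2)
    stop_cfg("stft_image: band upper edge %g Hz above Nyquist %g Hz",
             band[2], fs / 2)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_cfg("stft_image: overlap_frac must be in [0, 1)")
  ov <- floor(win_n * overlap_frac)
  K <- nrow(trial)
  pix <- array(0, c(K, out_size, out_size))
  freq_keep <- NULL; times <- NULL
  for (ch in seq_len(K)) {
    sp <- signal::specgram(trial[ch, ], n = win_n, Fs = fs,
                           window = signal::hanning(win_n), overlap = ov)
    keep <- sp$f >= band[1] & sp$f <= band[2]
    if (!any(keep)) stop_cfg("stft_image: no frequency bins inside band")
    mag <- Mod(sp$S[keep, , drop = FALSE])
    if (is.null(freq_keep)) { freq_keep <- sp$f[keep]; times <- sp$t }
    pix[ch, , ] <- bilinear_resize(minmax01(mag), out_size, out_size)
  }
  nb <- length(freq_keep)
  row_map <- pmin(pmax(ceiling((seq_len(out_size) - 0.5) * nb / out_size),
                       1), nb)
  time_freq_image(pix, freq_keep[row_map],
                  seq(min(times), max(times), length.out = out_size), "eeg")
}

#' Convert every trial of a trial set into a time-frequency image batch
#'
#' Applies [cwt_image()] (fNIRS) or [stft_image()] (EEG) to each trial and
#' stacks the results into a 4-d batch array in `[height x width x
#' channels x n_trials]` layout, the layout consumed by the encoders.
#'
#' @param ts a `trial_set`.
#' @param out_size image side length.
#' @param ... further arguments passed to the per-trial transform.
#' @return list with `x` (the batch array), `labels`, `subject_id`.
#' @export
trials_to_images <- function(ts, out_size = 64, ...) {
  stopifnot(inherits(ts, "trial_set"))
  nt <- n_trials(ts)
  C <- dim(ts$data)[2]
  x <- array(0, c(out_size, out_size, C, nt))
  for (i in seq_len(nt)) {
    tfi <- if (ts$modality == "eeg")
      stft_image(ts$data[i, , , drop = TRUE], ts$fs, out_size = out_size, ...)
    else
      cwt_image(ts$data[i, , , drop = TRUE], ts$fs, out_size = out_size, ...)
    # [C x H x W] -> [H x W x C]
    x[, , , i] <- aperm(tfi$pixels, c(2, 3, 1))
  }
  list(x = x, labels = ts$labels, subject_id = ts$subject_id)
}
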