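#' Configuration for the synthetic EEG/fNIRS study generator
#'
#' Bundles the acquisition and effect parameters used to simulate a
#' motor-imagery study: an fNIRS target domain (16 channels at 11 Hz,
#' 15 s task / 20 s rest trials, mirroring a typical clinical MI paradigm)
#' and an EEG source domain (22 channels at 250 Hz, 4 s trials).
#'
#' @param n_subjects number of subjects to simulate.
#' @param trials_per_class trials per class per subject (default 10, i.e.
#'   10 motor-imagery and 10 rest trials).
#' @param fs_fnirs fNIRS sampling rate in Hz.
#' @param fs_eeg EEG sampling rate in Hz.
#' @param n_channels_fnirs number of fNIRS measurement channels.
#' @param n_channels_eeg number of EEG channels.
#' @param task_s motor-imagery task duration in seconds (also the trial
#'   window length used for every generated trial).
#' @param rest_s rest duration between tasks in seconds.
#' @param effect_amp amplitude of the task-evoked HbO2 response
#'   (dimensionless, in units of the noise floor).
#' @param noise_sd standard deviation of the background noise.
#' @param subject_gain_sd log-sd of the per-subject multiplicative response
#'   gain (log-normal).
#' @param subject_latency_sd sd in seconds of the per-subject response
#'   latency shift (normal).
#' @param seed integer seed; identical configuration plus seed yields
#'   bit-identical data.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8, trials_per_class = 10,
                         fs_fnirs = 11, fs_eeg = 250,
                         n_channels_fnirs = 16, n_channels_eeg = 22,
                         task_s = 15, rest_s = 20,
                         effect_amp = 1, noise_sd = 4,
                         subject_gain_sd = 0.8, subject_latency_sd = 1.0,
                         seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_scalar(trials_per_class, "trials_per_class", lower = 1, integer = TRUE)
  check_scalar(fs_fnirs, "fs_fnirs", lower = 0, strict_lower = TRUE)
  check_scalar(fs_eeg, "fs_eeg", lower = 0, strict_lower = TRUE)
  check_scalar(n_channels_fnirs, "n_channels_fnirs", lower = 1, integer = TRUE)
  check_scalar(n_channels_eeg, "n_channels_eeg", lower = 1, integer = TRUE)
  check_scalar(task_s, "task_s", lower = 0, strict_lower = TRUE)
  check_scalar(rest_s, "rest_s", lower = 0, strict_lower = TRUE)
  check_scalar(effect_amp, "effect_amp", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_scalar(subject_gain_sd, "subject_gain_sd", lower = 0)
  check_scalar(subject_latency_sd, "subject_latency_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_class = as.integer(trials_per_class),
    fs_fnirs = fs_fnirs, fs_eeg = fs_eeg,
    n_channels_fnirs = as.integer(n_channels_fnirs),
    n_channels_eeg = as.integer(n_channels_eeg),
    task_s = task_s, rest_s = rest_s,
    effect_amp = effect_amp, noise_sd = noise_sd,
    subject_gain_sd = subject_gain_sd,
    subject_latency_sd = subject_latency_sd,
    seed = as.integer(seed)), class = "synth_config")
}

#' Labeled set of per-trial signal windows
#'
#' @param data numeric array `[n_trials x n_channels x n_samples]`.
#' @param labels per-trial class labels (integer 0/1 for the fNIRS target
#'   domain, factor/character for the EEG source domain).
#' @param subject_id subject identifier.
#' @param modality one of `"fnirs-hemo"`, `"fnirs-raw"`, `"eeg"`.
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel names (length `n_channels`).
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(data, labels, subject_id, modality, fs,
                      channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_cfg("trial_set: 'data' must be a 3-d array [trials x channels x samples]")
  if (length(labels) != dim(data)[1])
    stop_cfg("trial_set: labels length %d != n_trials %d",
             length(labels), dim(data)[1])
  if (anyNA(data) || any(!is.finite(data)))
    stop_cfg("trial_set: data contain NaN/Inf")
  modality <- match.arg(modality, c("fnirs-hemo", "fnirs-raw", "eeg"))
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop_cfg("trial_set: channel_names length mismatch")
  structure(list(data = data, labels = labels, subject_id = subject_id,
                 modality = modality, fs = fs,
                 channel_names = channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_set [%s] subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$modality, as.character(x$subject_id), d[1], d[2], d[3], x$fs))
  cat("  labels:", paste(utils::head(table(x$labels), 6),
                         names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(ts) dim(ts$data)[1]

#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma HRF (response peak near 5-6 s, undershoot near
#' 15-16 s, undershoot ratio 1/6), sampled on a regular grid and scaled to
#' unit peak.
#'
#' @param t time points in seconds (nonnegative).
#' @return numeric vector of HRF values, peak 1.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Deterministic integer stream seed for (config seed, subject, role).
subject_seed <- function(seed, subject_id, role = 0L) {
  id <- as.character(subject_id)
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  (as.integer(seed) * 7919L + h * 131L + as.integer(role) * 17L) %% 2147483647L
}

# Task-evoked response: boxcar of `dur_s` starting at `onset_s`, convolved
# with the canonical HRF on the trial's sampling grid, unit-amplitude boxcar.
hrf_boxcar_response <- function(n, fs, onset_s, dur_s) {
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= onset_s & t < onset_s + dur_s)
  hrf <- canonical_hrf(t)
  # discrete approximation of the continuous convolution (scaled by dt)
  out <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)] / fs
  out
}

#' Simulate one subject's fNIRS trial set (hemodynamic units)
#'
#' Motor-imagery trials carry a canonical-HRF-convolved boxcar response on
#' the contralateral half of the channels, scaled by `effect_amp` and a
#' per-subject log-normal gain, with a per-subject latency shift of the
#' onset. The HbR response is -0.3 times the HbO2 response. Every trial
#' (task and rest) carries 1/f noise plus a Mayer-wave sinusoid near 0.1 Hz
#' with random phase; the Mayer wave and half of the 1/f variance are
#' systemic (one realization shared by all channels of the trial, as in
#' real recordings where superficial physiology dominates), the rest is
#' channel-local. Rest trials have no task component.
#'
#' Channels are stacked as HbO2 then HbR: output channel count is
#' `2 * n_channels_fnirs`, names `CH<i>_HbO` / `CH<i>_HbR`.
#'
#' @param cfg a [synth_config()].
#' @param subject_id subject identifier (used to derive the stream seed, so
#'   different subjects get independent data under the same config).
#' @return a [trial_set()] with modality `"fnirs-hemo"`, trial length
#'   `floor(task_s * fs_fnirs)` samples, labels 1 = motor imagery, 0 = rest.
#' @export
generate_fnirs_subject <- function(cfg, subject_id) {
  if (!inherits(cfg, "synth_config"))
    stop_cfg("configuration error: 'cfg' must be a synth_config")
  fs <- cfg$fs_fnirs
  n <- floor(cfg$task_s * fs)
  K <- cfg$n_channels_fnirs
  n_tr <- 2L * cfg$trials_per_class
  labels <- rep(c(1L, 0L), each = cfg$trials_per_class)
  active <- seq_len(max(1L, K %/% 2L))   # "contralateral" half

  with_seed(subject_seed(cfg$seed, subject_id, 1L), {
    gain <- stats::rlnorm(1, 0, cfg$subject_gain_sd)
    latency <- stats::rnorm(1, 0, cfg$subject_latency_sd)
    onset <- max(0, latency)
    resp <- hrf_boxcar_response(n, fs, onset, cfg$task_s) *
      cfg$effect_amp * gain
    dat <- array(0, c(n_tr, 2L * K, n))
    t <- (seq_len(n) - 1) / fs
    # physiological noise: a systemic (global) component shared by every
    # channel of a trial — Mayer wave plus slow drift, which is what
    # dominates real fNIRS recordings and cannot be removed by averaging
    # across channels — and an independent channel-local component;
    # variance split equally between the two
    loc_sd <- cfg$noise_sd / sqrt(2)
    for (tr in seq_len(n_tr)) {
      f_mayer <- stats::runif(1, 0.095, 0.105)
      ph <- stats::runif(1, 0, 2 * pi)
      mayer <- 0.5 * cfg$noise_sd * sin(2 * pi * f_mayer * t + ph)
      glob_hbo <- pink_noise(n, loc_sd) + mayer
      glob_hbr <- pink_noise(n, loc_sd) - 0.3 * mayer
      task <- if (labels[tr] == 1L) resp else 0
      for (ch in seq_len(K)) {
        task_ch <- if (labels[tr] == 1L && ch %in% active) task else 0
        dat[tr, ch, ] <- glob_hbo + pink_noise(n, loc_sd) + task_ch
        dat[tr, K + ch, ] <- glob_hbr + pink_noise(n, loc_sd) - 0.3 * task_ch
      }
    }
    trial_set(dat, labels, subject_id, "fnirs-hemo", fs,
              channel_names = c(paste0("CH", seq_len(K), "_HbO"),
                                paste0("CH", seq_len(K), "_HbR")))
  })
}

#' Simulate one subject's EEG trial set
#'
#' Each class modulates mu-band (8-13 Hz) oscillation amplitude over a
#' class-specific subset of channels, superimposed on 1/f background noise
#' (an amplitude-modulation surrogate for event-related (de)synchronization).
#' Trials are 4 s long at `fs_eeg`.
#'
#' @param cfg a [synth_config()].
#' @param subject_id subject identifier.
#' @param classes nonempty character vector of class labels (e.g.
#'   `c("left", "right")` or the four-class set
#'   `c("left", "right", "foot", "tongue")`).
#' @param trial_s trial duration in seconds.
#' @return a [trial_set()] with modality `"eeg"`; labels are the class
#'   names, `trials_per_class` trials per class.
#' @export
generate_eeg_subject <- function(cfg, subject_id, classes = c("left", "right"),
                                 trial_s = 4) {
  if (!inherits(cfg, "synth_config"))
    stop_cfg("configuration error: 'cfg' must be a synth_config")
  if (length(classes) < 1L || anyDuplicated(classes))
    stop_cfg("configuration error: 'classes' must be a nonempty set of distinct labels")
  fs <- cfg$fs_eeg
  n <- floor(trial_s * fs)
  K <- cfg$n_channels_eeg
  n_cl <- length(classes)
  n_tr <- n_cl * cfg$trials_per_class
  labels <- rep(classes, each = cfg$trials_per_class)
  # class-specific spatial pattern: contiguous channel block per class
  blocks <- split(seq_len(K), cut(seq_len(K), breaks = n_cl, labels = FALSE))

  with_seed(subject_seed(cfg$seed, subject_id, 2L), {
    gain <- stats::rlnorm(1, 0, cfg$subject_gain_sd)
    dat <- array(0, c(n_tr, K, n))
    t <- (seq_len(n) - 1) / fs
    for (tr in seq_len(n_tr)) {
      k <- match(labels[tr], classes)
      for (ch in seq_len(K)) {
        amp <- if (ch %in% blocks[[k]]) cfg$effect_amp * gain
               else 0.1 * cfg$effect_amp * gain
        f_mu <- stats::runif(1, 8, 13)
        ph <- stats::runif(1, 0, 2 * pi)
        dat[tr, ch, ] <- pink_noise(n, cfg$noise_sd) +
          amp * cfg$noise_sd * sin(2 * pi * f_mu * t + ph)
      }
    }
    trial_set(dat, labels, subject_id, "eeg", fs)
  })
}

#' Convert hemodynamic trials to raw dual-wavelength optical intensities
#'
#' Inverts the modified Beer-Lambert law trial-by-trial: the concentration
#' changes are mapped to optical-density changes
#' `dA = d_cm * dpf * (eps %*% dC)` and then to intensities
#' `I = I0 * 10^(-dA)`. Applying [beer_lambert()] to the result recovers
#' the input concentrations (round trip exact to numerical precision).
#'
#' @param trials a `trial_set` with modality `"fnirs-hemo"` whose channels
#'   are stacked HbO2 then HbR (as produced by [generate_fnirs_subject()]).
#' @param eps 2x2 extinction matrix `[wavelength x chromophore]` in
#'   1/(mM*cm); see [extinction_matrix()].
#' @param dpf differential pathlength factor, length 1 or 2 (per wavelength).
#' @param d source-detector separation in mm.
#' @param i0 baseline intensity (arbitrary optical units).
#' @return a `trial_set` with modality `"fnirs-raw"`: per optical channel,
#'   two wavelength rows (`CH<i>_W1` block then `CH<i>_W2` block); the
#'   baseline `i0`, `eps`, `dpf` and `d` are attached as attributes.
#' @export
hemo_to_raw_intensity <- function(trials, eps = extinction_matrix(),
                                  dpf = c(6, 6), d = 30, i0 = 1) {
  stopifnot(inherits(trials, "trial_set"))
  if (trials$modality != "fnirs-hemo")
    stop_cfg("hemo_to_raw_intensity: expected modality 'fnirs-hemo', got '%s'",
             trials$modality)
  eps <- as_extinction(eps)
  check_scalar(d, "d", lower = 0, strict_lower = TRUE)
  check_scalar(i0, "i0", lower = 0, strict_lower = TRUE)
  dpf <- rep_len(dpf, 2)
  dims <- dim(trials$data)
  K <- dims[2] %/% 2L
  if (dims[2] != 2L * K)
    stop_cfg("hemo_to_raw_intensity: channel count must be even (HbO2+HbR stacks)")
  d_cm <- d / 10
  out <- array(0, dims)
  for (tr in seq_len(dims[1])) {
    hbo <- trials$data[tr, seq_len(K), , drop = FALSE]
    hbr <- trials$data[tr, K + seq_len(K), , drop = FALSE]
    for (w in 1:2) {
      dA <- d_cm * dpf[w] * (eps[w, 1] * hbo + eps[w, 2] * hbr)
      out[tr, (w - 1L) * K + seq_len(K), ] <- i0 * 10^(-dA)
    }
  }
  raw <- trial_set(out, trials$labels, trials$subject_id, "fnirs-raw",
                   trials$fs,
                   channel_names = c(paste0("CH", seq_len(K), "_W1"),
                                     paste0("CH", seq_len(K), "_W2")))
  attr(raw, "i0") <- i0; attr(raw, "eps") <- eps
  attr(raw, "dpf") <- dpf; attr(raw, "d") <- d
  raw
}

#' Simulate a whole multi-subject fNIRS study
#'
#' @param cfg a [synth_config()].
#' @return list of `trial_set` objects, one per subject (`S1`, `S2`, ...).
#' @export
generate_fnirs_study <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(i)
    generate_fnirs_subject(cfg, paste0("S", i)))
}
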