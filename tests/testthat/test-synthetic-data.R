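test_that("synth_config validates fields and names the offender", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_subjects = 0), "n_subjects")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(effect_amp = -1), "effect_amp")
  expect_error(synth_config(fs_fnirs = -2), "fs_fnirs")
})

test_that("fNIRS generation is deterministic in (config, seed) and varies with seed", {
  cfg1 <- synth_config(n_subjects = 1, trials_per_class = 3, seed = 1)
  a <- generate_fnirs_subject(cfg1, "S1")
  b <- generate_fnirs_subject(cfg1, "S1")
  expect_identical(a$data, b$data)
  cfg2 <- synth_config(n_subjects = 1, trials_per_class = 3, seed = 2)
  c_ <- generate_fnirs_subject(cfg2, "S1")
  expect_false(identical(a$data, c_$data))
  # different subjects under one config are independent draws
  d <- generate_fnirs_subject(cfg1, "S2")
  expect_false(identical(a$data, d$data))
})

test_that("noise-free MI trials reproduce the brute-force HRF convolution peak", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 2,
                      effect_amp = 1, noise_sd = 1e-9,
                      subject_gain_sd = 0, subject_latency_sd = 0, seed = 3)
  ts <- generate_fnirs_subject(cfg, "S1")
  n <- dim(ts$data)[3]
  expected <- oracle_hrf_boxcar(n, cfg$fs_fnirs, 0, cfg$task_s)
  mi <- which(ts$labels == 1)[1]
  got <- ts$data[mi, 1, ]   # active HbO channel
  expect_equal(max(got), max(expected), tolerance = 1e-6)
  expect_equal(got, expected, tolerance = 1e-5)
  # HbR mirrors HbO at -0.3
  K <- cfg$n_channels_fnirs
  expect_equal(ts$data[mi, K + 1, ], -0.3 * got, tolerance = 1e-6)
  # rest trials carry no task component
  rest <- which(ts$labels == 0)[1]
  expect_lt(max(abs(ts$data[rest, 1, ])), 1e-6)
})

test_that("zero effect amplitude makes MI and rest statistically indistinguishable", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 20,
                      effect_amp = 0, seed = 4)
  ts <- generate_fnirs_subject(cfg, "S1")
  ch_means <- apply(ts$data[, 1:8, ], 1, mean)   # active-channel means
  p <- stats::wilcox.test(ch_means[ts$labels == 1],
                          ch_means[ts$labels == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("EEG classes are separable by band power when modulation is strong", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 20,
                      effect_amp = 6, noise_sd = 0.05,
                      subject_gain_sd = 0, seed = 5)
  ts <- generate_eeg_subject(cfg, "S1", classes = c("left", "right"))
  expect_equal(oracle_bandpower_acc(ts, c("left", "right")), 1.0)
})

test_that("EEG with zero modulation classifies at chance", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 20,
                      effect_amp = 0, seed = 6)
  ts <- generate_eeg_subject(cfg, "S1", classes = c("left", "right"))
  acc <- oracle_bandpower_acc(ts, c("left", "right"))
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("EEG label construction matches the requested class set", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 5, seed = 7)
  cls <- c("left", "right", "foot", "tongue")
  ts <- generate_eeg_subject(cfg, "S1", classes = cls)
  expect_setequal(unique(ts$labels), cls)
  expect_true(all(table(ts$labels) == 5))
  expect_equal(dim(ts$data)[3], floor(4 * cfg$fs_eeg))
  expect_error(generate_eeg_subject(cfg, "S1", classes = character(0)),
               "classes")
})

test_that("hemo -> raw -> hemo is an identity and zero concentration is baseline", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 3, seed = 8)
  ts <- generate_fnirs_subject(cfg, "S1")
  ts$data <- ts$data * 1e-3   # generator units -> mM-scale concentrations
  raw <- hemo_to_raw_intensity(ts, i0 = 2.5)
  expect_equal(raw$modality, "fnirs-raw")
  back <- beer_lambert(raw)
  expect_lt(max(abs(back$data - ts$data)), 1e-8)
  # zero concentration change -> constant baseline intensity
  z <- ts; z$data[] <- 0
  rawz <- hemo_to_raw_intensity(z, i0 = 3)
  expect_true(all(abs(rawz$data - 3) < 1e-12))
  # singular extinction matrix is rejected
  expect_error(hemo_to_raw_intensity(ts, eps = matrix(1, 2, 2)),
               "singular|ill-conditioned")
})

test_that("a unit HbO2 change produces the hand-computed optical densities", {
  eps <- extinction_matrix()
  dpf <- c(6, 6); d <- 30
  dat <- array(0, c(1, 2, 1))
  dat[1, 1, 1] <- 1   # dHbO2 = 1, dHbR = 0
  ts <- trial_set(dat, 1L, "S1", "fnirs-hemo", 11)
  raw <- hemo_to_raw_intensity(ts, eps, dpf, d, i0 = 1)
  # dA_w = (d/10) * dpf_w * eps[w, HbO2]; I = 10^(-dA)
  dA <- unname(3 * 6 * eps[, 1])
  expect_equal(raw$data[1, 1, 1], 10^(-dA[1]), tolerance = 1e-12)
  expect_equal(raw$data[1, 2, 1], 10^(-dA[2]), tolerance = 1e-12)
})
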