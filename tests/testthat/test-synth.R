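test_that("clean ECG generator places R peaks as scheduled", {
  p <- synth_params(duration_s = 10, heart_rate_bpm = 60, rr_jitter = 0,
                    baseline_wander_amp = 0, burst_noise_amp = 0,
                    burst_rate = 0, impulse_amp = 0, impulse_rate = 0)
  g <- generate_clean_ecg(p)
  expect_true(length(g$r_peaks) %in% c(10L, 11L))
  expect_true(all(diff(g$r_peaks) == 200L))

  # zero amplitudes: silent signal, schedule still returned
  p0 <- synth_params(duration_s = 10, heart_rate_bpm = 60, rr_jitter = 0,
                     wave_amplitudes = c(p = 0, q = 0, r = 0, s = 0, t = 0))
  g0 <- generate_clean_ecg(p0)
  expect_true(all(g0$samples == 0))
  expect_gt(length(g0$r_peaks), 0)

  # global argmax of the waveform sits on (within 1 sample of) a listed peak
  p42 <- synth_params(duration_s = 30, seed = 42)
  g42 <- generate_clean_ecg(p42)
  expect_true(min(abs(which.max(g42$samples) - g42$r_peaks)) <= 1)
})

test_that("generator rejects invalid parameters", {
  expect_error(synth_params(duration_s = 0), "duration_s")
  expect_error(synth_params(fs = -1), "fs")
  expect_error(synth_params(heart_rate_bpm = 300), "heart_rate_bpm")
  expect_error(synth_params(leakage_coeff = 1), "leakage_coeff")
  expect_error(generate_motion_noise(synth_params(), 0), "n_samples")
})

test_that("motion noise components behave as stated", {
  # all amplitudes zero -> silence
  pz <- synth_params(baseline_wander_amp = 0, burst_noise_amp = 0,
                     burst_rate = 0, impulse_amp = 0, impulse_rate = 0)
  expect_true(all(generate_motion_noise(pz, 2000) == 0))

  # wander only: >= 95% of spectral energy below 0.8 Hz (periodogram oracle)
  pw <- synth_params(duration_s = 120, baseline_wander_amp = 1,
                     burst_noise_amp = 0, burst_rate = 0,
                     impulse_amp = 0, impulse_rate = 0, seed = 5)
  x <- generate_motion_noise(pw, 120 * 200)
  spec <- Mod(fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * 200 / n
  half <- freq <= 100
  expect_gt(sum(spec[half & freq < 0.8]) / sum(spec[half]), 0.95)

  # determinism
  expect_identical(generate_motion_noise(pw, 5000),
                   generate_motion_noise(pw, 5000))

  # doubling the burst amplitude quadruples the burst power (exact scaling)
  pb1 <- synth_params(duration_s = 120, baseline_wander_amp = 0,
                      burst_noise_amp = 1, burst_rate = 10,
                      impulse_amp = 0, impulse_rate = 0, seed = 9)
  pb2 <- synth_params(duration_s = 120, baseline_wander_amp = 0,
                      burst_noise_amp = 2, burst_rate = 10,
                      impulse_amp = 0, impulse_rate = 0, seed = 9)
  b1 <- generate_motion_noise(pb1, 120 * 200)
  b2 <- generate_motion_noise(pb2, 120 * 200)
  expect_equal(mean(b2^2) / mean(b1^2), 4, tolerance = 0.05)
})

test_that("measurement model algebra holds with noise off", {
  p <- synth_params(duration_s = 20, baseline_wander_amp = 0,
                    burst_noise_amp = 0, burst_rate = 0, impulse_amp = 0,
                    impulse_rate = 0, sensor_noise_std = 0,
                    leakage_coeff = 0.3)
  g <- generate_record(p)
  s <- g$truth$clean_ecg
  expect_equal(g$record$sigL - g$record$sigR, s, tolerance = 1e-12)
  refs <- build_references(g$record)
  # residual cardiac content of the reference is leakage_coeff * s / 2
  expect_equal(refs$r_left, 0.3 * s / 2, tolerance = 1e-12)
  # leak 0: ideal reference
  p0 <- synth_params(duration_s = 5, baseline_wander_amp = 0,
                     burst_noise_amp = 0, burst_rate = 0, impulse_amp = 0,
                     impulse_rate = 0, sensor_noise_std = 0,
                     leakage_coeff = 0)
  g0 <- generate_record(p0)
  expect_true(all(abs(build_references(g0$record)$r_left) < 1e-12))
})

test_that("reference correlates with motion, not with the cardiac signal", {
  g <- generate_record(synth_params(duration_s = 120, seed = 1))
  refs <- build_references(g$record)
  expect_gt(abs(cor(refs$r_left, g$truth$motion_noise)),
            abs(cor(refs$r_left, g$truth$clean_ecg)))
})

test_that("records are deterministic given the seed", {
  p <- synth_params(duration_s = 10, seed = 77)
  a <- generate_record(p)
  b <- generate_record(p)
  expect_identical(a$record$sigL, b$record$sigL)
  expect_identical(a$truth$true_r_peaks, b$truth$true_r_peaks)
  expect_identical(a$record$meta$seed, 77L)
})

test_that("noise-free record round-trips through ECGm to perfect detection", {
  p <- noise_preset("clean", duration_s = 60, seed = 3, sensor_noise_std = 0)
  g <- generate_record(p)
  d <- build_measured_ecg(g$record)
  truth <- peak_set(g$truth$true_r_peaks, g$record$fs)
  det <- pan_tompkins(d, g$record$fs)
  m <- match_peaks(truth, det)
  expect_equal(m$fn, 0L)
  expect_equal(m$fp, 0L)
})
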