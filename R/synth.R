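#' Parameters for the synthetic capacitive-ECG generator
#'
#' Describes one synthetic recording: a Gaussian-bump PQRST waveform with
#' jittered RR intervals, additive motion noise (baseline wander, bursts,
#' impulses), per-sensor white noise, and linear coupling of the motion
#' noise into the four sensor channels.  Amplitudes are in arbitrary sensor
#' units with the R wave normalised near 1.
#'
#' `wave_amplitudes` are magnitudes (all non-negative); the Q and S waves
#' are rendered as negative deflections.  P and T default small because
#' capacitive sensors barely pick them up.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz (default 200).
#' @param heart_rate_bpm mean heart rate, in (20, 240).
#' @param rr_jitter fractional standard deviation of RR intervals.
#' @param wave_amplitudes named magnitudes for p, q, r, s, t.
#' @param wave_widths named Gaussian widths (seconds) for p, q, r, s, t.
#' @param baseline_wander_amp RMS amplitude of the sub-0.8 Hz wander.
#' @param burst_noise_amp within-burst noise standard deviation.
#' @param burst_rate expected bursts per minute.
#' @param impulse_amp single-sample spike magnitude.
#' @param impulse_rate expected spikes per minute.
#' @param leakage_coeff fraction of the cardiac signal remaining in each
#'   reference channel difference, in `[0, 1)`; 0 means ideal references.
#' @param sensor_noise_std white measurement noise per sensor.
#' @param seed integer RNG seed; the whole record is a deterministic
#'   function of the parameters including the seed.
#' @return object of class `"synth_params"`.
#' @export
synth_params <- function(duration_s = 60, fs = 200, heart_rate_bpm = 70,
                         rr_jitter = 0.05,
                         wave_amplitudes = c(p = 0.06, q = 0.12, r = 1,
                                             s = 0.18, t = 0.12),
                         wave_widths = c(p = 0.045, q = 0.012, r = 0.013,
                                         s = 0.014, t = 0.09),
                         baseline_wander_amp = 18, burst_noise_amp = 12,
                         burst_rate = 10, impulse_amp = 22, impulse_rate = 18,
                         leakage_coeff = 0.1, sensor_noise_std = 0.02,
                         seed = 1L) {
  .check_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  .check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  .check_scalar_num(heart_rate_bpm, "heart_rate_bpm", 20, 240,
                    strict_lower = TRUE, strict_upper = TRUE)
  .check_scalar_num(rr_jitter, "rr_jitter", 0)
  .check_scalar_num(leakage_coeff, "leakage_coeff", 0, 1, strict_upper = TRUE)
  for (nm in c("baseline_wander_amp", "burst_noise_amp", "burst_rate",
               "impulse_amp", "impulse_rate", "sensor_noise_std"))
    .check_scalar_num(get(nm), nm, 0)
  waves <- c("p", "q", "r", "s", "t")
  wave_amplitudes <- wave_amplitudes[waves]
  wave_widths <- wave_widths[waves]
  if (anyNA(wave_amplitudes) || any(wave_amplitudes < 0))
    .fail("'wave_amplitudes' needs non-negative entries named p,q,r,s,t")
  if (anyNA(wave_widths) || any(wave_widths <= 0))
    .fail("'wave_widths' needs positive entries named p,q,r,s,t")
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm, rr_jitter = rr_jitter,
                 wave_amplitudes = wave_amplitudes, wave_widths = wave_widths,
                 baseline_wander_amp = baseline_wander_amp,
                 burst_noise_amp = burst_noise_amp, burst_rate = burst_rate,
                 impulse_amp = impulse_amp, impulse_rate = impulse_rate,
                 leakage_coeff = leakage_coeff,
                 sensor_noise_std = sensor_noise_std,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Noise presets for the synthetic generator
#'
#' `"clean"` emulates a stable subject (no motion, ideal references),
#' `"moderate"` emulates ordinary body motion / driving vibration with
#' imperfect references, and `"abnormal"` emulates severe artifacts
#' (sensor separation, unpaved-road vibration) that no algorithm is
#' expected to remove.
#'
#' @param preset one of `"clean"`, `"moderate"`, `"abnormal"`.
#' @param ... overrides passed on to [synth_params()].
#' @return a [synth_params()] object.
#' @export
noise_preset <- function(preset = c("clean", "moderate", "abnormal"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clean = list(baseline_wander_amp = 0, burst_noise_amp = 0,
                 burst_rate = 0, impulse_amp = 0, impulse_rate = 0,
                 leakage_coeff = 0, sensor_noise_std = 0.01),
    moderate = list(),   # the synth_params defaults *are* the moderate world
    abnormal = list(baseline_wander_amp = 60, burst_noise_amp = 60,
                    burst_rate = 30, impulse_amp = 120, impulse_rate = 60,
                    leakage_coeff = 0.2, sensor_noise_std = 0.05))
  do.call(synth_params, modifyList(base, list(...)))
}

# ---- internal generators (assume RNG already seeded by caller) ----

.gen_clean <- function(params) {
  fs <- params$fs
  n <- as.integer(round(params$duration_s * fs))
  rr_mean <- 60 / params$heart_rate_bpm * fs       # samples
  peaks <- integer(0)
  pos <- round(0.35 * fs)
  while (pos < n) {
    peaks <- c(peaks, as.integer(round(pos)))
    rr <- rr_mean * (1 + params$rr_jitter * rnorm(1))
    rr <- min(max(rr, 0.33 * rr_mean), 1.5 * rr_mean)
    pos <- pos + rr
  }
  # canonical wave offsets relative to R, seconds; Q and S deflect downward
  offs <- c(p = -0.20, q = -0.030, r = 0, s = 0.035, t = 0.25)
  sgn <- c(p = 1, q = -1, r = 1, s = -1, t = 1)
  x <- numeric(n)
  amp <- params$wave_amplitudes
  wid <- params$wave_widths
  for (pk in peaks) {
    for (wv in names(offs)) {
      c0 <- pk + offs[[wv]] * fs
      halfspan <- as.integer(ceiling(4 * wid[[wv]] * fs))
      i0 <- max(1L, as.integer(floor(c0)) - halfspan)
      i1 <- min(n, as.integer(ceiling(c0)) + halfspan)
      if (i0 > i1) next
      idx <- i0:i1
      x[idx] <- x[idx] + sgn[[wv]] * amp[[wv]] *
        exp(-((idx - c0) / (wid[[wv]] * fs))^2 / 2)
    }
  }
  list(samples = x, r_peaks = peaks)
}

.gen_noise <- function(params, n) {
  fs <- params$fs
  dur_min <- n / fs / 60
  out <- numeric(n)
  t <- seq_len(n) / fs
  if (params$baseline_wander_amp > 0) {
    k <- 4L
    f <- runif(k, 0.05, 0.8)
    ph <- runif(k, 0, 2 * pi)
    a <- runif(k, 0.5, 1)
    w <- drop(cos(outer(2 * pi * t, f) + rep(ph, each = n)) %*% a)
    w <- w / max(sd(w), .Machine$double.eps) * params$baseline_wander_amp
    out <- out + w
  }
  if (params$burst_noise_amp > 0 && params$burst_rate > 0) {
    nb <- rpois(1, params$burst_rate * dur_min)
    for (b in seq_len(nb)) {
      len <- as.integer(round(runif(1, 0.5, 2.5) * fs))
      start <- as.integer(floor(runif(1, 1, max(1, n - len))))
      idx <- start:min(n, start + len - 1L)
      g <- .lowpass(rnorm(length(idx)), fs, 10)
      g <- g / max(sd(g), .Machine$double.eps) * params$burst_noise_amp
      taper <- sin(pi * (seq_along(idx) - 0.5) / length(idx))^2
      out[idx] <- out[idx] + g * taper
    }
  }
  if (params$impulse_amp > 0 && params$impulse_rate > 0) {
    ni <- rpois(1, params$impulse_rate * dur_min)
    if (ni > 0) {
      pos <- sample.int(n, min(ni, n))
      out[pos] <- out[pos] + sample(c(-1, 1), length(pos), replace = TRUE) *
        params$impulse_amp
    }
  }
  out
}

# short FIR coupling path, unit gain at DC
.gen_coupling <- function(len = 5L) {
  h <- runif(len, 0.2, 1)
  h / sum(h)
}

.fir <- function(h, x) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_along(h)) {
    if (h[k] == 0) next
    lag <- k - 1L
    if (lag == 0L) y <- y + h[k] * x
    else y[(lag + 1L):n] <- y[(lag + 1L):n] + h[k] * x[1:(n - lag)]
  }
  y
}

#' Generate a clean PQRST waveform with known R peaks
#'
#' Sum of per-beat Gaussian bumps for the P, Q, R, S and T waves placed at
#' fixed offsets around each scheduled R position; RR intervals are drawn
#' around the mean heart rate with fractional jitter `rr_jitter`.
#'
#' @param params a [synth_params()] object.
#' @return list with `samples` (numeric) and `r_peaks` (1-based sample
#'   indices of the scheduled R maxima).
#' @export
generate_clean_ecg <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  .gen_clean(params)
}

#' Generate motion noise
#'
#' Sum of (a) baseline wander: random-phase sinusoids below 0.8 Hz with RMS
#' `baseline_wander_amp`; (b) Poisson-scheduled bursts of 10 Hz low-passed,
#' Hann-tapered white noise with standard deviation `burst_noise_amp`; and
#' (c) Poisson-scheduled single-sample spikes of `±impulse_amp`.
#'
#' @param params a [synth_params()] object.
#' @param n_samples number of samples to generate.
#' @return numeric vector of length `n_samples`.
#' @export
generate_motion_noise <- function(params, n_samples) {
  stopifnot(inherits(params, "synth_params"))
  if (n_samples <= 0) .fail("'n_samples' must be positive")
  set.seed(params$seed + 1L)
  .gen_noise(params, as.integer(n_samples))
}

#' Generate a synthetic four-channel capacitive-ECG record
#'
#' Measurement model: the outer sensors see opposite cardiac polarities
#' `±s/2`, the inner sensors see an attenuated cardiac pickup, and every
#' sensor sees the motion noise through its own short unit-DC-gain FIR
#' coupling path plus independent white noise:
#' \deqn{sigL = +s/2 + h_L * n + v_L}
#' \deqn{sigR = -s/2 + h_R * n + v_R}
#' \deqn{sigaL = +(1 - \lambda) s/2 + h_{aL} * n + v_{aL}}
#' \deqn{sigaR = -(1 - \lambda) s/2 + h_{aR} * n + v_{aR}}
#' so that `sigL - sigR` recovers `s` plus differential noise, and the
#' reference `rL = sigL - sigaL` carries motion information plus a residual
#' `leakage_coeff * s / 2` of the cardiac signal (the imperfect-correlation
#' condition; `leakage_coeff = 0` gives ideal references).
#'
#' @param params a [synth_params()] object.
#' @return list with `record` (a [cecg_record()]) and `truth` (list with
#'   `true_r_peaks`, `clean_ecg`, `motion_noise`).
#' @export
generate_record <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- as.integer(round(params$duration_s * params$fs))
  set.seed(params$seed)
  clean <- .gen_clean(params)
  set.seed(params$seed + 1L)
  noise <- .gen_noise(params, n)
  set.seed(params$seed + 2L)
  hL <- .gen_coupling(); hR <- .gen_coupling()
  haL <- .gen_coupling(); haR <- .gen_coupling()
  v <- function() if (params$sensor_noise_std > 0)
    rnorm(n, sd = params$sensor_noise_std) else numeric(n)
  s <- clean$samples
  lam <- params$leakage_coeff
  sigL <-  s / 2             + .fir(hL, noise) + v()
  sigR <- -s / 2             + .fir(hR, noise) + v()
  sigaL <-  (1 - lam) * s / 2 + .fir(haL, noise) + v()
  sigaR <- -(1 - lam) * s / 2 + .fir(haR, noise) + v()
  rec <- cecg_record(params$fs, sigL, sigR, sigaL, sigaR,
                     ecg_contact = s,
                     meta = list(seed = params$seed, params = params))
  truth <- list(true_r_peaks = clean$r_peaks, clean_ecg = s,
                motion_noise = noise)
  list(record = rec, truth = truth)
}
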