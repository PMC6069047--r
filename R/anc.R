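#' Active-noise-cancellation configuration
#'
#' Bundles the adaptive-filter configuration with the processing-window
#' layout (6-s windows with 2-s overlap by default, so that R peaks near
#' window boundaries are handled stably) and the optional postprocessing
#' fallback that substitutes the raw measured ECG for a window whose
#' filtered version looks abnormal.
#'
#' @param filter a [filter_config()].
#' @param window_s processing-window length in seconds (default 6).
#' @param overlap_s overlap between consecutive windows (default 2);
#'   must satisfy `window_s > overlap_s >= 0`.
#' @param postprocess enable the per-window fallback (default `FALSE`;
#'   evaluation comparisons are cleaner without it, and the synthetic data
#'   lack the hardware glitches it guards against).
#' @param pp_rr_ratio_bounds allowed ratio of consecutive RR intervals from
#'   three consecutively detected R peaks.
#' @param pp_power_ratio_max ceiling on filtered/raw window power.
#' @return object of class `"anc_config"`.
#' @export
anc_config <- function(filter = filter_config(), window_s = 6,
                       overlap_s = 2, postprocess = FALSE,
                       pp_rr_ratio_bounds = c(0.5, 2.0),
                       pp_power_ratio_max = 4.0) {
  stopifnot(inherits(filter, "filter_config"))
  if (!(window_s > overlap_s && overlap_s >= 0))
    .fail("need window_s > overlap_s >= 0")
  structure(list(filter = filter, window_s = window_s,
                 overlap_s = overlap_s, postprocess = isTRUE(postprocess),
                 pp_rr_ratio_bounds = pp_rr_ratio_bounds,
                 pp_power_ratio_max = pp_power_ratio_max),
            class = "anc_config")
}

#' Sliding processing windows
#'
#' Half-open, 0-based sample ranges of length `window_s * fs` advancing by
#' `(window_s - overlap_s) * fs`; a final partial window is included so the
#' whole record is covered.
#'
#' @param n_samples total samples.
#' @param fs sampling rate in Hz.
#' @param window_s,overlap_s window length and overlap in seconds.
#' @return list of `c(start, end)` integer pairs (half-open, 0-based).
#' @export
iter_windows <- function(n_samples, fs, window_s = 6, overlap_s = 2) {
  win <- as.integer(round(window_s * fs))
  hop <- as.integer(round((window_s - overlap_s) * fs))
  if (hop <= 0L) .fail("need window_s > overlap_s")
  out <- list()
  start <- 0L
  repeat {
    end <- min(start + win, n_samples)
    out[[length(out) + 1L]] <- c(start, end)
    if (end >= n_samples) break
    start <- start + hop
  }
  out
}

.ALGO_CODE <- c(apa = 1L, apsa = 2L, rvss = 3L, proposed = 4L)
.BRANCH_LAB <- c("APA", "APSA", "SKIPPED")

.run_anc_r <- function(d, rl, rr, cfg) {
  fc <- cfg$filter
  state <- init_state(fc)
  n <- length(d)
  m <- 2L * fc$L
  U <- matrix(0, m, fc$P)
  dv <- numeric(fc$P)
  filtered <- numeric(n)
  branch <- integer(n); q <- numeric(n); step_norm <- numeric(n)
  delta <- numeric(n); evec <- numeric(n)
  for (i in seq_len(n)) {
    if (fc$P > 1L) {
      U[, 2:fc$P] <- U[, 1:(fc$P - 1L)]
      dv[2:fc$P] <- dv[1:(fc$P - 1L)]
    }
    U[, 1L] <- reference_vector(rl, rr, i, fc$L)
    dv[1L] <- d[i]
    e1 <- dv[1L] - sum(U[, 1L] * state$w)
    filtered[i] <- e1
    res <- switch(fc$algorithm,
      apa = apa_step(state, U, dv, fc$mu, fc$eps_reg),
      apsa = {
        e <- dv - drop(crossprod(U, state$w))
        apsa_step(state, U, e, fc$mu)
      },
      rvss = rvss_step(state, U, dv, fc),
      proposed = proposed_step(state, U, dv, fc))
    state <- res$state
    tr <- res$trace
    branch[i] <- match(tr$branch, .BRANCH_LAB)
    q[i] <- tr$apa_update_norm
    step_norm[i] <- tr$step_norm
    delta[i] <- state$delta
    evec[i] <- tr$e
  }
  list(filtered = filtered, branch = branch, q = q, step_norm = step_norm,
       delta = delta, e = evec, w_final = state$w)
}

#' Run active noise cancellation over a record
#'
#' Streams the measured ECG `d(i)` sample by sample: builds the stacked
#' reference vector, computes the filter output `y(i)` and the error
#' `e(i) = d(i) - y(i)` (the denoised ECG), then performs one weight update
#' according to the configured algorithm.  The filter state persists
#' continuously across the whole record; the 6-s/2-s windows are used only
#' for the optional postprocessing fallback, which replaces a window by its
#' raw input when the filtered version fails the RR-ratio or power-ratio
#' sanity rules.
#'
#' @param ecg_m measured ECG (desired signal), numeric.
#' @param r_left,r_right reference signals, same length as `ecg_m`.
#' @param cfg an [anc_config()].
#' @param fs sampling rate in Hz (needed only when postprocessing is on).
#' @param engine `"cpp"` (default, compiled loop) or `"r"` (reference
#'   implementation built from the exported step functions).
#' @return object of class `"anc_result"`: `filtered`, `traces`
#'   (data.frame with iteration, branch, q = APA update norm, step_norm,
#'   delta, e), `w_final`, `windows_reverted` (0-based window indices where
#'   postprocessing substituted the raw signal), `config`.
#' @export
run_anc <- function(ecg_m, r_left, r_right, cfg = anc_config(), fs = NULL,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "anc_config"))
  n <- length(ecg_m)
  if (length(r_left) != n || length(r_right) != n)
    .fail("ecg_m, r_left, r_right must have equal length")
  fc <- cfg$filter
  if (engine == "cpp") {
    if (fc$eps_reg <= 0)
      .fail("the streaming loop needs eps_reg > 0 (U'U is singular at start-up)")
    raw <- .cpp_anc_stream(as.numeric(ecg_m), as.numeric(r_left),
                           as.numeric(r_right), fc$L, fc$P,
                           .ALGO_CODE[[fc$algorithm]], fc$mu, fc$mu1,
                           fc$gamma, fc$beta, fc$alpha, fc$delta0,
                           fc$eps_reg)
  } else {
    raw <- .run_anc_r(as.numeric(ecg_m), as.numeric(r_left),
                      as.numeric(r_right), cfg)
  }
  traces <- data.frame(iteration = seq_len(n),
                       branch = .BRANCH_LAB[raw$branch],
                       q = raw$q, step_norm = raw$step_norm,
                       delta = raw$delta, e = raw$e)
  filtered <- raw$filtered
  reverted <- integer(0)
  if (cfg$postprocess) {
    if (is.null(fs)) .fail("postprocessing needs 'fs'")
    wins <- iter_windows(n, fs, cfg$window_s, cfg$overlap_s)
    for (wi in seq_along(wins)) {
      rng <- (wins[[wi]][1] + 1L):wins[[wi]][2]
      fw <- filtered[rng]
      rw <- ecg_m[rng]
      pk <- if (length(fw) >= 2 * fs) pan_tompkins(fw, fs)
            else peak_set(integer(0), fs)
      pp <- postprocess_window(fw, rw, pk, cfg)
      if (pp$reverted) {
        filtered[rng] <- rw
        reverted <- c(reverted, wi - 1L)
      }
    }
  }
  structure(list(filtered = filtered, traces = traces,
                 w_final = raw$w_final, windows_reverted = reverted,
                 config = cfg),
            class = "anc_result")
}

#' @export
print.anc_result <- function(x, ...) {
  tb <- table(x$traces$branch)
  cat(sprintf("<anc_result> %d samples, algorithm '%s'\n",
              length(x$filtered), x$config$filter$algorithm))
  cat("  branches:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (length(x$windows_reverted))
    cat("  windows reverted by postprocessing:",
        paste(x$windows_reverted, collapse = ", "), "\n")
  invisible(x)
}

#' Per-window postprocessing fallback
#'
#' Rule 1: within every run of three consecutively detected R peaks, the
#' ratio of the two RR intervals must stay inside `pp_rr_ratio_bounds`.
#' Rule 2: the filtered/raw power ratio must not exceed
#' `pp_power_ratio_max`, and the filtered window must not be silent while
#' the raw one is not.  If either rule fails the raw window is returned.
#'
#' @param filtered_window,raw_window equal-length numeric windows.
#' @param detected_peaks a [peak_set()] with indices local to the window.
#' @param cfg an [anc_config()].
#' @return list with the output `window` and logical `reverted`.
#' @export
postprocess_window <- function(filtered_window, raw_window, detected_peaks,
                               cfg = anc_config()) {
  if (length(filtered_window) != length(raw_window))
    .fail("windows must have equal length")
  abnormal <- FALSE
  idx <- detected_peaks$indices
  if (length(idx) >= 3L) {
    rrs <- diff(idx)
    ratio <- rrs[-1] / rrs[-length(rrs)]
    lo <- cfg$pp_rr_ratio_bounds[1]; hi <- cfg$pp_rr_ratio_bounds[2]
    if (any(ratio < lo | ratio > hi)) abnormal <- TRUE
  }
  pf <- mean(filtered_window^2)
  pr <- mean(raw_window^2)
  if (pr > 0 && (pf / pr > cfg$pp_power_ratio_max || pf == 0))
    abnormal <- TRUE
  list(window = if (abnormal) raw_window else filtered_window,
       reverted = abnormal)
}

#' QRS power-conservation ratio
#'
#' Power of a filtered signal inside the 100-ms windows centred on the true
#' R peaks, divided by the power of a reference signal (normally the
#' band-passed clean ECG) in the same windows.  A value near 1 means the
#' QRS complexes survived filtering; aggressive filtering that erodes the
#' QRS drives it towards 0.
#'
#' @param filtered filtered signal.
#' @param reference clean (band-passed) signal of the same length.
#' @param true_peaks a [peak_set()] of ground-truth R peaks.
#' @param fs sampling rate in Hz.
#' @param qrs_window_s window width in seconds (default 0.100).
#' @return scalar ratio.
#' @export
qrs_conservation <- function(filtered, reference, true_peaks, fs,
                             qrs_window_s = 0.1) {
  mask <- .qrs_mask(length(filtered), true_peaks$indices, fs, qrs_window_s)
  denom <- mean(reference[mask]^2)
  if (denom == 0) return(NA_real_)
  mean(filtered[mask]^2) / denom
}
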