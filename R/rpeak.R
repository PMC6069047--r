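#' Ordered R-peak set
#'
#' @param indices strictly increasing 1-based sample indices.
#' @param fs sampling rate in Hz.
#' @return object of class `"peak_set"`.
#' @export
peak_set <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    .fail("peak indices must be strictly increasing")
  .check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  structure(list(indices = indices, fs = fs), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$indices)

#' QRS detector configuration
#'
#' Stage parameters of the classic real-time QRS detection chain.  The
#' defaults are the conventional published values: 5--15 Hz QRS-emphasis
#' band, 150-ms moving-window integration, 200-ms refractory period,
#' 0.125/0.875 threshold update, search-back at 1.66 times the running
#' average RR interval.
#'
#' @param band QRS emphasis band `c(low, high)` in Hz.
#' @param mwi_width_s moving-window integration width in seconds.
#' @param refractory_s minimum separation between detected peaks.
#' @param search_back enable missed-beat search-back.
#' @return object of class `"detector_config"`.
#' @export
detector_config <- function(band = c(5, 15), mwi_width_s = 0.150,
                            refractory_s = 0.200, search_back = TRUE) {
  if (!(band[1] > 0 && band[2] > band[1]))
    .fail("invalid detector band")
  .check_scalar_num(mwi_width_s, "mwi_width_s", 0, strict_lower = TRUE)
  .check_scalar_num(refractory_s, "refractory_s", 0, strict_lower = TRUE)
  structure(list(band = band, mwi_width_s = mwi_width_s,
                 refractory_s = refractory_s,
                 search_back = isTRUE(search_back)),
            class = "detector_config")
}

# centred moving average (no group delay)
.mwi <- function(x, width) {
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Pan-Tompkins QRS detection
#'
#' Classic stage chain: zero-phase band-pass in the QRS emphasis band,
#' five-point derivative, squaring, centred moving-window integration, then
#' adaptive signal/noise thresholds with a refractory period and optional
#' search-back for missed beats.  Detected locations are refined to the
#' local maximum of the band-passed signal within 50 ms of each
#' integration peak.  All thresholds are data-adaptive, so the detector is
#' invariant to positive rescaling of the input.
#'
#' @param signal numeric ECG, at least 2 s long.
#' @param fs sampling rate in Hz.
#' @param cfg a [detector_config()].
#' @return a [peak_set()].
#' @export
pan_tompkins <- function(signal, fs, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  n <- length(signal)
  if (n < 2 * fs) .fail("signal shorter than 2 s; cannot initialise detector")
  if (cfg$band[2] >= fs / 2) .fail("detector band exceeds Nyquist")

  bp <- bandpass(signal, fs, cfg$band[1], cfg$band[2], order = 2L,
                 zero_phase = TRUE)
  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  dv <- numeric(n)
  dv[5:n] <- (2 * bp[5:n] + bp[4:(n - 1)] - bp[2:(n - 3)] -
                2 * bp[1:(n - 4)]) / 8
  sq <- dv^2
  width <- max(1L, as.integer(round(cfg$mwi_width_s * fs)))
  mwi <- .mwi(sq, width)

  # candidate peaks: strict local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) return(peak_set(integer(0), fs))

  init <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  refr <- as.integer(round(cfg$refractory_s * fs))
  qrs <- integer(0)
  rr_hist <- numeric(0)
  noise_cand <- integer(0)    # rejected candidates since last QRS

  thr1 <- function() npki + 0.25 * (spki - npki)
  for (p in cand) {
    v <- mwi[p]
    if (length(qrs) && p - qrs[length(qrs)] < refr) next
    if (v > thr1()) {
      if (length(qrs)) rr_hist <- c(rr_hist, p - qrs[length(qrs)])
      if (length(rr_hist) > 8) rr_hist <- tail(rr_hist, 8)
      qrs <- c(qrs, p)
      spki <- 0.125 * v + 0.875 * spki
      noise_cand <- integer(0)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      noise_cand <- c(noise_cand, p)
      # search-back for a missed beat
      if (cfg$search_back && length(qrs) && length(rr_hist) >= 2) {
        if (p - qrs[length(qrs)] > 1.66 * mean(rr_hist)) {
          sb <- noise_cand[mwi[noise_cand] > 0.5 * thr1()]
          if (length(sb)) {
            best <- sb[which.max(mwi[sb])]
            if (best - qrs[length(qrs)] >= refr) {
              rr_hist <- c(rr_hist, best - qrs[length(qrs)])
              if (length(rr_hist) > 8) rr_hist <- tail(rr_hist, 8)
              qrs <- sort(c(qrs, best))
              spki <- 0.25 * mwi[best] + 0.75 * spki
              noise_cand <- integer(0)
            }
          }
        }
      }
    }
  }
  if (!length(qrs)) return(peak_set(integer(0), fs))

  # refine to the band-passed signal maximum within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  ref <- vapply(qrs, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, 1L)
  ref <- sort(unique(ref))
  # enforce the refractory property on the refined indices
  keep <- ref[1]
  for (p in ref[-1]) if (p - keep[length(keep)] >= refr) keep <- c(keep, p)
  peak_set(keep, fs)
}

#' Merge two peak sets
#'
#' Union of the indices with any two peaks closer than `tol_s` collapsed to
#' the earlier one; used to deduplicate detections from overlapping
#' processing windows.
#'
#' @param a,b [peak_set()] objects with the same sampling rate.
#' @param tol_s merge tolerance in seconds (default 0.080).
#' @return a [peak_set()].
#' @export
merge_peaks <- function(a, b, tol_s = 0.080) {
  if (a$fs != b$fs) .fail("peak sets have different sampling rates")
  tol <- round(tol_s * a$fs)
  all <- sort(unique(c(a$indices, b$indices)))
  if (!length(all)) return(peak_set(integer(0), a$fs))
  keep <- all[1]
  for (p in all[-1]) if (p - keep[length(keep)] >= tol) keep <- c(keep, p)
  peak_set(keep, a$fs)
}
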