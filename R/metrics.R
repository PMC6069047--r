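#' Match detected R peaks to true R peaks
#'
#' A search window of `window_s` (default 80 ms) is centred on each true
#' R peak; a detected peak falling inside a window is a true positive.
#' Matching is greedy, one-to-one, in time order: each detected peak can
#' match at most one true peak and vice versa (equivalent to the optimal
#' assignment for fixed-width windows; cross-checked against an exhaustive
#' matcher in the test suite).  Unmatched true peaks are false negatives,
#' unmatched detections false positives.
#'
#' @param true_peaks,detected [peak_set()] objects at the same rate.
#' @param window_s full search-window width in seconds.
#' @return object of class `"match_result"` with `tp`, `fn`, `fp` and
#'   `matched_pairs` (two-column matrix of true/detected indices).
#' @export
match_peaks <- function(true_peaks, detected, window_s = 0.080) {
  if (true_peaks$fs != detected$fs)
    .fail("peak sets have different sampling rates")
  half <- round(window_s / 2 * true_peaks$fs)
  tr <- true_peaks$indices; dt <- detected$indices
  i <- 1L; j <- 1L
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("true_index", "detected_index")))
  while (i <= length(tr) && j <= length(dt)) {
    if (abs(dt[j] - tr[i]) <= half) {
      pairs <- rbind(pairs, c(tr[i], dt[j]))
      i <- i + 1L; j <- j + 1L
    } else if (dt[j] < tr[i] - half) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fn = length(tr) - tp, fp = length(dt) - tp,
                 matched_pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FN=%d FP=%d\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' Sensitivity, positive predictivity and their average
#'
#' `Se = TP / (TP + FN) * 100`; `P+ = TP / (TP + FP) * 100`;
#' `Avg = (Se + P+) / 2`.  A zero denominator yields `NA` with attribute
#' `undefined = TRUE` rather than a silent zero.
#'
#' @param m a [match_peaks()] result.
#' @return percentage (0--100) or flagged `NA`.
#' @export
sensitivity <- function(m) {
  if (m$tp + m$fn == 0)
    return(structure(NA_real_, undefined = TRUE))
  100 * m$tp / (m$tp + m$fn)
}

#' @rdname sensitivity
#' @export
positive_predictivity <- function(m) {
  if (m$tp + m$fp == 0)
    return(structure(NA_real_, undefined = TRUE))
  100 * m$tp / (m$tp + m$fp)
}

#' @rdname sensitivity
#' @param se,p_plus percentages.
#' @export
avg_score <- function(se, p_plus) (se + p_plus) / 2

.qrs_mask <- function(n, peaks, fs, qrs_window_s = 0.1) {
  half <- as.integer(round(qrs_window_s / 2 * fs))
  mask <- logical(n)
  for (p in peaks) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}

#' Estimated signal-to-noise ratio
#'
#' Ratio of the mean squared amplitude inside the 100-ms windows centred
#' on the given R peaks (taken as signal power, since the QRS complex
#' dominates there) to the mean squared amplitude everywhere else (taken
#' as noise power).  Falls when filtering erodes QRS power or leaves
#' baseline noise behind.
#'
#' @param signal numeric signal.
#' @param r_peaks a [peak_set()]; true peaks when ground truth exists,
#'   detected peaks otherwise.
#' @param fs sampling rate in Hz.
#' @param qrs_window_s window width in seconds (default 0.100).
#' @return scalar ratio; `Inf` with attribute `undefined = TRUE` when the
#'   out-of-window power is zero.
#' @export
snr_hat <- function(signal, r_peaks, fs, qrs_window_s = 0.1) {
  if (!length(r_peaks$indices)) .fail("need at least one R peak")
  mask <- .qrs_mask(length(signal), r_peaks$indices, fs, qrs_window_s)
  ps <- mean(signal[mask]^2)
  pn <- mean(signal[!mask]^2)
  if (!is.finite(pn) || pn == 0)
    return(structure(Inf, undefined = TRUE))
  ps / pn
}

#' Performance increase ratio
#'
#' Ratio of the Avg improvement (over the raw measured ECG) achieved by
#' the proposed switched algorithm to that achieved by plain-APA noise
#' cancellation.
#'
#' @param davg_proposed,davg_apa Avg improvements in percentage points.
#' @return scalar ratio; `NA` with attribute `undefined = TRUE` when
#'   `davg_apa` is zero.
#' @export
pir <- function(davg_proposed, davg_apa) {
  if (davg_apa == 0) return(structure(NA_real_, undefined = TRUE))
  davg_proposed / davg_apa
}

#' Full evaluation report for one signal
#'
#' Convenience wrapper: matches detected against true peaks, computes Se,
#' P+, Avg and the estimated SNR of `signal` (using `snr_peaks`, defaulting
#' to the true peaks).
#'
#' @param true_peaks,detected [peak_set()] objects.
#' @param signal signal used for [snr_hat()]; optional.
#' @param fs sampling rate in Hz.
#' @param snr_peaks peaks for the SNR windows (default `true_peaks`).
#' @return object of class `"metrics_report"` with fields `tp`, `fn`,
#'   `fp`, `se`, `p_plus`, `avg`, `snr_hat`.
#' @export
metrics_report <- function(true_peaks, detected, signal = NULL, fs = NULL,
                           snr_peaks = true_peaks) {
  m <- match_peaks(true_peaks, detected)
  se <- sensitivity(m)
  pp <- positive_predictivity(m)
  sn <- if (!is.null(signal)) {
    if (is.null(fs)) fs <- true_peaks$fs
    snr_hat(signal, snr_peaks, fs)
  } else NA_real_
  structure(list(tp = m$tp, fn = m$fn, fp = m$fp,
                 se = as.numeric(se), p_plus = as.numeric(pp),
                 avg = avg_score(as.numeric(se), as.numeric(pp)),
                 snr_hat = as.numeric(sn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> TP=%d FN=%d FP=%d | Se=%.2f%% P+=%.2f%% Avg=%.2f%% | SNR^=%.2f\n",
    x$tp, x$fn, x$fp, x$se, x$p_plus, x$avg, x$snr_hat))
  invisible(x)
}
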