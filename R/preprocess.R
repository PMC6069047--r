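#' Butterworth biquad sections
#'
#' Designs an even-order digital Butterworth low- or high-pass filter as a
#' cascade of second-order sections (bilinear transform with frequency
#' prewarping).  Internal building block for [bandpass()].
#'
#' @param order filter order; even, currently 2 or 4.
#' @param fc cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return list of sections, each a list with numerator `b` and denominator
#'   `a` (length-3 vectors, `a[1] == 1`).
#' @keywords internal
butter_sections <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (!order %in% c(2L, 4L)) .fail("'order' must be 2 or 4, got %s", order)
  if (fc <= 0 || fc >= fs / 2) .fail("cutoff %g Hz outside (0, fs/2)", fc)
  w0 <- 2 * pi * fc / fs
  lapply(seq_len(order / 2), function(k) {
    theta <- (2 * k - 1) * pi / (2 * order)   # Butterworth pole angle
    Q <- 1 / (2 * sin(theta))
    alpha <- sin(w0) / (2 * Q)
    cw <- cos(w0)
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    b <- if (type == "low") c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
         else               c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    list(b = b / a[1], a = a / a[1])
  })
}

.apply_sections <- function(x, sections) {
  for (s in sections) x <- .cpp_iir(s$b, s$a, x)
  x
}

# forward-backward pass with odd reflection padding (zero phase)
.filtfilt_sections <- function(x, sections, fs) {
  n <- length(x)
  npad <- min(n - 1L, as.integer(round(2 * fs)))
  if (npad > 0) {
    pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- .apply_sections(xe, sections)
  y <- rev(.apply_sections(rev(y), sections))
  y[seq(npad + 1L, npad + n)]
}

#' Band-pass filter a signal
#'
#' Cascade of Butterworth high-pass (at `low`) and low-pass (at `high`)
#' sections.  The default 0.05--35 Hz band is the conventional acquisition
#' band for capacitive ECG.  The default realisation is causal (applied
#' forward only), matching near-real-time processing; set
#' `zero_phase = TRUE` for an offline forward-backward pass with no group
#' delay.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order per band edge (2 or 4; default 4, which
#'   attenuates 60 Hz interference below 5% at `fs = 200`).
#' @param zero_phase apply forward-backward instead of causal.
#' @return filtered signal, same length as `x`.
#' @export
#' @examples
#' fs <- 200
#' t <- seq(0, 5, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
#' y <- bandpass(x, fs)          # keeps 10 Hz, rejects 60 Hz
bandpass <- function(x, fs, low = 0.05, high = 35, order = 4L,
                     zero_phase = FALSE) {
  .check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  if (!(low > 0 && high > low && high < fs / 2))
    .fail("invalid band (%g, %g) Hz at fs = %g: need 0 < low < high < fs/2",
          low, high, fs)
  x <- as.numeric(x)
  if (length(x) == 0L) return(x)
  secs <- c(butter_sections(order, low, fs, "high"),
            butter_sections(order, high, fs, "low"))
  if (zero_phase) .filtfilt_sections(x, secs, fs) else .apply_sections(x, secs)
}

# internal low-pass (used by the burst-noise generator)
.lowpass <- function(x, fs, fc, order = 2L) {
  .apply_sections(as.numeric(x), butter_sections(order, fc, fs, "low"))
}

#' Construct a multichannel capacitive-ECG record
#'
#' Container for the four sensor channels (`sigL`, `sigR` from the outer
#' sensor pair, `sigaL`, `sigaR` from the inner pair) sampled at `fs`, with
#' an optional simultaneously recorded contact ECG.
#'
#' @param fs sampling rate in Hz.
#' @param sigL,sigR,sigaL,sigaR equal-length numeric channels.
#' @param ecg_contact optional contact-electrode ECG (ground truth source).
#' @param meta free-form provenance list.
#' @return object of class `"cecg_record"`.
#' @export
cecg_record <- function(fs, sigL, sigR, sigaL, sigaR, ecg_contact = NULL,
                        meta = list()) {
  .check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  chans <- list(sigL = sigL, sigR = sigR, sigaL = sigaL, sigaR = sigaR)
  n <- unique(vapply(chans, length, 1L))
  if (length(n) != 1L) .fail("all channels must have equal length")
  if (!is.null(ecg_contact) && length(ecg_contact) != n)
    .fail("'ecg_contact' length differs from sensor channels")
  structure(list(fs = fs, sigL = as.numeric(sigL), sigR = as.numeric(sigR),
                 sigaL = as.numeric(sigaL), sigaR = as.numeric(sigaR),
                 ecg_contact = if (is.null(ecg_contact)) NULL
                               else as.numeric(ecg_contact),
                 meta = meta),
            class = "cecg_record")
}

#' @export
print.cecg_record <- function(x, ...) {
  n <- length(x$sigL)
  cat(sprintf("<cecg_record> %d samples @ %g Hz (%.1f s)%s\n", n, x$fs,
              n / x$fs, if (is.null(x$ecg_contact)) "" else " + contact ECG"))
  invisible(x)
}

#' Measured ECG from the outer sensor pair
#'
#' The measured ECG is the band-passed (0.05--35 Hz) difference of the two
#' outer-sensor channels: differencing removes common-mode interference
#' while the opposite-polarity cardiac projections add.
#'
#' @param record a [cecg_record()].
#' @param zero_phase passed to [bandpass()].
#' @return numeric signal, same length as the record channels.
#' @export
build_measured_ecg <- function(record, zero_phase = FALSE) {
  stopifnot(inherits(record, "cecg_record"))
  if (is.null(record$sigL) || is.null(record$sigR))
    .fail("record is missing sigL/sigR")
  bandpass(record$sigL - record$sigR, record$fs, zero_phase = zero_phase)
}

#' Reference signals from adjacent sensor pairs
#'
#' The differences between adjacent outer and inner sensors retain the
#' motion-artifact component but (nearly) cancel the cardiac signal, making
#' them suitable noise references for active noise cancellation.  The
#' references are used raw by default; `band` optionally band-passes them.
#'
#' @param record a [cecg_record()].
#' @param band optional `c(low, high)` in Hz to band-pass the references;
#'   `NULL` (default) leaves them unfiltered.
#' @return list with numeric `r_left` and `r_right`.
#' @export
build_references <- function(record, band = NULL) {
  stopifnot(inherits(record, "cecg_record"))
  if (is.null(record$sigaL) || is.null(record$sigaR))
    .fail("record is missing sigaL/sigaR")
  rl <- record$sigL - record$sigaL
  rr <- record$sigR - record$sigaR
  if (!is.null(band)) {
    rl <- bandpass(rl, record$fs, band[1], band[2])
    rr <- bandpass(rr, record$fs, band[1], band[2])
  }
  list(r_left = rl, r_right = rr)
}

#' Stacked reference vector at one sample
#'
#' Builds the length-`2L` adaptive-filter input: the last `L` samples of the
#' left reference followed by the last `L` samples of the right reference,
#' most recent first.  Indices before the start of the record read as zero,
#' so output stays aligned with input from the first sample.
#'
#' @param r_left,r_right reference signals.
#' @param i current sample (1-based).
#' @param L taps per reference channel (half the filter length).
#' @return numeric vector of length `2 * L`.
#' @export
reference_vector <- function(r_left, r_right, i, L) {
  if (i < 1L || L < 1L) .fail("need i >= 1 and L >= 1")
  idx <- i - seq_len(L) + 1L
  take <- function(r) ifelse(idx >= 1L, r[pmax(idx, 1L)], 0)
  c(take(r_left), take(r_right))
}
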