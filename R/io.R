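#' Write / read a record as CSV
#'
#' The CSV carries columns `time_s, sigL, sigR, sigaL, sigaR` and, when
#' available, `clean_ecg` (the contact/ground-truth ECG).  Ground-truth R
#' peaks, if given, go to a sidecar text file (`<path>.rpeaks.txt`, one
#' 1-based sample index per line).
#'
#' @param record a [cecg_record()].
#' @param path output CSV path.
#' @param r_peaks optional [peak_set()] or integer vector of true R peaks.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, r_peaks = NULL) {
  stopifnot(inherits(record, "cecg_record"))
  n <- length(record$sigL)
  cols <- list(time_s = (seq_len(n) - 1) / record$fs,
               sigL = record$sigL, sigR = record$sigR,
               sigaL = record$sigaL, sigaR = record$sigaR)
  if (!is.null(record$ecg_contact)) cols$clean_ecg <- record$ecg_contact
  dt <- data.table::as.data.table(cols)
  data.table::fwrite(dt, path)
  if (!is.null(r_peaks)) {
    idx <- if (inherits(r_peaks, "peak_set")) r_peaks$indices else r_peaks
    writeLines(as.character(idx), paste0(path, ".rpeaks.txt"))
  }
  invisible(path)
}

#' @rdname write_record_csv
#' @param fs sampling rate override; by default inferred from `time_s`.
#' @return for `read_record_csv`: a list with `record` and (if the sidecar
#'   exists) `true_r_peaks`.
#' @export
read_record_csv <- function(path, fs = NULL) {
  dt <- data.table::fread(path)
  need <- c("sigL", "sigR", "sigaL", "sigaR")
  if (!all(need %in% names(dt)))
    .fail("CSV must contain columns %s", paste(need, collapse = ", "))
  if (is.null(fs)) {
    if (!"time_s" %in% names(dt) || nrow(dt) < 2)
      .fail("cannot infer fs: no time_s column")
    fs <- 1 / stats::median(diff(dt$time_s))
  }
  rec <- cecg_record(fs, dt$sigL, dt$sigR, dt$sigaL, dt$sigaR,
                     ecg_contact = if ("clean_ecg" %in% names(dt))
                       dt$clean_ecg else NULL,
                     meta = list(source = path))
  side <- paste0(path, ".rpeaks.txt")
  out <- list(record = rec)
  if (file.exists(side))
    out$true_r_peaks <- as.integer(readLines(side))
  out
}

#' Read / write peak index files
#'
#' One 1-based sample index per line.
#'
#' @param peaks a [peak_set()].
#' @param path file path.
#' @export
write_peaks <- function(peaks, path) {
  writeLines(as.character(peaks$indices), path)
  invisible(path)
}

#' @rdname write_peaks
#' @param fs sampling rate in Hz.
#' @export
read_peaks <- function(path, fs) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  peak_set(as.integer(lines), fs)
}
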