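# Lightweight tabular containers: a uniformly sampled scalar trace is a
# tibble with columns `time` and `value` plus an `fs` attribute; missing
# samples are NA in `value`. EEG recordings keep their channels x samples
# matrix with montage metadata.

#' Construct a uniformly sampled scalar trace
#'
#' @param values Numeric vector; `NA` marks missing samples.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble with columns `time`, `value` and attribute `fs`,
#'   class `narousal_ts`.
#' @export
new_ts <- function(values, fs, t0 = 0) {
  stopifnot(is.numeric(fs), fs > 0)
  out <- tibble::tibble(
    time = t0 + (seq_along(values) - 1) / fs,
    value = as.numeric(values)
  )
  attr(out, "fs") <- fs
  class(out) <- c("narousal_ts", class(out))
  out
}

#' Sampling rate of a trace
#' @param x A `narousal_ts` or a data frame with a `time` column.
#' @return Sampling rate in Hz.
#' @export
ts_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  dt <- stats::median(diff(x$time))
  1 / dt
}

ts_values <- function(x) {
  if (is.data.frame(x)) x$value else as.numeric(x)
}

#' Construct an EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolt scale).
#' @param fs Sampling rate in Hz; must exceed twice the highest analyzed
#'   frequency (>= 80 Hz for analyses up to 40 Hz).
#' @param montage A montage tibble from [montage_1020()].
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, montage) {
  stopifnot(is.matrix(data), nrow(data) == nrow(montage))
  if (anyNA(data)) stop("eeg_recording(): data contains missing samples", call. = FALSE)
  if (fs < 80) stop("eeg_recording(): fs must be at least 80 Hz", call. = FALSE)
  rownames(data) <- montage$label
  structure(
    list(data = data, fs = fs, montage = montage),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Convert an EEG recording to a long tibble
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time`, `value`.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$montage$label, each = ncol(x$data)),
    time = rep((seq_len(ncol(x$data)) - 1) / x$fs, nrow(x$data)),
    value = as.vector(t(x$data))
  )
}
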