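# Time-resolved band power: 1 s non-overlapping epochs, detrended
# Hann-tapered periodograms, band means, then the log -> 40 s Gaussian
# smooth -> z-score transformation chain, and the dot-product correlation
# with an arousal trajectory (identical to Pearson r on z-scored inputs).

#' Band definitions
#'
#' Standard presets for the time-resolved analysis (`delta` 1-4 Hz) and
#' the envelope-ISC / contrast context (`delta` 2-4 Hz); theta is 4-7 Hz
#' in both and the alpha band is the subject's low-IAF band
#' `[IAF - 1, IAF]`. The low-IAF band is averaged with fractional-overlap
#' weights at the 1 Hz epoch resolution; integer-edged bands use the
#' half-open convention `lo <= f < hi` except the top band, which includes
#' `hi`.
#'
#' @param iaf Individual alpha frequency in Hz.
#' @param preset `"power"` (delta 1-4) or `"isc"` (delta 2-4).
#' @return Tibble with columns `name`, `lo`, `hi`, `fractional`.
#' @export
band_definitions <- function(iaf = 10, preset = c("power", "isc")) {
  preset <- match.arg(preset)
  delta_lo <- if (preset == "power") 1 else 2
  tibble::tibble(
    name = c("delta", "theta", "low_iaf"),
    lo = c(delta_lo, 4, iaf - 1),
    hi = c(4, 7, iaf),
    fractional = c(FALSE, FALSE, TRUE)
  )
}

# Weights of frequency bins for one band. Integer-edged bands take bins
# with lo <= f < hi (plus f == hi for the top band); fractional bands
# weight each bin by the overlap of its [f - res/2, f + res/2) interval
# with [lo, hi].
band_bin_weights <- function(freqs, lo, hi, fractional, is_top, res) {
  if (!fractional) {
    w <- as.numeric(freqs >= lo & freqs < hi)
    if (is_top) w[freqs == hi] <- 1
  } else {
    w <- pmax(0, pmin(freqs + res / 2, hi) - pmax(freqs - res / 2, lo)) / res
  }
  w
}

#' Time-resolved band power per channel
#'
#' Segments the recording into consecutive non-overlapping `epoch_s`-long
#' epochs; each epoch is linearly detrended, Hann-tapered, and its
#' periodogram averaged over the band's frequency bins; band means are
#' then log10-transformed ("raw_log" stage). A trailing partial epoch is
#' dropped with a warning. Epochs with numerically zero power (e.g. a
#' constant input after detrending) are floored with a warning.
#'
#' @param eeg An `eeg_recording`.
#' @param bands A band tibble from [band_definitions()].
#' @param epoch_s Epoch length in seconds (default 1).
#' @return A `band_power_series`: list with `values` (a named list, one
#'   channels x epochs matrix per band), `n_epochs`, `bands`,
#'   `stage = "raw_log"`.
#' @export
epoch_band_power <- function(eeg, bands = band_definitions(), epoch_s = 1) {
  fs <- eeg$fs
  nwin <- round(epoch_s * fs)
  n <- ncol(eeg$data)
  n_epochs <- floor(n / nwin)
  if (n_epochs * nwin != n) {
    warning("epoch_band_power(): dropping a partial final epoch")
  }
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nwin - 1) / (nwin - 1)))
  freqs <- (seq_len(floor(nwin / 2) + 1) - 1) * fs / nwin
  res <- fs / nwin
  tgrid <- seq_len(nwin)
  detrend_mat <- {
    X <- cbind(1, tgrid)
    diag(nwin) - X %*% solve(crossprod(X), t(X))
  }
  top <- which.max(bands$hi)
  Wmat <- vapply(seq_len(nrow(bands)), function(b) {
    band_bin_weights(freqs, bands$lo[b], bands$hi[b], bands$fractional[b],
                     b == top, res)
  }, numeric(length(freqs)))
  if (any(colSums(Wmat) == 0)) {
    stop("epoch_band_power(): a band contains no frequency bins", call. = FALSE)
  }
  half <- length(freqs)
  floored <- FALSE
  out <- purrr::map(seq_len(nrow(bands)), function(b) {
    matrix(0, nrow(eeg$data), n_epochs, dimnames = list(eeg$montage$label, NULL))
  })
  names(out) <- bands$name
  for (ch in seq_len(nrow(eeg$data))) {
    segs <- matrix(eeg$data[ch, seq_len(n_epochs * nwin)], nwin, n_epochs)
    segs <- (detrend_mat %*% segs) * w
    P <- Mod(stats::mvfft(segs))^2 / (fs * sum(w^2))
    P <- P[seq_len(half), , drop = FALSE]
    P[2:(half - 1), ] <- 2 * P[2:(half - 1), ]
    for (b in seq_len(nrow(bands))) {
      bp <- colSums(P * Wmat[, b]) / sum(Wmat[, b])
      if (any(bp < 1e-15)) {
        floored <- TRUE
        bp <- pmax(bp, 1e-15)
      }
      out[[b]][ch, ] <- log10(bp)
    }
  }
  if (floored) warning("epoch_band_power(): near-zero-power epochs floored at 1e-15")
  structure(list(values = out, n_epochs = n_epochs, bands = bands,
                 epoch_s = epoch_s, stage = "raw_log"),
            class = "band_power_series")
}

#' Smooth and z-score band-power series
#'
#' Applies the Gaussian smoothing kernel (window `smooth_window_s`
#' epochs, same convention as the pupil pipeline) along epochs, then
#' z-scores each channel across epochs, removing tonic per-channel
#' offsets and isolating phasic power changes.
#'
#' @param series A `band_power_series` at stage `"raw_log"`.
#' @param smooth_window_s Smoothing window in epochs/seconds (default 40).
#' @return The series at stage `"zscored"`.
#' @export
transform_power <- function(series, smooth_window_s = 40) {
  stopifnot(inherits(series, "band_power_series"))
  if (series$stage != "raw_log") {
    stop("transform_power(): expected stage 'raw_log'", call. = FALSE)
  }
  vals <- purrr::imap(series$values, function(m, band) {
    sm <- t(apply(m, 1, gaussian_smooth, window = smooth_window_s))
    sds <- apply(sm, 1, stats::sd)
    if (any(sds == 0)) {
      stop("transform_power(): zero-variance channel(s): ",
           paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    }
    z <- t(apply(sm, 1, zscore))
    rownames(z) <- rownames(m)
    z
  })
  structure(list(values = vals, n_epochs = series$n_epochs,
                 bands = series$bands, epoch_s = series$epoch_s,
                 stage = "zscored"),
            class = "band_power_series")
}

#' Long-tibble view of a band-power series
#' @param x A `band_power_series`.
#' @param ... Unused.
#' @return Tibble with columns `band`, `channel`, `epoch`, `value`.
#' @method tidy band_power_series
#' @export
tidy.band_power_series <- function(x, ...) {
  purrr::imap_dfr(x$values, function(m, band) {
    tibble::tibble(
      band = band,
      channel = rep(rownames(m), each = ncol(m)),
      epoch = rep(seq_len(ncol(m)), nrow(m)),
      value = as.vector(t(m))
    )
  })
}

#' Correlate band-power envelopes with an arousal trajectory
#'
#' The statistic is the dot product of the z-scored power envelope and the
#' z-scored arousal vector divided by `N - 1`, which equals the Pearson
#' correlation coefficient exactly. Series are trimmed to their common
#' length (offsets logged via a message when trimming occurs).
#'
#' @param series A `band_power_series` at stage `"zscored"`.
#' @param arousal A 1 Hz arousal trajectory (`narousal_ts` or numeric),
#'   z-scored internally.
#' @param modality Label recorded in the output (annotation/pupil).
#' @param max_trim Maximum tolerated length mismatch in epochs (default
#'   10; larger mismatches raise an alignment error).
#' @return A `correlation_map` tibble: columns `band`, `channel`,
#'   `modality`, `r`.
#' @export
correlate_with_arousal <- function(series, arousal, modality = "annotation",
                                   max_trim = 10) {
  stopifnot(inherits(series, "band_power_series"))
  if (series$stage != "zscored") {
    stop("correlate_with_arousal(): expected stage 'zscored'", call. = FALSE)
  }
  a <- ts_values(arousal)
  n_e <- series$n_epochs
  if (abs(length(a) - n_e) > max_trim) {
    stop(sprintf(
      "correlate_with_arousal(): arousal length %d vs %d epochs exceeds the %d-sample tolerance",
      length(a), n_e, max_trim), call. = FALSE)
  }
  n <- min(length(a), n_e)
  if (n < n_e || n < length(a)) {
    message(sprintf("correlate_with_arousal(): trimming to %d common epochs", n))
  }
  az <- zscore(a[seq_len(n)])
  out <- purrr::imap_dfr(series$values, function(m, band) {
    mz <- t(apply(m[, seq_len(n), drop = FALSE], 1, zscore))
    tibble::tibble(
      band = band,
      channel = rownames(m),
      modality = modality,
      r = as.vector(mz %*% az) / (n - 1)
    )
  })
  class(out) <- c("correlation_map", class(out))
  out
}
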