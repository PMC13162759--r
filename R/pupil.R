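# Pupil preprocessing chain: initial-sample exclusion, robust spike
# marking, moving-median interpolation, derivative-based de-blinking,
# median filtering, a >40% missingness exclusion gate, 1 Hz resampling,
# luminance regression and Gaussian smoothing.

#' Convert movie frames to a 1 Hz luminance series
#'
#' Each RGB frame is converted to grayscale (Rec. 601 luma weights
#' 0.299/0.587/0.114) and averaged over pixels; per-frame values are then
#' averaged within each second.
#'
#' @param frames List of frames; each either a `height x width x 3` RGB
#'   array or a `height x width` grayscale matrix, values in grey levels
#'   (0-255) or in `[0, 1]` (scaled up to grey levels).
#' @param frame_rate Frames per second.
#' @return A `narousal_ts` at 1 Hz with values in `[0, 255]`.
#' @export
frames_to_luminance <- function(frames, frame_rate) {
  if (length(frames) == 0) {
    stop("frames_to_luminance(): empty frame set", call. = FALSE)
  }
  per_frame <- purrr::map_dbl(frames, function(fr) {
    if (length(dim(fr)) == 3) {
      gray <- 0.299 * fr[, , 1] + 0.587 * fr[, , 2] + 0.114 * fr[, , 3]
    } else {
      gray <- fr
    }
    mean(gray)
  })
  if (max(per_frame) <= 1) per_frame <- per_frame * 255
  sec <- floor((seq_along(per_frame) - 1) / frame_rate)
  vals <- as.numeric(tapply(per_frame, sec, mean))
  new_ts(vals, fs = 1)
}

# Rolling median over a k-point window with reflected-edge padding;
# NAs inside the window are ignored.
moving_median <- function(x, k = 101) {
  half <- floor(k / 2)
  n <- length(x)
  pad <- c(rev(x[seq_len(min(half, n))]), x, rev(x[seq.int(max(1, n - half + 1), n)]))
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- pad[i:(i + 2 * half)]
    out[i] <- stats::median(win, na.rm = TRUE)
  }
  out
}

fill_moving_median <- function(x, k = 101) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  med <- moving_median(x, k)
  x[miss] <- med[miss]
  if (anyNA(x)) {   # windows that were entirely missing: nearest-value fill
    x <- stats::approx(which(!is.na(x)), x[!is.na(x)], xout = seq_along(x),
                       rule = 2)$y
  }
  x
}

# 100-point (odd-rounded) median filter with reflected-edge padding.
median_filter <- function(x, k = 101) {
  if (k %% 2 == 0) k <- k + 1
  half <- floor(k / 2)
  n <- length(x)
  pad <- c(rev(x[seq_len(half)]), x, rev(x[(n - half + 1):n]))
  as.numeric(stats::runmed(pad, k))[(half + 1):(half + n)]
}

exclusion_condition <- function(stage, fraction) {
  structure(
    class = c("narousal_exclusion", "error", "condition"),
    list(message = sprintf(
      "subject excluded: %.1f%% missing at stage '%s' (gate: > 40%%)",
      100 * fraction, stage),
      call = NULL, stage = stage, fraction = fraction)
  )
}

gate_missing <- function(miss, stage, gate = 0.4) {
  frac <- mean(miss)
  if (frac > gate) stop(exclusion_condition(stage, frac))
  frac
}

#' Clean a raw pupil trace
#'
#' Applies, in order: (1) exclusion of the first `drop_initial` samples
#' (luminance adaptation); (2) robust spike marking (deviation from a
#' `median_window`-point running median larger than `spike_mad` median
#' absolute deviations); (3) interpolation of missing samples with a
#' `median_window`-point moving median; (4) de-blinking, marking samples
#' whose first difference exceeds `deriv_sd` standard deviations of the
#' first-difference distribution (two-sided), then re-filling as in (3);
#' (5) a `median_window`-point median filter. After every stage the
#' missing fraction is checked against the 40% exclusion gate; exceeding
#' it raises a `narousal_exclusion` condition carrying the stage name.
#'
#' @param raw A `narousal_ts` (60 Hz pupil trace; `NA` marks device
#'   dropouts) or a numeric vector.
#' @param drop_initial Initial samples to discard (default 300).
#' @param median_window Moving-median / median-filter window in samples.
#' @param spike_mad Spike threshold in MADs from the running median.
#' @param deriv_sd De-blinking threshold in SDs of the first difference.
#' @param gate Missing-fraction exclusion gate (default 0.4).
#' @return A cleaned `narousal_ts` at the input rate, with attribute `qc`:
#'   a tibble of per-stage missing fractions.
#' @export
clean_pupil <- function(raw, drop_initial = 300, median_window = 100,
                        spike_mad = 5, deriv_sd = 3, gate = 0.4) {
  fs <- if (is.data.frame(raw)) ts_fs(raw) else 60
  x <- ts_values(raw)
  if (length(x) <= drop_initial) {
    stop("clean_pupil(): trace shorter than the initial exclusion window",
         call. = FALSE)
  }
  k <- median_window + 1L  # odd window spanning `median_window` points
  qc <- list()
  x <- x[-seq_len(drop_initial)]
  qc$missingness_gate <- gate_missing(is.na(x), "missingness_gate", gate)

  med <- moving_median(x, k)
  dev <- abs(x - med)
  madv <- stats::mad(x - med, na.rm = TRUE)
  spikes <- !is.na(x) & madv > 0 & dev > spike_mad * madv
  x[spikes] <- NA_real_
  qc$spike_removal <- gate_missing(is.na(x), "spike_removal", gate)

  x <- fill_moving_median(x, k)

  d <- diff(x)
  sd_d <- stats::sd(d)
  blink <- c(FALSE, abs(d) > deriv_sd * sd_d) | c(abs(d) > deriv_sd * sd_d, FALSE)
  x[blink] <- NA_real_
  qc$deblink <- gate_missing(is.na(x), "deblink", gate)
  x <- fill_moving_median(x, k)

  x <- median_filter(x, k)
  qc$final_filter <- gate_missing(is.na(x), "final_filter", gate)

  out <- new_ts(x, fs = fs, t0 = drop_initial / fs)
  attr(out, "qc") <- tibble::tibble(
    stage = names(qc), missing_fraction = unlist(qc)
  )
  out
}

#' Resample to 1 Hz, regress out luminance, and smooth
#'
#' Linearly interpolates the cleaned trace onto a uniform 1 Hz grid
#' spanning seconds `0 .. duration - 1` of the movie (nearest-value
#' extrapolation outside the trace's support, including the dropped
#' initial adaptation window), regresses the pupil on luminance by
#' ordinary least squares (intercept + slope) and keeps the residuals,
#' then applies Gaussian smoothing with a `smooth_window_s`-sample window.
#'
#' @param clean Cleaned trace from [clean_pupil()].
#' @param luminance Luminance series at 1 Hz covering the movie duration.
#' @param smooth_window_s Smoothing window in seconds (default 40).
#' @return A `narousal_ts` at 1 Hz with attributes `slope` and
#'   `intercept` from the luminance regression.
#' @export
resample_and_regress <- function(clean, luminance, smooth_window_s = 40) {
  lum <- ts_values(luminance)
  dur <- length(lum)
  grid <- seq_len(dur) - 1
  tt <- clean$time
  vv <- clean$value
  if (min(tt) > dur - 1 || max(tt) < 0) {
    stop("resample_and_regress(): trace and luminance do not overlap",
         call. = FALSE)
  }
  p <- stats::approx(tt, vv, xout = grid, rule = 2)$y
  fit <- stats::lm(p ~ lum)
  res <- stats::residuals(fit)
  sm <- gaussian_smooth(res, smooth_window_s)
  out <- new_ts(sm, fs = 1)
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "residuals") <- res
  out
}
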