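# Welch spectra and spectral parametrization: the power spectrum is
# modelled as an aperiodic (1/f) component plus up to six Gaussian peaks,
# S(f) = L(f) + sum_n G_n(f) with L(f) = b - chi * log10(f) in log10
# power. Derived metrics: flattened spectra, individual alpha frequency,
# the rest-vs-movie aperiodic contrast and a frequency-bin cluster
# permutation contrast.

#' Welch power spectral density
#'
#' Hann-tapered averaged periodogram with 50% overlap, returned as log10
#' power. With `zero_pad_s = 10` and a 2 s window the frequency grid has
#' 0.1 Hz spacing, the high-resolution variant used for individual alpha
#' frequency detection.
#'
#' @param x Numeric signal (or `eeg_recording`, averaged over channels
#'   into a global field spectrum).
#' @param fs Sampling rate in Hz (taken from the recording if given one).
#' @param window_s Segment length in seconds (default 1.28).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param zero_pad_s Optional FFT length in seconds; segments are
#'   zero-padded to this length to refine the frequency grid.
#' @param f_max Truncate the returned grid at this frequency (default
#'   Nyquist).
#' @return A `power_spectrum` tibble with columns `freq` (Hz) and `power`
#'   (log10 power), attributes `resolution` and `fs`.
#' @export
welch_psd <- function(x, fs = NULL, window_s = 1.28, overlap = 0.5,
                      zero_pad_s = NULL, f_max = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    x <- colMeans(x$data)
  }
  stopifnot(!is.null(fs))
  nwin <- round(window_s * fs)
  if (nwin > length(x)) {
    stop("welch_psd(): window longer than the signal", call. = FALSE)
  }
  hop <- max(1L, round(nwin * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nwin - 1) / (nwin - 1)))  # Hann
  nfft <- if (is.null(zero_pad_s)) nwin else round(zero_pad_s * fs)
  stopifnot(nfft >= nwin)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(c(seg, rep(0, nfft - nwin))))^2
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  psd <- acc * scale
  half <- floor(nfft / 2) + 1
  psd <- psd[seq_len(half)]
  psd[2:(half - 1)] <- 2 * psd[2:(half - 1)]
  freq <- (seq_len(half) - 1) * fs / nfft
  if (!is.null(f_max)) {
    keep <- freq <= f_max
    freq <- freq[keep]; psd <- psd[keep]
  }
  out <- tibble::tibble(freq = freq, power = log10(pmax(psd, 1e-300)))
  attr(out, "resolution") <- fs / nfft
  attr(out, "fs") <- fs
  class(out) <- c("power_spectrum", class(out))
  out
}

aperiodic_eval <- function(freq, offset, exponent) offset - exponent * log10(freq)

gaussian_eval <- function(freq, center, height, width) {
  height * exp(-((freq - center)^2) / (2 * width^2))
}

# Robust line fit of log10 power on log10 frequency: ordinary fit, then
# refit excluding bins lying more than 1 SD above the first-pass line
# (peak resistance).
robust_aperiodic_fit <- function(freq, power) {
  lf <- log10(freq)
  fit <- stats::lm(power ~ lf)
  res <- stats::residuals(fit)
  keep <- res <= stats::sd(res)
  if (sum(keep) >= 5) fit <- stats::lm(power[keep] ~ lf[keep])
  co <- stats::coef(fit)
  c(offset = unname(co[1]), exponent = unname(-co[2]))
}

fit_one_peak <- function(freq, resid, width_bounds, f_range) {
  i0 <- which.max(resid)
  p0 <- c(center = freq[i0], height = resid[i0],
          width = mean(width_bounds))
  obj <- function(p) {
    sum((resid - gaussian_eval(freq, p[1], p[2], p[3]))^2)
  }
  fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = c(f_range[1], 0, width_bounds[1]),
                      upper = c(f_range[2], Inf, width_bounds[2]))
  fit$par
}

#' Fit the aperiodic + Gaussian-peaks spectral model
#'
#' Iterative decomposition in fixed aperiodic mode (no knee): (1) robust
#' line fit of log10 power against log10 frequency; (2) Gaussian peaks are
#' fitted and subtracted from the residual, largest first, until
#' `max_peaks` or the largest residual falls below `min_height`; (3) the
#' aperiodic component is refit on the peak-removed spectrum; (4) a final
#' simultaneous refinement of all parameters. Peaks retained must reach
#' `min_height` log10 units above the aperiodic fit.
#'
#' @param spectrum A `power_spectrum` (log10 power).
#' @param f_range Fit range in Hz (default 2-40).
#' @param max_peaks Maximum number of Gaussian peaks (default 6).
#' @param width_limits Peak width limits in Hz, bounding twice the
#'   Gaussian SD (default `c(1, 20)`).
#' @param min_height Minimum peak height in log10 units (default 0.15).
#' @return A `spectral_fit`: aperiodic `offset` and `exponent`, a `peaks`
#'   tibble (center, height, width), the `flattened` spectrum (input minus
#'   aperiodic component) and `fit_error` (mean absolute model residual).
#' @export
fit_spectral_model <- function(spectrum, f_range = c(2, 40), max_peaks = 6,
                               width_limits = c(1, 20), min_height = 0.15) {
  keep <- spectrum$freq >= f_range[1] & spectrum$freq <= f_range[2] &
    spectrum$freq > 0
  freq <- spectrum$freq[keep]
  power <- spectrum$power[keep]
  if (length(freq) < 5) {
    stop("fit_spectral_model(): fewer than 5 bins in the fit range",
         call. = FALSE)
  }
  wb <- width_limits / 2   # limits bound 2 * gaussian SD
  ap <- robust_aperiodic_fit(freq, power)
  resid <- power - aperiodic_eval(freq, ap[1], ap[2])
  peaks <- list()
  for (k in seq_len(max_peaks)) {
    if (max(resid) < min_height) break
    p <- fit_one_peak(freq, resid, wb, range(freq))
    if (p[2] < min_height) break
    peaks[[length(peaks) + 1]] <- p
    resid <- resid - gaussian_eval(freq, p[1], p[2], p[3])
  }
  peak_sum <- function(pl) {
    if (!length(pl)) return(rep(0, length(freq)))
    Reduce(`+`, purrr::map(pl, function(p) gaussian_eval(freq, p[1], p[2], p[3])))
  }
  ap <- robust_aperiodic_fit(freq, power - peak_sum(peaks))
  if (length(peaks)) {
    # joint refinement of aperiodic + all peaks
    pack <- c(ap, unlist(peaks))
    np <- length(peaks)
    obj <- function(th) {
      model <- aperiodic_eval(freq, th[1], th[2])
      for (j in seq_len(np)) {
        model <- model + gaussian_eval(freq, th[3 * j], th[3 * j + 1],
                                       th[3 * j + 2])
      }
      sum((power - model)^2)
    }
    lower <- c(-Inf, -Inf, rep(c(min(freq), 0, wb[1]), np))
    upper <- c(Inf, Inf, rep(c(max(freq), Inf, wb[2]), np))
    ref <- try(stats::optim(pack, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper), silent = TRUE)
    if (!inherits(ref, "try-error") && ref$value <= obj(pack)) {
      th <- ref$par
      ap <- c(offset = th[1], exponent = th[2])
      peaks <- purrr::map(seq_len(np), function(j) {
        c(center = th[3 * j], height = th[3 * j + 1], width = th[3 * j + 2])
      })
      peaks <- purrr::keep(peaks, function(p) p[2] >= min_height)
    }
  }
  peaks_tbl <- if (length(peaks)) {
    tibble::tibble(
      center = purrr::map_dbl(peaks, 1),
      height = purrr::map_dbl(peaks, 2),
      width = purrr::map_dbl(peaks, 3)
    )
  } else {
    tibble::tibble(center = double(), height = double(), width = double())
  }
  model <- aperiodic_eval(freq, ap[1], ap[2]) + peak_sum(peaks)
  flattened <- tibble::tibble(freq = freq,
                              power = power - aperiodic_eval(freq, ap[1], ap[2]))
  attr(flattened, "resolution") <- attr(spectrum, "resolution")
  class(flattened) <- c("power_spectrum", class(flattened))
  structure(
    list(aperiodic = c(offset = unname(ap[1]), exponent = unname(ap[2])),
         peaks = peaks_tbl,
         flattened = flattened,
         fit_error = mean(abs(power - model)),
         f_range = f_range),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> offset %.3f, exponent %.3f, %d peak(s), MAE %.4f\n",
              x$aperiodic["offset"], x$aperiodic["exponent"],
              nrow(x$peaks), x$fit_error))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Individual alpha frequency from a resting global spectrum
#'
#' Fits the spectral model over 1-40 Hz and takes the frequency of maximal
#' flattened power within 8-13 Hz as the IAF; the low-IAF band is
#' `[IAF - 1, IAF]`. Requires a high-resolution spectrum (0.1 Hz grid from
#' the zero-padded Welch variant). Errors if the model detects no peak in
#' the alpha range, instructing the caller to fall back to a group-level
#' IAF.
#'
#' @param spectrum A `power_spectrum` spanning at least 1-40 Hz at 0.1 Hz
#'   resolution.
#' @param alpha_range Search range (default `c(8, 13)`).
#' @return An `iaf_estimate`: list with `iaf`, `low_band`, and the
#'   underlying `fit`.
#' @export
estimate_iaf <- function(spectrum, alpha_range = c(8, 13)) {
  res <- attr(spectrum, "resolution")
  if (is.null(res) || res > 0.1 + 1e-9) {
    stop("estimate_iaf(): needs a spectrum at 0.1 Hz resolution ",
         "(welch_psd with window_s = 2, zero_pad_s = 10)", call. = FALSE)
  }
  fit <- fit_spectral_model(spectrum, f_range = c(1, 40))
  in_range <- fit$peaks$center >= alpha_range[1] &
    fit$peaks$center <= alpha_range[2]
  if (!any(in_range)) {
    stop("estimate_iaf(): no alpha peak detected in [8, 13] Hz; ",
         "fall back to the group-median IAF for this subject", call. = FALSE)
  }
  fl <- fit$flattened
  sel <- fl$freq >= alpha_range[1] & fl$freq <= alpha_range[2]
  iaf <- fl$freq[sel][which.max(fl$power[sel])]
  structure(list(iaf = iaf, low_band = c(iaf - 1, iaf), fit = fit),
            class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate> IAF = %.2f Hz, low-IAF band [%.2f, %.2f] Hz\n",
              x$iaf, x$low_band[1], x$low_band[2]))
  invisible(x)
}

#' Paired contrast of aperiodic exponents (rest vs movie)
#'
#' Classical paired-samples t-test on per-subject aperiodic exponents,
#' two-sided. The statistic is computed on movie minus rest differences,
#' so a positive t means a steeper (larger-exponent) spectrum during
#' movie viewing.
#'
#' @param exponents_rest,exponents_movie Equal-length per-subject vectors
#'   (n >= 3).
#' @return Tibble with `t`, `df`, `p`, `mean_rest`, `mean_movie`,
#'   `mean_diff`.
#' @export
aperiodic_contrast <- function(exponents_rest, exponents_movie) {
  n <- length(exponents_rest)
  if (length(exponents_movie) != n) {
    stop("aperiodic_contrast(): unequal condition lengths", call. = FALSE)
  }
  if (n < 3) stop("aperiodic_contrast(): need n >= 3 pairs", call. = FALSE)
  d <- exponents_movie - exponents_rest
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1,
                            mean_rest = mean(exponents_rest),
                            mean_movie = mean(exponents_movie),
                            mean_diff = 0))
    }
    stop("aperiodic_contrast(): degenerate (zero-variance, nonzero) differences",
         call. = FALSE)
  }
  tt <- stats::t.test(exponents_movie, exponents_rest, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_rest = mean(exponents_rest),
                 mean_movie = mean(exponents_movie),
                 mean_diff = mean(d))
}

# Contiguous same-sign supra-threshold runs over frequency bins.
# Non-finite t values (zero-variance bins) never exceed the threshold.
freq_clusters <- function(t_vals, t_crit) {
  t_vals[!is.finite(t_vals)] <- 0
  supra <- abs(t_vals) > t_crit
  sgn <- sign(t_vals)
  out <- list()
  i <- 1
  n <- length(t_vals)
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
      out[[length(out) + 1]] <- list(bins = i:j, sign = sgn[i],
                                     mass = sum(abs(t_vals[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Frequency-bin cluster permutation contrast (rest vs movie)
#'
#' Paired per-bin t-tests on flattened spectra; contiguous same-sign bins
#' exceeding the two-tailed critical t (uncorrected alpha) form clusters
#' whose mass is the summed |t|. The null flips each subject's condition
#' labels (sign flips of the paired differences) and retains the maximum
#' cluster mass per permutation; cluster p-values are add-one corrected
#' proportions of null maxima at or above the observed mass.
#'
#' @param flattened_rest,flattened_movie Subjects x frequency matrices of
#'   flattened log10 power on a common grid.
#' @param freqs Frequency grid (Hz) matching the matrix columns.
#' @param f_range Contrast range in Hz (default 2-18).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param alpha Uncorrected bin-level threshold (default 0.05).
#' @param seed Integer seed.
#' @return A `freq_cluster_test`: tibble of clusters (sign, `f_lo`,
#'   `f_hi`, `n_bins`, `mass`, `peak_t`, `p`, `significant`) with the
#'   per-bin t curve and null distribution as attributes.
#' @export
frequency_cluster_test <- function(flattened_rest, flattened_movie, freqs,
                                   f_range = c(2, 18), n_perm = 1000,
                                   alpha = 0.05, seed = 1) {
  if (!all(dim(flattened_rest) == dim(flattened_movie))) {
    stop("frequency_cluster_test(): condition matrices differ in shape",
         call. = FALSE)
  }
  if (n_perm < 100) warning("frequency_cluster_test(): n_perm < 100 gives a coarse null")
  keep <- freqs >= f_range[1] & freqs <= f_range[2]
  d <- flattened_movie[, keep, drop = FALSE] - flattened_rest[, keep, drop = FALSE]
  fr <- freqs[keep]
  n <- nrow(d)
  t_obs <- col_onesample_t(d)
  t_crit <- stats::qt(1 - alpha / 2, df = n - 1)
  obs <- freq_clusters(t_obs, t_crit)
  flips <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  })
  t_null <- signflip_t_matrix(d, flips)
  null_max <- apply(t_null, 1, function(tv) {
    cl <- freq_clusters(tv, t_crit)
    if (length(cl)) max(purrr::map_dbl(cl, "mass")) else 0
  })
  rows <- purrr::map(obs, function(cl) {
    tibble::tibble(
      sign = cl$sign,
      f_lo = fr[min(cl$bins)], f_hi = fr[max(cl$bins)],
      n_bins = length(cl$bins),
      mass = cl$sign * cl$mass,
      peak_t = t_obs[cl$bins][which.max(abs(t_obs[cl$bins]))],
      p = (1 + sum(null_max >= cl$mass)) / (1 + n_perm)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(sign = double(), f_lo = double(), f_hi = double(),
                   n_bins = integer(), mass = double(), peak_t = double(),
                   p = double())
  out$significant <- out$p < 0.05
  attr(out, "t_curve") <- tibble::tibble(freq = fr, t = t_obs)
  attr(out, "null_max") <- null_max
  attr(out, "t_crit") <- t_crit
  class(out) <- c("freq_cluster_test", class(out))
  out
}
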