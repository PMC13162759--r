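# Synthetic cohort generator: a latent 1 Hz arousal trajectory drives
# annotation raters, luminance-contaminated pupil traces with injected
# blinks/spikes/missing runs, and multichannel EEG whose band-limited
# power envelopes are coupled to the latent with configurable sign and
# strength per channel. Ground truth is retained throughout so recovery
# can be tested.

#' Generate a latent arousal trajectory
#'
#' Low-pass-filtered Gaussian noise at 1 Hz, standardized to mean 0 and
#' unit SD. The cutoff is `1 / smoothness_s` Hz, giving a controllable
#' autocorrelation scale matched to the 40 s smoothing used downstream.
#'
#' @param duration_s Duration in seconds (>= 60); the output has one
#'   sample per second.
#' @param smoothness_s Temporal smoothness scale in seconds (> 0).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A `narousal_ts` at 1 Hz with a `seed` attribute.
#' @export
generate_latent_arousal <- function(duration_s, smoothness_s = 40, seed = 1) {
  if (!is.numeric(duration_s) || duration_s < 60) {
    stop("generate_latent_arousal(): duration_s must be >= 60", call. = FALSE)
  }
  if (smoothness_s <= 0) {
    stop("generate_latent_arousal(): smoothness_s must be > 0", call. = FALSE)
  }
  n <- as.integer(duration_s)
  x <- withr::with_seed(seed, stats::rnorm(n + 4 * ceiling(smoothness_s)))
  w <- min(0.999, 2 / smoothness_s)   # cutoff as fraction of Nyquist (fs = 1)
  bf <- signal::butter(2, w, type = "low")
  y <- signal::filtfilt(bf, x)
  y <- y[(length(y) - n + 1):length(y)]   # drop filter warm-up
  out <- new_ts(zscore(y), fs = 1)
  attr(out, "seed") <- seed
  out
}

#' Generate a cohort of annotation raters
#'
#' Each rater mixes the latent trajectory with independent smooth noise
#' (`fidelity * latent + (1 - fidelity) * noise`), restandardizes the
#' mixture, then rescales it onto the 0-250 continuous rating scale
#' (centre 125, spread `scale_sd` rating units per z unit) and clips to
#' the scale bounds. Output is sampled at 1 Hz like the latent.
#'
#' @param latent Latent trajectory from [generate_latent_arousal()].
#' @param n_subjects Number of raters (>= 2; pairwise ISC needs pairs).
#' @param fidelity Mixing weight in `[0, 1]`; 1 reproduces the latent for
#'   every rater, 0 gives independent raters.
#' @param seed Integer seed.
#' @param smoothness_s Smoothness of each rater's private noise.
#' @param scale_sd Rating units per z unit (default 40 keeps clipping rare).
#' @return Long tibble with columns `subject`, `time`, `value` (0-250),
#'   attribute `fs = 1`.
#' @export
generate_annotation_cohort <- function(latent, n_subjects, fidelity,
                                       seed = 1, smoothness_s = 40,
                                       scale_sd = 40) {
  if (n_subjects < 2) {
    stop("generate_annotation_cohort(): n_subjects must be >= 2", call. = FALSE)
  }
  if (fidelity < 0 || fidelity > 1) {
    stop("generate_annotation_cohort(): fidelity must be in [0, 1]", call. = FALSE)
  }
  lv <- ts_values(latent)
  dur <- length(lv)
  raters <- purrr::map(seq_len(n_subjects), function(i) {
    noise <- ts_values(generate_latent_arousal(dur, smoothness_s,
                                               seed = child_seed(seed, i)))
    mix <- fidelity * lv + (1 - fidelity) * noise
    if (stats::sd(mix) > 0) mix <- zscore(mix)
    pmin(250, pmax(0, 125 + scale_sd * mix))
  })
  out <- tibble::tibble(
    subject = rep(paste0("s", seq_len(n_subjects)), each = dur),
    time = rep(seq_len(dur) - 1, n_subjects),
    value = unlist(raters)
  )
  attr(out, "fs") <- 1
  out
}

#' Generate a synthetic movie luminance series
#'
#' Smooth mean-grey-level trajectory in `[0, 255]` at 1 Hz, emulating the
#' per-second average intensity of grayscale-converted movie frames.
#'
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @return A `narousal_ts` at 1 Hz with values in grey levels.
#' @export
generate_luminance <- function(duration_s, seed = 1) {
  base <- ts_values(generate_latent_arousal(duration_s, smoothness_s = 15,
                                            seed = child_seed(seed, 7001L)))
  new_ts(pmin(255, pmax(0, 128 + 45 * base)), fs = 1)
}

#' Default artifact parameters for synthetic pupil traces
#'
#' @param blink_rate_per_min Blinks per minute (each a 200-400 ms drop to
#'   below 5% of baseline with 50 ms linear ramps).
#' @param spike_rate_per_min Isolated large-amplitude single-sample spikes
#'   per minute.
#' @param missing_rate_per_min Dropped (NA) runs per minute.
#' @param missing_run_s Length of each missing run in seconds.
#' @param noise_sd Additive white measurement noise SD (same units as the
#'   trace).
#' @return Named list of artifact parameters.
#' @export
pupil_artifact_params <- function(blink_rate_per_min = 12,
                                  spike_rate_per_min = 2,
                                  missing_rate_per_min = 0.5,
                                  missing_run_s = 1,
                                  noise_sd = 0.02) {
  list(blink_rate_per_min = blink_rate_per_min,
       spike_rate_per_min = spike_rate_per_min,
       missing_rate_per_min = missing_rate_per_min,
       missing_run_s = missing_run_s,
       noise_sd = noise_sd)
}

#' Generate a cohort of pupil traces
#'
#' Each subject's clean trace is
#' `baseline + a * latent - b * luminance_centred`, upsampled to `fs` by
#' sample-and-hold, plus smooth idiosyncratic drift and white noise.
#' Blinks, spikes and missing runs are injected at the configured rates.
#' The artifact-free clean trace and the injected artifact masks are
#' retained as attributes for recovery tests.
#'
#' @param latent Latent trajectory (1 Hz).
#' @param luminance Luminance series (1 Hz) spanning the same duration.
#' @param n_subjects Number of subjects.
#' @param fs Output sampling rate in Hz (default 60).
#' @param a Arousal gain in trace units per z unit.
#' @param b Luminance gain in trace units per grey level (entering with a
#'   negative sign: brighter frames constrict the pupil).
#' @param baseline Baseline diameter (arbitrary units).
#' @param artifact_params From [pupil_artifact_params()].
#' @param seed Integer seed.
#' @return List of `narousal_ts` traces (one per subject), each with
#'   attributes `clean` (ground-truth artifact-free values), `blink_mask`,
#'   `spike_mask`, `missing_mask`.
#' @export
generate_pupil_cohort <- function(latent, luminance, n_subjects, fs = 60,
                                  a = 0.25, b = 0.004, baseline = 4,
                                  artifact_params = pupil_artifact_params(),
                                  seed = 1) {
  lv <- ts_values(latent)
  lum <- ts_values(luminance)
  if (length(lv) != length(lum)) {
    stop("generate_pupil_cohort(): latent and luminance durations differ",
         call. = FALSE)
  }
  dur <- length(lv)
  n <- as.integer(dur * fs)
  lat_hi <- hold_1hz(lv, fs, n)
  lum_hi <- hold_1hz(lum - mean(lum), fs, n)
  ap <- artifact_params
  purrr::map(seq_len(n_subjects), function(i) {
    withr::with_seed(child_seed(seed, 100L + i), {
      drift <- ts_values(generate_latent_arousal(dur, smoothness_s = 60,
                                                 seed = child_seed(seed, 200L + i)))
      clean <- baseline + a * lat_hi - b * lum_hi +
        0.05 * hold_1hz(drift, fs, n)
      x <- clean + stats::rnorm(n, sd = ap$noise_sd)
      blink_mask <- rep(FALSE, n)
      n_blinks <- stats::rpois(1, ap$blink_rate_per_min * dur / 60)
      if (n_blinks > 0) {
        for (s in sort(sample.int(n - ceiling(0.5 * fs), n_blinks))) {
          dur_b <- round(stats::runif(1, 0.2, 0.4) * fs)
          ramp <- max(1L, round(0.05 * fs))
          idx <- s:min(n, s + dur_b - 1)
          prof <- rep(0.02, length(idx))
          rl <- min(ramp, length(idx))
          prof[seq_len(rl)] <- seq(1, 0.02, length.out = rl)
          prof[(length(idx) - rl + 1):length(idx)] <- seq(0.02, 1, length.out = rl)
          x[idx] <- x[idx] * prof
          blink_mask[idx] <- TRUE
        }
      }
      spike_mask <- rep(FALSE, n)
      n_spikes <- stats::rpois(1, ap$spike_rate_per_min * dur / 60)
      if (n_spikes > 0) {
        at <- sample.int(n, n_spikes)
        x[at] <- x[at] + sample(c(-1, 1), n_spikes, TRUE) *
          stats::runif(n_spikes, 1.5, 3)
        spike_mask[at] <- TRUE
      }
      missing_mask <- rep(FALSE, n)
      n_runs <- stats::rpois(1, ap$missing_rate_per_min * dur / 60)
      if (n_runs > 0) {
        len <- round(ap$missing_run_s * fs)
        for (s in sample.int(max(1L, n - len), n_runs)) {
          missing_mask[s:min(n, s + len - 1)] <- TRUE
        }
      }
      x[missing_mask] <- NA_real_
      out <- new_ts(x, fs = fs)
      attr(out, "clean") <- clean
      attr(out, "blink_mask") <- blink_mask
      attr(out, "spike_mask") <- spike_mask
      attr(out, "missing_mask") <- missing_mask
      out
    })
  })
}

#' Coupling specification for EEG synthesis
#'
#' Per (channel, band) coupling coefficients between the latent arousal
#' and the band's amplitude envelope. `beta = 0` entries yield envelopes
#' statistically independent of the latent.
#'
#' @param montage Montage tibble.
#' @param bands Character vector of band names (subset of
#'   `c("delta", "theta", "alpha")`).
#' @param beta Default coefficient for all entries.
#' @param overrides Optional tibble with columns `channel`, `band`, `beta`
#'   replacing individual entries.
#' @return Tibble with columns `channel`, `band`, `beta` (all |beta| <= 1).
#' @export
coupling_spec <- function(montage = montage_1020(),
                          bands = c("delta", "theta", "alpha"),
                          beta = 0, overrides = NULL) {
  out <- tidyr::expand_grid(channel = montage$label, band = bands)
  out$beta <- beta
  if (!is.null(overrides)) {
    key <- paste(out$channel, out$band)
    okey <- paste(overrides$channel, overrides$band)
    hit <- match(okey, key)
    out$beta[hit[!is.na(hit)]] <- overrides$beta[!is.na(hit)]
  }
  if (any(abs(out$beta) > 1)) {
    stop("coupling_spec(): |beta| must be <= 1", call. = FALSE)
  }
  out
}

#' Convenience coupling: posterior channels coupled in selected bands
#'
#' @param montage Montage tibble.
#' @param beta Coupling coefficient applied to posterior channels.
#' @param bands Bands to couple.
#' @return A coupling tibble as from [coupling_spec()].
#' @export
posterior_coupling <- function(montage = montage_1020(), beta = -0.3,
                               bands = c("delta", "theta", "alpha")) {
  post <- region_sets(montage)$posterior
  ov <- tidyr::expand_grid(channel = post, band = bands)
  ov$beta <- beta
  coupling_spec(montage, bands = c("delta", "theta", "alpha"),
                beta = 0, overrides = ov)
}

# 1/f^chi background noise of length n via FFT shaping of white noise.
one_over_f_noise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]      # mirror to two-sided frequencies
  g <- rep(0, n)
  pos <- f > 0
  # power spectrum ~ 1/f^chi  =>  amplitude ~ f^(-chi/2)
  g[pos] <- f[pos]^(-exponent / 2)
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrowband noise carrier: Gaussian frequency-domain mask centred on the
# band, unit variance. Gives Welch band power realistic (chi-squared)
# variance, unlike a pure tone.
narrowband_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  c0 <- (lo + hi) / 2
  bw <- (hi - lo) / 2
  g <- exp(-((f - c0)^2) / (2 * (bw / 2)^2))
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a cohort of EEG recordings with known arousal couplings
#'
#' Each channel is `1/f^chi` background noise plus band-limited
#' oscillations whose amplitude envelopes follow
#' `A_b(t) = amplitude_b * max(1 + beta * latent(t), floor)`, with the
#' latent sampled-and-held at 1 s resolution. The alpha oscillation is
#' centred on a per-subject individual alpha frequency drawn uniformly
#' from `iaf_range`. Deterministic given `seed`.
#'
#' @param latent Latent trajectory at 1 Hz.
#' @param montage Montage tibble.
#' @param coupling Coupling tibble from [coupling_spec()].
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate (default 200 Hz).
#' @param aperiodic_exponent 1/f exponent chi of the background.
#' @param background_sd Background noise SD in microvolts.
#' @param amplitudes Named numeric: mean oscillation amplitude (microvolts)
#'   per band.
#' @param band_freqs Named list of `c(lo, hi)` per band; the alpha entry is
#'   replaced per subject by `c(iaf - 1, iaf + 1)`.
#' @param iaf_range Range the per-subject alpha centre frequency is drawn
#'   from (within 8-13 Hz).
#' @param envelope_floor Smallest admissible relative envelope; envelopes
#'   that would go negative are clipped here with a warning.
#' @param envelope_noise_sd Log-amplitude SD of the slow idiosyncratic
#'   envelope modulation (vigilance-like drifts unrelated to the latent);
#'   each channel/band envelope is multiplied by
#'   `exp(envelope_noise_sd * eta(t))` with `eta` a slow unit-variance
#'   process. This term dominates band-power variance, which is what
#'   keeps subject-level arousal-power correlations in the realistic
#'   0.1-0.3 magnitude range at `|beta| = 0.3`. Set to 0 for a noiseless
#'   configuration.
#' @param envelope_noise_smoothness_s Smoothness scale of `eta` (seconds).
#' @param seed Integer seed.
#' @return List of `eeg_recording` objects, each with attributes `iaf`
#'   (the subject's true alpha centre) and `coupling` (the ground-truth
#'   table used).
#' @export
generate_eeg_cohort <- function(latent, montage = montage_1020(),
                                coupling = coupling_spec(montage),
                                n_subjects = 12, fs = 200,
                                aperiodic_exponent = 1.2,
                                background_sd = 12,
                                amplitudes = c(delta = 5, theta = 5, alpha = 6),
                                band_freqs = list(delta = c(1, 4),
                                                  theta = c(4, 7),
                                                  alpha = NULL),
                                iaf_range = c(8.5, 12.5),
                                envelope_floor = 0.05,
                                envelope_noise_sd = 2,
                                envelope_noise_smoothness_s = 30, seed = 1) {
  stopifnot(iaf_range[1] >= 8, iaf_range[2] <= 13)
  bands <- unique(coupling$band)
  if (!all(bands %in% c("delta", "theta", "alpha"))) {
    stop("generate_eeg_cohort(): bands must be among delta/theta/alpha",
         call. = FALSE)
  }
  lv <- ts_values(latent)
  n <- as.integer(length(lv) * fs)
  n_ch <- nrow(montage)
  warned <- FALSE
  purrr::map(seq_len(n_subjects), function(i) {
    withr::with_seed(child_seed(seed, 300L + i), {
      iaf <- stats::runif(1, iaf_range[1], iaf_range[2])
      dat <- matrix(0, n_ch, n)
      for (ch in seq_len(n_ch)) {
        dat[ch, ] <- background_sd * one_over_f_noise(n, aperiodic_exponent, fs)
      }
      for (b in bands) {
        fr <- band_freqs[[b]]
        if (b == "alpha" && is.null(fr)) fr <- c(iaf - 1, iaf + 1)
        beta_ch <- coupling$beta[coupling$band == b][match(
          montage$label, coupling$channel[coupling$band == b])]
        amp <- amplitudes[[b]]
        for (ch in seq_len(n_ch)) {
          env1 <- 1 + beta_ch[ch] * lv
          if (any(env1 < envelope_floor)) {
            if (!warned) {
              warning("generate_eeg_cohort(): envelope clipped at floor ",
                      envelope_floor)
              warned <<- TRUE
            }
            env1 <- pmax(env1, envelope_floor)
          }
          if (envelope_noise_sd > 0) {
            eta <- ts_values(generate_latent_arousal(
              length(lv), envelope_noise_smoothness_s,
              seed = child_seed(seed, 400L + 1000L * i + 17L * ch +
                                  match(b, c("delta", "theta", "alpha")))))
            env1 <- env1 * exp(envelope_noise_sd * eta)
          }
          env <- hold_1hz(env1, fs, n)
          dat[ch, ] <- dat[ch, ] + amp * env * narrowband_noise(n, fs, fr[1], fr[2])
        }
      }
      rec <- eeg_recording(dat, fs, montage)
      attr(rec, "iaf") <- iaf
      attr(rec, "coupling") <- coupling
      rec
    })
  })
}

#' Write a synthetic cohort to disk
#'
#' One CSV per trace (`time,value`) plus a JSON manifest recording seeds,
#' parameters and the ground-truth coupling table.
#'
#' @param annotations Long annotation tibble.
#' @param pupil List of pupil traces.
#' @param dir Output directory (created if needed).
#' @param manifest Named list written as JSON alongside the CSVs.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(annotations, pupil, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(annotations$subject)) {
    utils::write.csv(
      annotations[annotations$subject == s, c("time", "value")],
      file.path(dir, paste0("annotation_", s, ".csv")), row.names = FALSE)
  }
  for (i in seq_along(pupil)) {
    utils::write.csv(pupil[[i]][, c("time", "value")],
                     file.path(dir, sprintf("pupil_s%d.csv", i)),
                     row.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
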