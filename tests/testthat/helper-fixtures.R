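# Shared fixtures, built in code at test time.

fixture_montage <- function() montage_1020(32)

# Small EEG recording with arbitrary content for contract tests.
fixture_recording <- function(duration_s = 20, fs = 200, n_channels = 2,
                              seed = 1) {
  mont <- fixture_montage()[seq_len(n_channels), ]
  dat <- withr::with_seed(seed, {
    matrix(stats::rnorm(n_channels * duration_s * fs), n_channels)
  })
  eeg_recording(dat, fs, mont)
}

# Band-power series at the z-scored stage built directly from a matrix of
# channel envelopes (channels x epochs), bypassing spectral estimation.
fixture_zscored_series <- function(m, band = "theta") {
  z <- t(apply(m, 1, function(x) (x - mean(x)) / stats::sd(x)))
  rownames(z) <- rownames(m)
  structure(
    list(values = stats::setNames(list(z), band), n_epochs = ncol(m),
         bands = band_definitions(), epoch_s = 1, stage = "zscored"),
    class = "band_power_series"
  )
}

# Analytic log10 power spectrum: aperiodic line plus optional Gaussian
# peaks, on a regular grid.
fixture_spectrum <- function(freqs, offset = 1, exponent = 1,
                             peaks = NULL, noise_sd = 0, seed = 1) {
  p <- offset - exponent * log10(freqs)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      p <- p + peaks$height[i] *
        exp(-(freqs - peaks$center[i])^2 / (2 * peaks$width[i]^2))
    }
  }
  if (noise_sd > 0) {
    p <- p + withr::with_seed(seed, stats::rnorm(length(freqs), sd = noise_sd))
  }
  out <- tibble::tibble(freq = freqs, power = p)
  attr(out, "resolution") <- freqs[2] - freqs[1]
  class(out) <- c("power_spectrum", class(out))
  out
}
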