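test_that("Welch spectra localize tones and honour zero-padding", {
  fs <- 200
  t <- seq_len(10 * fs) / fs
  sp <- welch_psd(sin(2 * pi * 10 * t), fs = fs)
  expect_equal(sp$freq[which.max(sp$power)], sp$freq[which.min(abs(sp$freq - 10))])
  expect_equal(attr(sp, "resolution"), fs / round(1.28 * fs))

  spz <- welch_psd(rnorm(4 * fs), fs = fs, window_s = 2, zero_pad_s = 10)
  expect_equal(attr(spz, "resolution"), 0.1, tolerance = 1e-12)
  expect_error(welch_psd(rnorm(100), fs = fs, window_s = 2), "window")
})

test_that("Welch PSD integrates to the signal variance (Parseval)", {
  # independent oracle: total power of white noise equals its variance
  set.seed(1)
  fs <- 100
  x <- rnorm(50 * fs)
  sp <- welch_psd(x, fs = fs)
  total <- sum(10^sp$power) * attr(sp, "resolution")
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("white noise fits flat: exponent ~ 0", {
  set.seed(2)
  sp <- welch_psd(rnorm(60 * 200), fs = 200, f_max = 45)
  fit <- fit_spectral_model(sp)
  expect_lt(abs(fit$aperiodic["exponent"]), 0.1)
  flat_slope <- coef(lm(fit$flattened$power ~ log10(fit$flattened$freq)))[2]
  expect_lt(abs(flat_slope), 0.05)
})

test_that("an exact aperiodic line is recovered with no spurious peaks", {
  sp <- fixture_spectrum(seq(2, 40, by = 0.5), offset = 1, exponent = 1.2)
  fit <- fit_spectral_model(sp)
  expect_lt(abs(fit$aperiodic["exponent"] - 1.2), 0.05)
  expect_lt(abs(fit$aperiodic["offset"] - 1), 0.05)
  expect_equal(nrow(fit$peaks), 0)
  expect_error(fit_spectral_model(fixture_spectrum(seq(2, 3, 0.5))), "5 bins")
})

test_that("an injected Gaussian peak is localized within 0.2 Hz", {
  pk <- tibble::tibble(center = 10, height = 0.5, width = 1.5)
  sp <- fixture_spectrum(seq(2, 40, by = 0.25), offset = 1, exponent = 1,
                         peaks = pk, noise_sd = 0.01, seed = 3)
  fit <- fit_spectral_model(sp)
  expect_gte(nrow(fit$peaks), 1)
  main <- fit$peaks[which.max(fit$peaks$height), ]
  expect_lt(abs(main$center - 10), 0.2)
  expect_lt(abs(main$height - 0.5), 0.15)
})

test_that("peaks below the minimum height are not reported", {
  pk <- tibble::tibble(center = 10, height = 0.1, width = 1.5)
  sp <- fixture_spectrum(seq(2, 40, by = 0.25), peaks = pk)
  fit <- fit_spectral_model(sp)
  expect_equal(nrow(fit$peaks), 0)
})

test_that("the model reconstructs the spectrum within its fit error", {
  pk <- tibble::tibble(center = c(6, 10), height = c(0.3, 0.6),
                       width = c(1.2, 1.5))
  sp <- fixture_spectrum(seq(2, 40, by = 0.25), offset = 0.5, exponent = 1.4,
                         peaks = pk, noise_sd = 0.02, seed = 4)
  fit <- fit_spectral_model(sp)
  keep <- sp$freq >= 2 & sp$freq <= 40
  model <- (fit$aperiodic["offset"] - fit$aperiodic["exponent"] *
              log10(sp$freq[keep]))
  if (nrow(fit$peaks)) {
    for (i in seq_len(nrow(fit$peaks))) {
      model <- model + fit$peaks$height[i] *
        exp(-(sp$freq[keep] - fit$peaks$center[i])^2 /
              (2 * fit$peaks$width[i]^2))
    }
  }
  resid <- abs(sp$power[keep] - model)
  expect_equal(mean(resid), fit$fit_error, tolerance = 1e-12)
  expect_lt(max(resid), 10 * fit$fit_error + 0.05)
})

test_that("exponent recovery holds across a grid of 1/f slopes", {
  errs <- vapply(c(0.5, 1, 1.5, 2), function(chi) {
    mont <- fixture_montage()[1, , drop = FALSE]
    lat <- generate_latent_arousal(120, seed = 5)
    rec <- generate_eeg_cohort(lat, mont, coupling_spec(mont, beta = 0),
                               n_subjects = 1, aperiodic_exponent = chi,
                               amplitudes = c(delta = 0, theta = 0, alpha = 0),
                               seed = 50 + round(10 * chi))[[1]]
    fit <- fit_spectral_model(welch_psd(rec, f_max = 45))
    abs(fit$aperiodic["exponent"] - chi)
  }, 0)
  expect_lt(mean(errs), 0.1)
})

test_that("IAF is the flattened-power argmax in the alpha range", {
  pk <- tibble::tibble(center = 9.7, height = 0.6, width = 1.2)
  sp <- fixture_spectrum(seq(1, 40, by = 0.1), offset = 1, exponent = 1,
                         peaks = pk)
  est <- estimate_iaf(sp)
  expect_lt(abs(est$iaf - 9.7), 0.1 + 1e-9)
  expect_equal(est$low_band, c(est$iaf - 1, est$iaf))

  # two alpha peaks: the higher-power one wins
  pk2 <- tibble::tibble(center = c(9, 12), height = c(0.6, 0.3),
                        width = c(1, 1))
  sp2 <- fixture_spectrum(seq(1, 40, by = 0.1), peaks = pk2)
  expect_lt(abs(estimate_iaf(sp2)$iaf - 9), 0.1 + 1e-9)

  # no alpha peak: error instructing the group-median fallback
  sp3 <- fixture_spectrum(seq(1, 40, by = 0.1))
  expect_error(estimate_iaf(sp3), "group-median")
  # coarse grids are rejected
  expect_error(estimate_iaf(fixture_spectrum(seq(1, 40, by = 0.5))),
               "resolution")
})

test_that("the paired aperiodic contrast matches the closed form", {
  set.seed(6)
  n <- 25
  rest <- rnorm(n, 1.1, 0.2)
  movie <- rest + rnorm(n, 0.1, 0.25)
  res <- aperiodic_contrast(rest, movie)
  d <- movie - rest
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, n - 1)
  expect_equal(res$p, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-12)

  same <- aperiodic_contrast(rest, rest)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(aperiodic_contrast(rest, rest + 0.3), "degenerate")
  expect_error(aperiodic_contrast(rest[1:2], movie[1:2]), "n >= 3")
})

test_that("identical conditions produce no frequency clusters", {
  set.seed(7)
  m <- matrix(rnorm(10 * 33), 10)
  freqs <- seq(2, 18, by = 0.5)
  res <- frequency_cluster_test(m, m, freqs, n_perm = 200, seed = 8)
  expect_equal(nrow(res), 0)
})

test_that("an injected alpha suppression yields a negative cluster", {
  set.seed(9)
  freqs <- seq(2, 18, by = 0.5)
  n <- 20
  rest <- matrix(rnorm(n * length(freqs), sd = 0.1), n)
  movie <- matrix(rnorm(n * length(freqs), sd = 0.1), n)
  hit <- freqs >= 9 & freqs <= 14
  movie[, hit] <- movie[, hit] - 0.17  # ~ d = 1.2 on paired differences
  res <- frequency_cluster_test(rest, movie, freqs, n_perm = 500, seed = 10)
  neg <- res[res$sign < 0 & res$significant, ]
  expect_gte(nrow(neg), 1)
  expect_lte(neg$f_lo[1], 9.5)
  expect_gte(neg$f_hi[1], 13.5)
  expect_lt(neg$mass[1], 0)
})

test_that("the sign-flip engine reproduces the exhaustive null (paired)", {
  set.seed(11)
  n <- 8
  freqs <- seq(2, 6, by = 0.5)
  d <- matrix(rnorm(n * length(freqs)), n)
  t_crit <- qt(0.975, n - 1)
  # exhaustive 2^8 enumeration oracle
  flips_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  max_mass <- function(tv) {
    runs <- rle(as.vector((abs(tv) > t_crit) * sign(tv)))
    if (all(runs$values == 0)) return(0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    max(vapply(which(runs$values != 0), function(i) {
      sum(abs(tv[starts[i]:ends[i]]))
    }, 0))
  }
  exact <- apply(flips_all, 1, function(s) {
    ds <- d * s
    mm <- colMeans(ds)
    vv <- apply(ds, 2, sd)
    max_mass(mm / (vv / sqrt(n)))
  })
  res <- frequency_cluster_test(matrix(0, n, length(freqs)), d, freqs,
                                n_perm = 2000, seed = 12)
  null <- attr(res, "null_max")
  se <- sd(exact) / sqrt(2000)
  expect_lt(abs(mean(null) - mean(exact)), 4 * se)
})
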