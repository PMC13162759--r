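test_that("latent arousal is standardized, smooth and deterministic", {
  lat <- generate_latent_arousal(1200, smoothness_s = 40, seed = 1)
  expect_length(lat$value, 1200)
  expect_lt(abs(mean(lat$value)), 1e-9)
  expect_equal(sd(lat$value), 1, tolerance = 1e-12)
  expect_identical(lat$value,
                   generate_latent_arousal(1200, 40, seed = 1)$value)
  expect_false(identical(lat$value,
                         generate_latent_arousal(1200, 40, seed = 2)$value))
  # smoothness 40 s implies near-unity lag-1 autocorrelation
  r1 <- cor(lat$value[-1], lat$value[-1200])
  expect_gt(r1, 0.9)
  expect_error(generate_latent_arousal(30), "duration")
  expect_error(generate_latent_arousal(600, smoothness_s = 0), "smoothness")
})

test_that("annotation cohort spans the rating scale and tracks fidelity", {
  lat <- generate_latent_arousal(600, seed = 3)
  expect_error(generate_annotation_cohort(lat, 1, 0.5), "n_subjects")
  expect_error(generate_annotation_cohort(lat, 5, 1.5), "fidelity")

  full <- generate_annotation_cohort(lat, 4, fidelity = 1, seed = 1)
  m <- t(matrix(full$value, 600))
  prs <- cor(t(m))[upper.tri(diag(4))]
  expect_true(all(prs > 0.999))  # identical up to clipping

  none <- generate_annotation_cohort(lat, 6, fidelity = 0, seed = 1)
  m0 <- t(matrix(none$value, 600))
  expect_lt(abs(mean(cor(t(m0))[upper.tri(diag(6))])), 0.25)
  expect_true(all(none$value >= 0 & none$value <= 250))
})

test_that("cohort mean Fisher-z ISC matches a Monte-Carlo oracle", {
  # oracle: direct pairwise-correlation simulation over replicate cohorts
  # of mixtures fidelity * latent + (1 - fidelity) * noise
  fidelity <- 0.7
  oracle <- local({
    zs <- vapply(1:30, function(rep) {
      lat <- generate_latent_arousal(400, seed = 1000 + rep)
      m <- vapply(1:8, function(i) {
        noise <- generate_latent_arousal(400, seed = 2000 + 50 * rep + i)$value
        mix <- fidelity * lat$value + (1 - fidelity) * noise
        (mix - mean(mix)) / sd(mix)
      }, numeric(400))
      r <- cor(m)[upper.tri(diag(8))]
      mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))
    }, 0)
    mean(zs)
  })
  lat <- generate_latent_arousal(400, seed = 7)
  ann <- generate_annotation_cohort(lat, 8, fidelity, seed = 11)
  res <- pairwise_isc(ann)
  expect_lt(abs(res$mean_z - oracle), 0.1)
})

test_that("pupil traces honour ground truth, artifacts and luminance sign", {
  lat <- generate_latent_arousal(120, seed = 2)
  lum <- generate_luminance(120, seed = 2)
  quiet <- pupil_artifact_params(blink_rate_per_min = 0, spike_rate_per_min = 0,
                                 missing_rate_per_min = 0, noise_sd = 0)
  tr <- generate_pupil_cohort(lat, lum, 1, artifact_params = quiet, seed = 4)[[1]]
  expect_identical(tr$value, attr(tr, "clean"))

  noisy <- generate_pupil_cohort(lat, lum, 1, seed = 4)[[1]]
  bm <- attr(noisy, "blink_mask")
  expect_gt(sum(bm), 0)
  sm <- attr(noisy, "spike_mask")
  near_zero <- !is.na(noisy$value) & noisy$value < 1 & !sm
  # injected blink samples account for the near-zero portion of the trace
  expect_gt(mean(near_zero[bm & !attr(noisy, "missing_mask")]), 0.5)
  expect_true(all(which(near_zero) %in% which(bm)))

  # b > 0 makes the raw trace anticorrelate with luminance
  strong <- generate_pupil_cohort(lat, lum, 1, a = 0, b = 0.01,
                                  artifact_params = quiet, seed = 5)[[1]]
  lum_hi <- rep(lum$value, each = 60)
  expect_lt(cor(strong$value, lum_hi), -0.9)

  short_lum <- generate_luminance(60, seed = 1)
  expect_error(generate_pupil_cohort(lat, short_lum, 1), "duration")
})

test_that("EEG cohort recovers its aperiodic exponent and coupling signs", {
  mont <- fixture_montage()[1:4, ]
  lat <- generate_latent_arousal(300, seed = 5)
  cpl0 <- coupling_spec(mont, beta = 0)
  rec <- generate_eeg_cohort(lat, mont, cpl0, n_subjects = 1, seed = 6,
                             amplitudes = c(delta = 0, theta = 0, alpha = 0),
                             aperiodic_exponent = 1.5)[[1]]
  # oracle: straight log-log regression on the noise-only Welch spectrum
  sp <- welch_psd(rec$data[1, ], fs = rec$fs, f_max = 45)
  keep <- sp$freq >= 2 & sp$freq <= 40
  chi_hat <- -coef(lm(sp$power[keep] ~ log10(sp$freq[keep])))[2]
  expect_lt(abs(chi_hat - 1.5), 0.1)

  expect_identical(
    generate_eeg_cohort(lat, mont, cpl0, n_subjects = 1, seed = 9)[[1]]$data,
    generate_eeg_cohort(lat, mont, cpl0, n_subjects = 1, seed = 9)[[1]]$data
  )
})

test_that("band power rises monotonically with the latent when coupled", {
  mont <- fixture_montage()[1:2, ]
  lat <- generate_latent_arousal(120, seed = 8)
  cpl <- coupling_spec(mont, bands = "theta", beta = 0.8)
  rec <- suppressWarnings(   # |beta| near 1 clips the envelope at its floor
    generate_eeg_cohort(lat, mont, cpl, n_subjects = 1, seed = 8,
                        background_sd = 0, envelope_noise_sd = 0,
                        amplitudes = c(delta = 0, theta = 5, alpha = 0)))[[1]]
  bp <- epoch_band_power(rec, band_definitions(10))
  # average over the carrier noise before comparing: smoothed log power
  # should be ordered like the envelope (1 + b*L)^2
  theta <- gaussian_smooth(bp$values$theta[1, ], 20)
  expect_gt(cor(theta, rank(lat$value), method = "spearman"), 0.9)
})

test_that("uncoupled channels stay independent of the latent", {
  mont <- fixture_montage()[1:6, ]
  lat <- generate_latent_arousal(300, seed = 12)
  cpl <- coupling_spec(mont, beta = 0)
  recs <- generate_eeg_cohort(lat, mont, cpl, n_subjects = 4, seed = 13)
  rs <- unlist(lapply(recs, function(rec) {
    tz <- transform_power(epoch_band_power(rec, band_definitions(10)))
    correlate_with_arousal(tz, lat)$r
  }))
  # distribution of correlations centred on zero
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cohorts round-trip through CSV + manifest export", {
  lat <- generate_latent_arousal(60 * 2, seed = 1)
  lum <- generate_luminance(120, seed = 1)
  ann <- generate_annotation_cohort(lat, 2, 0.8, seed = 1)
  pup <- generate_pupil_cohort(lat, lum, 1, seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(ann, pup, dir, manifest = list(seed = 1, fidelity = 0.8))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read.csv(file.path(dir, "annotation_s1.csv"))
  expect_equal(back$value, ann$value[ann$subject == "s1"])
})
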