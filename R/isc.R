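# Inter-subject correlation: all unique participant pairs, Fisher-z
# aggregation, circular time-shift surrogate null, and per-channel ISC
# maps for EEG power envelopes.

new_isc_result <- function(pairwise_r, null = NULL, p = NULL, n_perm = NULL) {
  z <- fisher_z(pairwise_r[upper.tri(pairwise_r)])
  structure(
    list(
      pairwise_r = pairwise_r,
      mean_z = mean(z),
      mean_r = tanh(mean(z)),
      sd_r = stats::sd(pairwise_r[upper.tri(pairwise_r)]),
      n_subjects = nrow(pairwise_r),
      null_distribution = null,
      n_perm = n_perm,
      p = p
    ),
    class = "isc_result"
  )
}

pairwise_r_matrix <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("pairwise_isc(): constant series for subject(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(m))
  diag(r) <- NA_real_
  r
}

#' Pairwise inter-subject correlation
#'
#' Computes Pearson correlations between all `n (n - 1) / 2` unique
#' subject pairs, Fisher-z transforms them, and reports the z-mean and its
#' back-transform. `|r| = 1` pairs are clipped before `atanh` with a
#' warning.
#'
#' @param data Long tibble (`subject`, `time`, `value`) or subjects x time
#'   matrix; at least 2 subjects, equal lengths, each nonconstant.
#' @return An `isc_result` with the pairwise matrix, `mean_z`, `mean_r`
#'   and `sd_r`.
#' @export
pairwise_isc <- function(data) {
  m <- as_subject_matrix(data)
  if (nrow(m) < 2) stop("pairwise_isc(): need at least 2 subjects", call. = FALSE)
  new_isc_result(pairwise_r_matrix(m))
}

#' Circular time-shift surrogate test for ISC
#'
#' Each permutation applies an independent random circular shift to every
#' subject's series (destroying stimulus alignment while preserving each
#' series' value distribution and autocorrelation), recomputes the mean
#' Fisher-z ISC, and the one-sided empirical p-value is
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param data As in [pairwise_isc()].
#' @param n_perm Number of surrogates (>= 1; default 1000).
#' @param min_shift_s Minimum shift in samples, avoiding near-identity
#'   surrogates; shifts are drawn uniformly from
#'   `[min_shift_s, T - min_shift_s]`.
#' @param seed Integer seed.
#' @return An `isc_result` carrying `null_distribution` and `p`.
#' @export
circular_shift_null <- function(data, n_perm = 1000, min_shift_s = 10,
                                seed = 1) {
  m <- as_subject_matrix(data)
  n_sub <- nrow(m)
  len <- ncol(m)
  if (n_perm < 1) stop("circular_shift_null(): n_perm must be >= 1", call. = FALSE)
  if (len < 2 * min_shift_s) {
    stop("circular_shift_null(): series shorter than twice the minimum shift",
         call. = FALSE)
  }
  obs <- pairwise_r_matrix(m)
  obs_z <- mean(fisher_z(obs[upper.tri(obs)]))
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      shifts <- sample(seq.int(min_shift_s, len - min_shift_s), n_sub,
                       replace = TRUE)
      sm <- m
      for (i in seq_len(n_sub)) sm[i, ] <- circular_shift(m[i, ], shifts[i])
      r <- stats::cor(t(sm))
      mean(fisher_z(r[upper.tri(r)]))
    }, 0)
  })
  p <- (1 + sum(null >= obs_z)) / (1 + n_perm)
  new_isc_result(obs, null = null, p = p, n_perm = n_perm)
}

#' Per-channel ISC of EEG power envelopes
#'
#' ISC is computed on slow band-power envelopes rather than raw
#' oscillatory phase, sidestepping phase-mismatch across subjects. For
#' each channel the pairwise Pearson correlations across subjects are
#' Fisher-z averaged and back-transformed, yielding a topography table.
#'
#' @param envelopes Either a long tibble with columns `subject`,
#'   `channel`, `epoch`, `value` (e.g. [tidy()] of [transform_power()]
#'   outputs bound over subjects) or a list (one element per subject) of
#'   channels x epochs matrices with channel rownames.
#' @param band Optional band label recorded in the output.
#' @return Tibble with columns `channel`, `mean_r`, `mean_z`, `sd_r`
#'   (one row per channel), class `isc_topography`.
#' @export
eeg_power_isc <- function(envelopes, band = NA_character_) {
  if (is.data.frame(envelopes)) {
    channels <- unique(envelopes$channel)
    get_chan <- function(ch) {
      as_subject_matrix(envelopes[envelopes$channel == ch, ])
    }
  } else {
    channels <- rownames(envelopes[[1]])
    get_chan <- function(ch) {
      do.call(rbind, purrr::map(envelopes, function(m) m[ch, ]))
    }
  }
  rows <- purrr::map(channels, function(ch) {
    res <- pairwise_isc(get_chan(ch))
    tibble::tibble(channel = ch, mean_r = res$mean_r, mean_z = res$mean_z,
                   sd_r = res$sd_r)
  })
  out <- dplyr::bind_rows(rows)
  out$band <- band
  class(out) <- c("isc_topography", class(out))
  out
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf("<isc_result> %d subjects, %d pairs\n", x$n_subjects,
              sum(upper.tri(x$pairwise_r))))
  cat(sprintf("  mean r = %.3f (Fisher-z mean %.3f), SD of pairwise r = %.3f\n",
              x$mean_r, x$mean_z, x$sd_r))
  if (!is.null(x$p)) {
    cat(sprintf("  circular-shift null: %d surrogates, p = %.4g\n",
                x$n_perm, x$p))
  }
  invisible(x)
}
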