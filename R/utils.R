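# Shared numerical helpers: standardization, Fisher z, Gaussian smoothing,
# circular shifts, and vectorized t-statistics used by the permutation engines.

#' Z-score a numeric vector
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (denominator `n - 1`). With this convention the dot product of two
#' z-scored vectors divided by `n - 1` equals their Pearson correlation
#' exactly.
#'
#' @param x Numeric vector without missing values.
#' @return Numeric vector with mean 0 and unit sample SD.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zscore(): input has zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Fisher z transform with clipping at |r| = 1
#'
#' `atanh(r)` diverges at `|r| = 1`; perfectly correlated pairs (which arise
#' for identical synthetic raters) are clipped to `sign(r) * (1 - 1e-12)`
#' with a warning before transforming.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Fisher z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("fisher_z(): correlations outside [-1, 1]", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  hit <- abs(r) >= 1
  if (any(hit)) {
    warning("fisher_z(): |r| = 1 clipped to 1 - 1e-12 before atanh")
    r[hit] <- sign(r[hit]) * (1 - 1e-12)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Gaussian smoothing with edge renormalization
#'
#' Convolves with a truncated Gaussian kernel of standard deviation
#' `window / 6`, truncated at `floor(window / 2)` samples either side.
#' Near the edges the kernel is renormalized over the samples actually
#' available, so the filter is linear and shift-equivariant away from the
#' edges and does not dampen edge values.
#'
#' @param x Numeric vector.
#' @param window Kernel window length in samples (the paper-style "window
#'   size"; e.g. 40 samples for a 40 s window at 1 Hz).
#' @return Smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, window) {
  stopifnot(window >= 1)
  half <- max(1L, floor(window / 2))
  sigma <- window / 6
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Circularly shift a vector
#'
#' Rotates `x` by `k` samples (positive `k` delays the series). The output
#' is a permutation of the input, so its sorted values are identical to the
#' original's: the rotation preserves amplitude distribution and
#' autocorrelation while destroying stimulus alignment.
#'
#' @param x Numeric vector.
#' @param k Integer shift (any sign; reduced modulo `length(x)`).
#' @return Rotated vector.
#' @export
circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# One-sample t statistic per column of a subjects x variables matrix
# (two-pass variance, exact to the closed form mean / (sd / sqrt(n))).
# Zero-variance zero-mean columns give t = 0.
col_onesample_t <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- colSums(sweep(x, 2, m)^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  unname(t)
}

# t statistics for all sign-flip permutations at once. `flips` is a
# n_perm x n_subjects matrix of +/-1. Squared values are flip-invariant,
# so only the mean changes per permutation.
signflip_t_matrix <- function(x, flips) {
  n <- nrow(x)
  m <- (flips %*% x) / n                      # n_perm x n_var means
  q <- matrix(colSums(x^2), nrow(flips), ncol(x), byrow = TRUE)
  v <- (q - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  t
}

# Sample-and-hold a 1 Hz series onto a higher-rate grid of n samples.
hold_1hz <- function(x, fs, n) {
  idx <- pmin(length(x), floor((seq_len(n) - 1) / fs) + 1)
  x[idx]
}

# Coerce a long tibble (subject, time/epoch, value) or a subjects x time
# matrix into a subjects x time matrix with subject names.
as_subject_matrix <- function(data, value_col = "value") {
  if (is.matrix(data)) {
    if (is.null(rownames(data))) rownames(data) <- paste0("s", seq_len(nrow(data)))
    return(data)
  }
  if (!is.data.frame(data)) {
    stop("expected a subjects x time matrix or a long data frame", call. = FALSE)
  }
  need <- c("subject", value_col)
  if (!all(need %in% names(data))) {
    stop("long data frame must have columns 'subject' and '", value_col, "'",
         call. = FALSE)
  }
  time_col <- intersect(c("time", "epoch"), names(data))[1]
  if (is.na(time_col)) stop("long data frame needs a 'time' or 'epoch' column",
                            call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::arrange(data, .data$subject, .data[[time_col]]),
    id_cols = "subject", names_from = dplyr::all_of(time_col),
    values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$subject)
  storage.mode(m) <- "double"
  m
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483587)
}
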