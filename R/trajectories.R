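# Group-level arousal trajectories: validation of the 0-250 / 1 Hz
# annotation contract, z-scored group means per modality, and the
# cross-modal annotation-pupil correlation.

#' Validate a continuous annotation series
#'
#' Asserts the annotation acquisition contract: sampled at 1 Hz with
#' values on the 0-250 continuous rating scale. Returns the series
#' unchanged.
#'
#' @param series A `narousal_ts` or data frame with `time` and `value`.
#' @return The input, invisibly validated.
#' @export
validate_annotations <- function(series) {
  fs <- ts_fs(series)
  if (abs(fs - 1) > 1e-6) {
    stop(sprintf("validate_annotations(): expected 1 Hz sampling, got %g Hz", fs),
         call. = FALSE)
  }
  v <- ts_values(series)
  bad <- which(!is.na(v) & (v < 0 | v > 250))
  if (length(bad)) {
    stop(sprintf(
      "validate_annotations(): %d value(s) outside [0, 250] (first at t = %gs: %g)",
      length(bad), series$time[bad[1]], v[bad[1]]), call. = FALSE)
  }
  series
}

#' Group-mean arousal trajectory
#'
#' Optionally z-scores each subject's series, then averages element-wise
#' across subjects. Averaging attenuates idiosyncratic rater noise, so the
#' group mean tracks the shared stimulus-driven component better than any
#' single subject.
#'
#' @param data Long tibble with columns `subject`, `time`, `value`, a list
#'   of traces, or a subjects x time matrix.
#' @param zscore_first Z-score each subject before averaging (default TRUE).
#' @param modality Label recorded on the result (`"annotation"` or
#'   `"pupil"`).
#' @return A `narousal_ts` at 1 Hz with attributes `n_subjects` and
#'   `modality`.
#' @export
group_mean_trajectory <- function(data, zscore_first = TRUE,
                                  modality = "annotation") {
  if (is.list(data) && !is.data.frame(data) && !is.matrix(data)) {
    lens <- lengths(purrr::map(data, ts_values))
    if (length(unique(lens)) != 1) {
      stop("group_mean_trajectory(): series lengths differ", call. = FALSE)
    }
    m <- do.call(rbind, purrr::map(data, ts_values))
    rownames(m) <- paste0("s", seq_len(nrow(m)))
  } else {
    m <- as_subject_matrix(data)
  }
  if (nrow(m) < 2) {
    stop("group_mean_trajectory(): need at least 2 subjects", call. = FALSE)
  }
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    if (all(flat)) {
      stop("group_mean_trajectory(): all subjects have zero variance (",
           paste(rownames(m)[flat], collapse = ", "), ")", call. = FALSE)
    }
    warning("group_mean_trajectory(): excluding zero-variance subject(s): ",
            paste(rownames(m)[flat], collapse = ", "))
    m <- m[!flat, , drop = FALSE]
  }
  if (zscore_first) m <- t(apply(m, 1, zscore))
  out <- new_ts(colMeans(m), fs = 1)
  attr(out, "n_subjects") <- nrow(m)
  attr(out, "modality") <- modality
  out
}

#' Cross-modal correlation between two group trajectories
#'
#' Pearson correlation between the group-mean annotation and pupil
#' trajectories, with a two-sided parametric p-value. Because both series
#' are strongly autocorrelated, a circular-shift permutation p-value is
#' available as an alternative.
#'
#' @param annot,pupil Trajectories of equal length (`narousal_ts` or
#'   numeric).
#' @param method `"parametric"` (default) or `"circular_shift"`.
#' @param n_perm,min_shift_s,seed Permutation settings when
#'   `method = "circular_shift"`.
#' @return Tibble with columns `r`, `p`, `n`, `method`.
#' @export
crossmodal_correlation <- function(annot, pupil, method = c("parametric",
                                                            "circular_shift"),
                                   n_perm = 1000, min_shift_s = 10, seed = 1) {
  method <- match.arg(method)
  x <- ts_values(annot)
  y <- ts_values(pupil)
  if (length(x) != length(y)) {
    stop("crossmodal_correlation(): trajectories differ in length", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("crossmodal_correlation(): zero-variance trajectory", call. = FALSE)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (method == "parametric") {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    null <- withr::with_seed(seed, {
      shifts <- sample(seq.int(min_shift_s, n - min_shift_s), n_perm,
                       replace = TRUE)
      vapply(shifts, function(k) stats::cor(x, circular_shift(y, k)), 0)
    })
    p <- (1 + sum(abs(null) >= abs(r))) / (1 + n_perm)
  }
  tibble::tibble(r = r, p = p, n = n, method = method)
}
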