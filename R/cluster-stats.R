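# Group-level inference on per-subject correlation maps: per-channel
# one-sample t-tests, spatial adjacency from electrode positions,
# sign-homogeneous cluster formation, the max-cluster-mass sign-flip
# permutation test, FDR for ROI-level maps, and effect sizes.

#' Per-channel one-sample t-test
#'
#' Tests, at each channel, whether the mean correlation across subjects
#' differs from zero.
#'
#' @param maps Subjects x channels matrix (channel colnames) or long
#'   tibble with columns `subject`, `channel`, `r`.
#' @return A `stat_map` tibble: `channel`, `mean`, `t`, `df`.
#' @export
channel_ttest <- function(maps) {
  m <- as_channel_matrix(maps)
  n <- nrow(m)
  if (n < 3) stop("channel_ttest(): need at least 3 subjects", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("channel_ttest(): zero-variance channel(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    channel = colnames(m),
    mean = colMeans(m),
    t = col_onesample_t(m),
    df = n - 1
  )
  class(out) <- c("stat_map", class(out))
  out
}

as_channel_matrix <- function(maps) {
  if (is.matrix(maps)) {
    if (is.null(colnames(maps))) colnames(maps) <- paste0("ch", seq_len(ncol(maps)))
    return(maps)
  }
  if (!all(c("subject", "channel", "r") %in% names(maps))) {
    stop("maps must be a matrix or a tibble with subject/channel/r columns",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(maps[, c("subject", "channel", "r")],
                             names_from = "channel", values_from = "r")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$subject)
  m
}

#' Spatial adjacency from electrode positions
#'
#' Channels are adjacent when the Euclidean (chord) distance between
#' their unit-sphere positions is below `threshold`. Positions must be
#' normalized to unit head radius (maximal radius within 10% of 1).
#'
#' @param montage Montage tibble with `x`, `y`, `z` columns.
#' @param threshold Distance threshold (default 0.4).
#' @return Symmetric logical channels x channels matrix, zero diagonal.
#' @export
build_adjacency <- function(montage, threshold = 0.4) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  radii <- sqrt(rowSums(pos^2))
  if (abs(max(radii) - 1) > 0.1) {
    stop("build_adjacency(): positions not normalized to unit head radius",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(pos))
  adj <- d < threshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  adj
}

# Connected components among `active` nodes of `adj`, visited in
# deterministic channel-index order.
connected_components <- function(adj, active) {
  n <- length(active)
  comp <- integer(n)
  cur <- 0L
  for (s in which(active)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & active & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Cluster list (members, sign, mass, peak_t) for a t vector.
clusters_from_t <- function(t_vals, adj, t_crit) {
  out <- list()
  for (sgn in c(1, -1)) {
    active <- (sign(t_vals) == sgn) & (abs(t_vals) > t_crit)
    if (!any(active)) next
    comp <- connected_components(adj, active)
    for (k in seq_len(max(comp))) {
      members <- which(comp == k)
      tv <- t_vals[members]
      out[[length(out) + 1]] <- list(
        members = members, sign = sgn, mass = sum(abs(tv)),
        peak_t = tv[which.max(abs(tv))]
      )
    }
  }
  out
}

#' Form sign-homogeneous spatial clusters
#'
#' Supra-threshold channels (|t| above `t_crit`) sharing the same sign are
#' grouped into connected components of the adjacency graph.
#'
#' @param stat A `stat_map` from [channel_ttest()] (or a named t vector).
#' @param adjacency Adjacency matrix from [build_adjacency()].
#' @param t_crit Two-tailed critical t (> 0) at the uncorrected bin-level
#'   alpha.
#' @return Tibble with one row per cluster: `cluster`, `sign`,
#'   `n_channels`, `channels` (list column), `mass` (signed sum of t, i.e.
#'   `sign * sum |t|`), `peak_t`.
#' @export
form_clusters <- function(stat, adjacency, t_crit) {
  stopifnot(t_crit > 0)
  t_vals <- if (is.data.frame(stat)) stats::setNames(stat$t, stat$channel) else stat
  labels <- names(t_vals)
  cl <- clusters_from_t(t_vals, adjacency, t_crit)
  if (!length(cl)) {
    return(tibble::tibble(cluster = integer(), sign = double(),
                          n_channels = integer(), channels = list(),
                          mass = double(), peak_t = double()))
  }
  tibble::tibble(
    cluster = seq_along(cl),
    sign = purrr::map_dbl(cl, "sign"),
    n_channels = purrr::map_int(cl, ~ length(.x$members)),
    channels = purrr::map(cl, ~ labels[.x$members]),
    mass = purrr::map_dbl(cl, ~ .x$sign * .x$mass),
    peak_t = purrr::map_dbl(cl, "peak_t")
  )
}

#' Max-cluster-mass sign-flip permutation test
#'
#' One-sample cluster inference on subjects x channels correlation maps:
#' per-channel t-tests are thresholded at the two-tailed uncorrected
#' critical t, sign-homogeneous adjacent channels form clusters whose
#' mass is the summed |t|. Under the null each subject's whole map is
#' multiplied by a random sign; the maximum cluster mass (over both
#' signs) per permutation builds the null, and each observed cluster's
#' corrected p is the add-one proportion of null maxima at or above its
#' mass.
#'
#' @param maps Subjects x channels matrix or long `subject`/`channel`/`r`
#'   tibble.
#' @param adjacency Adjacency matrix from [build_adjacency()].
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param alpha Uncorrected channel-level threshold (default 0.05).
#' @param seed Integer seed.
#' @return A `cluster_test` object: cluster tibble (with `p_corrected`,
#'   `significant`, Cohen's `d` of the peak channel, and the cluster-mean
#'   correlation `avg_r`), plus the stat map and null distribution.
#' @export
signflip_permutation <- function(maps, adjacency, n_perm = 10000,
                                 alpha = 0.05, seed = 1) {
  m <- as_channel_matrix(maps)
  if (n_perm < 1) stop("signflip_permutation(): n_perm must be >= 1", call. = FALSE)
  stat <- channel_ttest(m)
  n <- nrow(m)
  t_crit <- stats::qt(1 - alpha / 2, df = n - 1)
  clusters <- form_clusters(stat, adjacency, t_crit)
  flips <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  })
  t_null <- signflip_t_matrix(m, flips)
  supra_any <- rowSums(abs(t_null) > t_crit) > 0
  null_max <- numeric(n_perm)
  for (i in which(supra_any)) {
    cl <- clusters_from_t(t_null[i, ], adjacency, t_crit)
    if (length(cl)) null_max[i] <- max(purrr::map_dbl(cl, "mass"))
  }
  if (nrow(clusters)) {
    clusters$p_corrected <- purrr::map_dbl(abs(clusters$mass), function(ms) {
      (1 + sum(null_max >= ms)) / (1 + n_perm)
    })
    clusters$significant <- clusters$p_corrected < 0.05
    clusters$d <- cohens_d_from_t(clusters$peak_t, n)
    clusters$avg_r <- purrr::map_dbl(clusters$channels, function(chs) {
      mean(m[, chs, drop = FALSE])
    })
  } else {
    clusters$p_corrected <- double()
    clusters$significant <- logical()
    clusters$d <- double()
    clusters$avg_r <- double()
  }
  structure(
    list(clusters = clusters, stat_map = stat, null_max = null_max,
         t_crit = t_crit, n_perm = n_perm, n_subjects = n),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d subjects, t_crit = %.2f, %d permutations\n",
              x$n_subjects, x$t_crit, x$n_perm))
  if (nrow(x$clusters)) {
    print(x$clusters[, c("cluster", "sign", "n_channels", "mass", "peak_t",
                         "p_corrected", "d", "avg_r")])
  } else {
    cat("  no supra-threshold clusters\n")
  }
  invisible(x)
}

#' One-sample Cohen's d from a t statistic
#'
#' `d = t / sqrt(n)` for a one-sample design with `n` subjects.
#'
#' @param t t statistic(s).
#' @param n Number of subjects (> 0).
#' @return Cohen's d, same sign as `t`.
#' @export
cohens_d_from_t <- function(t, n) {
  if (!is.numeric(n) || any(n <= 0)) {
    stop("cohens_d_from_t(): n must be positive", call. = FALSE)
  }
  t / sqrt(n)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values and the rejection mask at level `q`.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p`, `p_adjusted`, `rejected`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("fdr_correct(): p-values outside [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adjusted = adj, rejected = adj <= q)
}
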