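# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ISC result into a pair table
#' @param x An `isc_result`.
#' @param ... Unused.
#' @return Tibble with one row per unique subject pair (`subject_i`,
#'   `subject_j`, `r`, `z`).
#' @method tidy isc_result
#' @export
tidy.isc_result <- function(x, ...) {
  m <- x$pairwise_r
  idx <- which(upper.tri(m), arr.ind = TRUE)
  labs <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  tibble::tibble(
    subject_i = labs[idx[, 1]],
    subject_j = labs[idx[, 2]],
    r = m[idx],
    z = suppressWarnings(fisher_z(m[idx]))
  )
}

#' @rdname tidy.isc_result
#' @method glance isc_result
#' @export
glance.isc_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_pairs = sum(upper.tri(x$pairwise_r)),
    mean_r = x$mean_r,
    mean_z = x$mean_z,
    sd_r = x$sd_r,
    n_perm = x$n_perm %||% NA_integer_,
    p = x$p %||% NA_real_
  )
}

#' Null distribution plot for a circular-shift ISC test
#' @param object An `isc_result` with a null distribution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isc_result
#' @export
autoplot.isc_result <- function(object, ...) {
  if (is.null(object$null_distribution)) {
    stop("autoplot.isc_result(): no null distribution; run circular_shift_null()",
         call. = FALSE)
  }
  df <- tibble::tibble(z = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_z, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "surrogate mean Fisher z", y = "count",
                  title = sprintf("Circular-shift null (p = %.4g)", object$p))
}

#' Tidy a spectral fit into its peak table
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return The peaks tibble (`center`, `height`, `width`).
#' @method tidy spectral_fit
#' @export
tidy.spectral_fit <- function(x, ...) x$peaks

#' @rdname tidy.spectral_fit
#' @method glance spectral_fit
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(
    offset = unname(x$aperiodic["offset"]),
    exponent = unname(x$aperiodic["exponent"]),
    n_peaks = nrow(x$peaks),
    fit_error = x$fit_error
  )
}

#' Spectrum and model overlay for a spectral fit
#' @param object A `spectral_fit`.
#' @param ... Unused.
#' @return A ggplot object: flattened spectrum with fitted peaks.
#' @method autoplot spectral_fit
#' @export
autoplot.spectral_fit <- function(object, ...) {
  fl <- object$flattened
  model <- rep(0, nrow(fl))
  if (nrow(object$peaks)) {
    for (i in seq_len(nrow(object$peaks))) {
      model <- model + gaussian_eval(fl$freq, object$peaks$center[i],
                                     object$peaks$height[i],
                                     object$peaks$width[i])
    }
  }
  df <- tibble::tibble(freq = fl$freq, flattened = fl$power, model = model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$flattened), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)", y = "log10 power above aperiodic fit",
                  title = sprintf("Flattened spectrum (exponent %.2f)",
                                  object$aperiodic["exponent"]))
}

#' Line plot of a power spectrum
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "log10 power")
}

#' Tidy a sensor cluster test into a cluster table
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return Tibble with one row per cluster (`n_channels`, `channels`,
#'   `mass`, `p_corrected`, `peak_t`, `d`, `avg_r`, `significant`).
#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @rdname tidy.cluster_test
#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_perm = x$n_perm,
    t_crit = x$t_crit,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant %||% logical())
  )
}

#' Topographic scatter of a cluster test's t map
#'
#' Channels are drawn at their flat schematic positions, coloured by t,
#' with members of significant clusters outlined.
#'
#' @param object A `cluster_test`.
#' @param montage The montage the maps were computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_test
#' @export
autoplot.cluster_test <- function(object, montage = montage_1020(), ...) {
  df <- dplyr::left_join(object$stat_map,
                         montage[, c("label", "sx", "sy")],
                         by = c(channel = "label"))
  sig_ch <- unlist(object$clusters$channels[object$clusters$significant])
  df$in_cluster <- df$channel %in% sig_ch
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sx, y = .data$sy)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), size = 5) +
    ggplot2::geom_point(data = df[df$in_cluster, ], shape = 21, size = 6,
                        stroke = 1.2, colour = "black", fill = NA) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2,
                       vjust = -1.6) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "t")
}

#' Trajectory line plot
#' @param object A `narousal_ts`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot narousal_ts
#' @export
autoplot.narousal_ts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "value")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
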