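# Approximate spherical montage for the extended 10-20 system. Positions
# are built from the standard 2D schematic (outer ring at 18 degree steps,
# inner rows interpolated between the ring and the midline) and projected
# onto the unit sphere. This reproduces the neighbourhood structure that
# the 0.4 chord-distance adjacency threshold expects; it is not a digitized
# head model.

ring_labels <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8",
                 "PO8", "O2", "Oz", "O1", "PO7", "P7", "TP7", "T7",
                 "FT7", "F7", "AF7", "Fp1")

schematic_positions <- function() {
  # outer ring: azimuth measured clockwise from the nasion (front)
  az <- seq(0, by = 18, length.out = 20) * pi / 180
  ring <- tibble::tibble(
    label = ring_labels,
    x = sin(az), y = cos(az)
  )
  midline <- tibble::tibble(
    label = c("AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz"),
    x = 0, y = c(0.75, 0.5, 0.25, 0, -0.25, -0.5, -0.75)
  )
  # inner rows interpolated between the lateral ring electrode and midline
  interp_row <- function(ring_label, mid_label, labels, fracs) {
    a <- ring[ring$label == ring_label, ]
    b <- midline[midline$label == mid_label, ]
    tibble::tibble(
      label = labels,
      x = a$x + fracs * (b$x - a$x),
      y = a$y + fracs * (b$y - a$y)
    )
  }
  rows <- dplyr::bind_rows(
    interp_row("AF7", "AFz", "AF3", 0.5),
    interp_row("AF8", "AFz", "AF4", 0.5),
    interp_row("F7", "Fz", c("F5", "F3", "F1"), c(0.25, 0.5, 0.75)),
    interp_row("F8", "Fz", c("F6", "F4", "F2"), c(0.25, 0.5, 0.75)),
    interp_row("FT7", "FCz", c("FC5", "FC3", "FC1"), c(0.25, 0.5, 0.75)),
    interp_row("FT8", "FCz", c("FC6", "FC4", "FC2"), c(0.25, 0.5, 0.75)),
    interp_row("T7", "Cz", c("C5", "C3", "C1"), c(0.25, 0.5, 0.75)),
    interp_row("T8", "Cz", c("C6", "C4", "C2"), c(0.25, 0.5, 0.75)),
    interp_row("TP7", "CPz", c("CP5", "CP3", "CP1"), c(0.25, 0.5, 0.75)),
    interp_row("TP8", "CPz", c("CP6", "CP4", "CP2"), c(0.25, 0.5, 0.75)),
    interp_row("P7", "Pz", c("P5", "P3", "P1"), c(0.25, 0.5, 0.75)),
    interp_row("P8", "Pz", c("P6", "P4", "P2"), c(0.25, 0.5, 0.75)),
    interp_row("PO7", "POz", "PO3", 0.5),
    interp_row("PO8", "POz", "PO4", 0.5)
  )
  dplyr::bind_rows(ring, midline, rows)
}

montage_32_labels <- c(
  "Fp1", "Fp2", "AFz", "F7", "F3", "Fz", "F4", "F8",
  "FC3", "FCz", "FC4", "T7", "C3", "Cz", "C4", "T8",
  "CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2"
)

#' Standard 10-20 style montage on the unit sphere
#'
#' Builds an approximate spherical montage (10-20/10-10 naming) used for
#' EEG synthesis, spatial adjacency and region grouping. `n_channels = 32`
#' selects a standard subset that retains the full posterior row
#' (PO7/PO3/POz/PO4/PO8, O1/Oz/O2); `n_channels = 61` returns the full
#' extended grid.
#'
#' @param n_channels Either 32 or 61.
#' @return Tibble with columns `label`, `x`, `y`, `z` (unit-sphere
#'   coordinates) and `sx`, `sy` (flat schematic coordinates for plotting).
#' @export
montage_1020 <- function(n_channels = 32) {
  flat <- schematic_positions()
  if (n_channels == 32) {
    flat <- flat[match(montage_32_labels, flat$label), ]
  } else if (n_channels != 61) {
    stop("montage_1020(): n_channels must be 32 or 61", call. = FALSE)
  }
  stopifnot(!anyNA(flat$label), !any(duplicated(flat$label)))
  r <- sqrt(flat$x^2 + flat$y^2)
  theta <- pmin(r, 1) * pi / 2          # inclination from the vertex
  phi <- atan2(flat$x, flat$y)          # azimuth from the nasion
  tibble::tibble(
    label = flat$label,
    x = sin(theta) * sin(phi),
    y = sin(theta) * cos(phi),
    z = cos(theta),
    sx = flat$x, sy = flat$y
  )
}

#' Region channel sets
#'
#' Named channel groups used for pooled spectra and cluster-table labels.
#' The occipital and fronto-central sets follow the standard
#' parieto-occipital / frontal pooling convention; labels absent from the
#' montage are dropped silently.
#'
#' @param montage A montage tibble.
#' @return Named list of character vectors of channel labels.
#' @export
region_sets <- function(montage = montage_1020()) {
  occ <- c("PO3", "PO4", "PO7", "PO8", "POz", "O1", "O2", "Oz")
  fc <- c("Fpz", "Fp1", "Fp2", "AFz", "AF3", "AF4", "AF7", "AF8",
          "Fz", paste0("F", 1:8), "FCz", paste0("FC", 1:8),
          "Cz", paste0("C", 1:8))
  post <- c(occ, "P3", "P4", "P7", "P8", "Pz", "P1", "P2", "P5", "P6",
            "CP3", "CP4", "CPz")
  keep <- function(x) intersect(x, montage$label)
  list(
    occipital = keep(occ),
    fronto_central = keep(fc),
    posterior = keep(post)
  )
}
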