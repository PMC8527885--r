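#' Quantification configuration
#'
#' Parameters of the per-section spatial metrics: the imaging-field window
#' used for the field-maximum density, the adherence distance to the
#' epithelium, and the geometry of the volumetric microscopic-biofilm
#' criterion.
#'
#' @param window_um Side of the square counting window (one imaging field),
#'   microns.
#' @param adherence_distance_um Maximum distance from the epithelial border
#'   at which a bacterium counts as adherent (inclusive boundary).
#' @param section_thickness_um Physical thickness of the histological
#'   section, used to turn the 2D field-maximum count into a volumetric
#'   density. No imaging-protocol value is published for this conversion;
#'   the default is a typical 5-um section and is fully configurable.
#' @param biofilm_density_threshold_per_ml Volumetric density above which
#'   (strictly) a section carries a microscopic biofilm; the literature
#'   criterion is 1e9 bacteria per mL of invaded mucus.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(window_um = 144.72, adherence_distance_um = 3.0,
                         section_thickness_um = 5.0,
                         biofilm_density_threshold_per_ml = 1e9) {
  stopifnot(window_um > 0, adherence_distance_um > 0,
            section_thickness_um > 0, biofilm_density_threshold_per_ml > 0)
  structure(list(window_um = window_um,
                 adherence_distance_um = adherence_distance_um,
                 section_thickness_um = section_thickness_um,
                 biofilm_density_threshold_per_ml =
                   biofilm_density_threshold_per_ml),
            class = "quant_config")
}

#' Maximum per-field bacterial count
#'
#' Partitions the plane into non-overlapping `window_um` tiles anchored at
#' the origin (half-open: a point on a tile's upper/left boundary belongs to
#' that tile; partial edge tiles count like any other) and returns the
#' largest per-tile centroid count. With `sliding = TRUE` the maximum is
#' instead taken over all window placements (brute force over the offsets
#' that matter), which can only be larger.
#'
#' @param detections Data frame with `x_um`, `y_um`.
#' @param window_um Window side in microns.
#' @param sliding Use a sliding window instead of the fixed partition.
#' @return Integer count (0 for no detections).
#' @export
max_window_count <- function(detections, window_um = 144.72,
                             sliding = FALSE) {
  stopifnot(window_um > 0)
  n <- nrow(detections)
  if (n == 0) return(0L)
  x <- detections$x_um; y <- detections$y_um
  if (!sliding) {
    tile <- paste(floor(x / window_um), floor(y / window_um))
    return(max(tabulate(factor(tile))))
  }
  # sliding: only window origins at (xi, yj) - window_um + 0 need checking;
  # equivalently anchor the window's left/top edge at each point.
  best <- 0L
  for (i in seq_len(n)) {
    inx <- x >= x[i] & x < x[i] + window_um
    yy <- y[inx]
    yy <- sort(yy)
    # count points within a window_um span of y, anchored at each point
    for (a in yy) {
      cnt <- sum(yy >= a & yy < a + window_um)
      if (cnt > best) best <- cnt
    }
  }
  as.integer(best)
}

#' Count epithelium-adherent bacteria
#'
#' Bacteria whose minimum Euclidean distance to the epithelial polyline is
#' at most `distance_um` ("within" read inclusively).
#'
#' @param detections Data frame with `x_um`, `y_um`.
#' @param trace An [epithelium_trace()].
#' @param distance_um Adherence distance in microns.
#' @return Integer count.
#' @export
count_adherent <- function(detections, trace, distance_um = 3.0) {
  stopifnot(distance_um > 0)
  if (nrow(detections) == 0) return(0L)
  d <- dist_to_trace(detections$x_um, detections$y_um, trace)
  sum(d <= distance_um)
}

#' Volumetric bacterial density of a counting field
#'
#' Converts a per-field 2D count into bacteria per mL by dividing by the
#' field volume `window_um^2 * thickness_um` (1 um^3 = 1e-12 mL). At the
#' default 144.72-um field and 5-um thickness the volume is ~104,719 um^3,
#' so the 1e9/mL criterion sits at ~104.7 bacteria per field.
#'
#' @param count Non-negative bacterial count.
#' @param window_um Field side, microns.
#' @param thickness_um Section thickness, microns.
#' @return Density in bacteria per mL.
#' @export
volumetric_density <- function(count, window_um = 144.72,
                               thickness_um = 5.0) {
  if (window_um <= 0 || thickness_um <= 0)
    stop("field geometry must be positive")
  stopifnot(count >= 0)
  count / (window_um^2 * thickness_um * 1e-12)
}

#' Microscopic-biofilm call from volumetric density
#'
#' Strictly greater than the threshold (default 1e9 bacteria/mL, the
#' published density defining bacterial invasion of the mucus layer).
#'
#' @param density_per_ml Non-negative density.
#' @param threshold_per_ml Criterion threshold.
#' @return Logical.
#' @export
classify_microscopic_biofilm <- function(density_per_ml,
                                         threshold_per_ml = 1e9) {
  stopifnot(all(density_per_ml >= 0))
  density_per_ml > threshold_per_ml
}

#' Surface-layer height summaries
#'
#' @param profile Data frame with `height_um` (or a bare numeric vector) of
#'   per-column surface-layer heights.
#' @return A list with `max_um` and `mean_um`.
#' @export
layer_heights <- function(profile) {
  h <- if (is.data.frame(profile)) profile$height_um else profile
  if (length(h) == 0) stop("empty layer profile")
  stopifnot(all(h >= 0))
  list(max_um = max(h), mean_um = mean(h))
}

#' Per-section biofilm metrics
#'
#' Assembles every per-section quantity: total and epithelium-adherent
#' counts with per-mm-of-epithelium rates, the field-maximum count and its
#' volumetric density, the microscopic-biofilm call, and surface-layer
#' height summaries.
#'
#' @param detections Data frame with `x_um`, `y_um`.
#' @param trace An [epithelium_trace()] (must have positive arc length).
#' @param profile Optional layer profile (data frame with `height_um`);
#'   `NULL` leaves the height fields `NA`.
#' @param cfg A [quant_config()].
#' @return One-row data frame of class `section_metrics` with columns
#'   `total_count`, `epithelium_length_um`, `total_per_mm`,
#'   `adherent_count`, `adherent_per_mm`, `max_window_count`,
#'   `max_density_per_ml`, `layer_max_um`, `layer_mean_um`,
#'   `is_microscopic_biofilm`.
#' @export
section_metrics <- function(detections, trace, profile = NULL,
                            cfg = quant_config()) {
  stopifnot(inherits(trace, "epithelium_trace"),
            inherits(cfg, "quant_config"))
  len <- trace$length_um
  if (len <= 0) stop("zero epithelium length: normalization undefined")
  total <- nrow(detections)
  adherent <- count_adherent(detections, trace, cfg$adherence_distance_um)
  mwc <- max_window_count(detections, cfg$window_um)
  dens <- volumetric_density(mwc, cfg$window_um, cfg$section_thickness_um)
  if (!is.null(profile)) {
    lh <- layer_heights(profile)
  } else {
    lh <- list(max_um = NA_real_, mean_um = NA_real_)
  }
  out <- data.frame(
    total_count = as.integer(total),
    epithelium_length_um = len,
    total_per_mm = total / (len / 1000),
    adherent_count = as.integer(adherent),
    adherent_per_mm = adherent / (len / 1000),
    max_window_count = as.integer(mwc),
    max_density_per_ml = dens,
    layer_max_um = lh$max_um,
    layer_mean_um = lh$mean_um,
    is_microscopic_biofilm =
      classify_microscopic_biofilm(dens,
                                   cfg$biofilm_density_threshold_per_ml))
  class(out) <- c("section_metrics", "data.frame")
  out
}
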