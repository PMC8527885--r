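#' Configuration for a synthetic confocal section
#'
#' Describes how a single-channel, DAPI-like confocal section of an
#' intestinal biopsy is simulated: a horizontal strip of `n_fields`
#' contiguous square imaging fields with the epithelial border running as a
#' smooth polyline along the lower edge. Biofilm-positive (`"BF+"`) sections
#' carry `fold_change` times more bacteria than biofilm-negative (`"BF-"`)
#' ones, and most of them concentrate in a band directly adjacent to the
#' epithelium; `"BF-"` bacteria stay scattered beyond an intact mucus layer
#' of width `mucus_gap_um`.
#'
#' @param field_size_um Side length of one square imaging field, in microns.
#' @param pixel_size_um Pixel size in microns. The default makes one field
#'   an effectively exact 1024 px.
#' @param n_fields Number of fields tiled horizontally.
#' @param bf_status `"BF+"` or `"BF-"`, the endoscopic biofilm status the
#'   section emulates.
#' @param mean_count_bfneg Expected bacteria per field in a `"BF-"` section
#'   (Poisson rate).
#' @param fold_change Multiplier on the per-field rate for `"BF+"` sections;
#'   must be >= 1.
#' @param adherent_band_um Width of the near-epithelium band in which `"BF+"`
#'   bacteria concentrate.
#' @param mucus_gap_um Minimum standoff of `"BF-"` bacteria from the
#'   epithelium (the intact mucus layer).
#' @param adherent_fraction Fraction of `"BF+"` bacteria placed inside the
#'   adherent band (the rest are scattered more distally).
#' @param psf_sigma_um Gaussian sigma of a rendered bacterial spot.
#' @param background_level,peak_intensity Background and spot peak intensity
#'   on the arbitrary [0, 1] intensity scale.
#' @param noise `"poisson"` for shot noise, `"none"` for a clean rendering.
#' @param photons_per_unit Photon count corresponding to intensity 1.0; sets
#'   the Poisson noise level.
#' @param layer_amp_um Peak height of the simulated surface (mucus/bacteria)
#'   layer, in microns. `NULL` picks a status-dependent default (40 for
#'   `"BF+"`, 12 for `"BF-"`), so positive sections have visibly taller
#'   layers.
#' @param layer_shape `"bumpy"` for a smooth multi-bump profile normalised to
#'   peak at `layer_amp_um`, `"constant"` for a flat profile.
#' @param seed Integer seed; identical config + seed reproduces the section
#'   exactly.
#' @return An object of class `section_sim_config` (a validated list).
#' @seealso [simulate_section()], [simulate_layer_profile()]
#' @export
section_sim_config <- function(field_size_um = 144.72,
                               pixel_size_um = 0.14133,
                               n_fields = 1L,
                               bf_status = c("BF+", "BF-"),
                               mean_count_bfneg = 12,
                               fold_change = 10,
                               adherent_band_um = 15,
                               mucus_gap_um = 30,
                               adherent_fraction = 0.9,
                               psf_sigma_um = 0.5,
                               background_level = 0.05,
                               peak_intensity = 0.6,
                               noise = c("poisson", "none"),
                               photons_per_unit = 200,
                               layer_amp_um = NULL,
                               layer_shape = c("bumpy", "constant"),
                               seed = NULL) {
  bf_status <- match.arg(bf_status)
  noise <- match.arg(noise)
  layer_shape <- match.arg(layer_shape)
  stopifnot(field_size_um > 0, pixel_size_um > 0, n_fields >= 1,
            mean_count_bfneg >= 0, fold_change >= 1,
            adherent_band_um > 0, mucus_gap_um > 0,
            adherent_fraction >= 0, adherent_fraction <= 1,
            psf_sigma_um > 0, background_level >= 0, peak_intensity >= 0,
            photons_per_unit > 0)
  ratio <- field_size_um / pixel_size_um
  if (abs(ratio - round(ratio)) > 0.5)
    stop("field_size_um must be an integer number of pixels (within 0.5 px)")
  if (is.null(layer_amp_um))
    layer_amp_um <- if (bf_status == "BF+") 40 else 12
  stopifnot(layer_amp_um >= 0)
  cfg <- list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
              n_fields = as.integer(n_fields), bf_status = bf_status,
              mean_count_bfneg = mean_count_bfneg, fold_change = fold_change,
              adherent_band_um = adherent_band_um, mucus_gap_um = mucus_gap_um,
              adherent_fraction = adherent_fraction,
              psf_sigma_um = psf_sigma_um,
              background_level = background_level,
              peak_intensity = peak_intensity, noise = noise,
              photons_per_unit = photons_per_unit,
              layer_amp_um = layer_amp_um, layer_shape = layer_shape,
              seed = seed)
  class(cfg) <- "section_sim_config"
  cfg
}

# Smooth epithelial border along the lower image edge: a gentle sum of
# incommensurate sinusoids with random phases, ~12 um above the bottom.
.sim_epithelium <- function(width_um, height_um) {
  xs <- seq(0, width_um, by = 2)
  if (xs[length(xs)] < width_um) xs <- c(xs, width_um)
  ph <- stats::runif(3, 0, 2 * pi)
  y <- height_um - 12 + 5 * (0.50 * sin(2 * pi * xs / 313 + ph[1]) +
                             0.35 * sin(2 * pi * xs / 171 + ph[2]) +
                             0.15 * sin(2 * pi * xs / 88  + ph[3]))
  epithelium_trace(xs, y)
}

# Surface-layer height per image column (no re-seeding; callers manage RNG).
.sim_profile <- function(cfg, xs) {
  if (cfg$layer_shape == "constant" || cfg$layer_amp_um == 0) {
    h <- rep(cfg$layer_amp_um, length(xs))
  } else {
    width <- max(xs)
    centers <- stats::runif(4, 0, width)
    widths <- stats::runif(4, 20, 60)
    amps <- stats::runif(4, 0.3, 1)
    s <- rep(0.05, length(xs))
    for (j in seq_len(4))
      s <- s + amps[j] * exp(-(xs - centers[j])^2 / (2 * widths[j]^2))
    h <- cfg$layer_amp_um * s / max(s)
  }
  data.frame(x_um = xs, height_um = h)
}

#' Simulate a surface-layer height profile
#'
#' Per-column height (in microns) of the mucus/bacteria surface layer sitting
#' on the epithelium, as measured on bright-field sections. Profiles are
#' smooth non-negative bump mixtures normalised so their maximum equals
#' `layer_amp_um`; consequently `"BF+"` sections (default amplitude 40)
#' always peak higher than `"BF-"` ones (default 12).
#'
#' @param cfg A [section_sim_config()].
#' @param width_um Width to cover; defaults to the full section width.
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return A data frame with columns `x_um` and `height_um`.
#' @export
simulate_layer_profile <- function(cfg, width_um = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "section_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(width_um)) width_um <- cfg$field_size_um * cfg$n_fields
  px <- cfg$pixel_size_um
  n_col <- round(width_um / px)
  xs <- (seq_len(n_col) - 0.5) * px
  .sim_profile(cfg, xs)
}

#' Simulate a confocal section with ground truth
#'
#' Generates one synthetic DAPI-like section: per-field bacterial counts are
#' Poisson with rate `mean_count_bfneg` (times `fold_change` for `"BF+"`),
#' `"BF+"` bacteria are concentrated within `adherent_band_um` of the
#' epithelial border while `"BF-"` bacteria keep a `mucus_gap_um` standoff,
#' and each bacterium is rendered as a Gaussian spot of sigma `psf_sigma_um`
#' plus optional Poisson shot noise.
#'
#' Coordinates are continuous microns with the origin at the top-left pixel
#' corner; pixel `i` is centred at `(i - 0.5) * pixel_size_um`.
#'
#' @param cfg A [section_sim_config()].
#' @param render If `FALSE`, skip rendering the intensity image (much faster
#'   when only ground-truth geometry and counts are needed).
#' @return A list with elements `section` (a `confocal_section`, or `NULL`
#'   when `render = FALSE`) and `truth`: a list with `centroids`
#'   (data frame `x_um`, `y_um`), `epithelium` (an [epithelium_trace()]),
#'   `layer_profile` (data frame `x_um`, `height_um`) and `bf_status`.
#' @examples
#' sim <- simulate_section(section_sim_config(pixel_size_um = 144.72 / 256,
#'                                            seed = 1))
#' nrow(sim$truth$centroids)
#' @export
simulate_section <- function(cfg, render = TRUE) {
  stopifnot(inherits(cfg, "section_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  px <- cfg$pixel_size_um
  field_px <- round(cfg$field_size_um / px)
  w_px <- field_px * cfg$n_fields
  h_px <- field_px
  w_um <- w_px * px
  h_um <- h_px * px

  epi <- .sim_epithelium(w_um, h_um)

  rate <- cfg$mean_count_bfneg *
    if (cfg$bf_status == "BF+") cfg$fold_change else 1
  counts <- stats::rpois(cfg$n_fields, rate)
  n <- sum(counts)
  if (n > 0) {
    field0 <- rep(seq_len(cfg$n_fields) - 1L, counts)
    x <- field0 * cfg$field_size_um +
      stats::runif(n, 0, cfg$field_size_um)
    x <- pmin(x, w_um - px)
    y_epi <- stats::approx(epi$x_um, epi$y_um, xout = x, rule = 2)$y
    if (cfg$bf_status == "BF+") {
      band <- cfg$adherent_band_um
      adherent <- stats::runif(n) < cfg$adherent_fraction
      d <- numeric(n)
      d[adherent] <- stats::runif(sum(adherent), 0.5, band - 0.5)
      hi <- pmax(band + 2, y_epi[!adherent] - 2)
      d[!adherent] <- stats::runif(sum(!adherent), band + 1, hi)
      y <- y_epi - d
    } else {
      d <- stats::runif(n, cfg$mucus_gap_um, pmax(cfg$mucus_gap_um + 1,
                                                  y_epi - 2))
      y <- y_epi - d
    }
    y <- pmin(pmax(y, px), h_um - px)
    centroids <- data.frame(x_um = x, y_um = y)
  } else {
    centroids <- data.frame(x_um = numeric(0), y_um = numeric(0))
  }

  xs_col <- (seq_len(w_px) - 0.5) * px
  profile <- .sim_profile(cfg, xs_col)

  section <- NULL
  if (render) {
    img <- matrix(cfg$background_level, nrow = h_px, ncol = w_px)
    if (n > 0)
      img <- .render_spots(img, centroids, px, cfg$psf_sigma_um,
                           cfg$peak_intensity)
    if (cfg$noise == "poisson") {
      k <- cfg$photons_per_unit
      img <- matrix(stats::rpois(length(img), img * k) / k,
                    nrow = h_px, ncol = w_px)
    }
    img <- pmin(img, 1)
    section <- confocal_section(img, px)
  }

  list(section = section,
       truth = list(centroids = centroids, epithelium = epi,
                    layer_profile = profile, bf_status = cfg$bf_status))
}

# Additively render Gaussian spots over local +-4 sigma windows.
.render_spots <- function(img, centroids, px, sigma_um, peak) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma_um / px)
  for (j in seq_len(nrow(centroids))) {
    x0 <- centroids$x_um[j]; y0 <- centroids$y_um[j]
    ci <- ceiling(x0 / px); ri <- ceiling(y0 / px)
    cols <- max(1, ci - half):min(w, ci + half)
    rows <- max(1, ri - half):min(h, ri + half)
    u <- (cols - 0.5) * px
    v <- (rows - 0.5) * px
    g <- peak * outer(exp(-(v - y0)^2 / (2 * sigma_um^2)),
                      exp(-(u - x0)^2 / (2 * sigma_um^2)))
    img[rows, cols] <- img[rows, cols] + g
  }
  img
}

#' Construct a confocal section object
#'
#' @param intensities Numeric matrix of non-negative intensities
#'   (rows = image rows, i.e. the y axis).
#' @param pixel_size_um Pixel size in microns.
#' @return An object of class `confocal_section`.
#' @export
confocal_section <- function(intensities, pixel_size_um) {
  stopifnot(is.matrix(intensities), is.numeric(intensities),
            pixel_size_um > 0, all(intensities >= 0))
  structure(list(intensities = intensities,
                 pixel_size_um = pixel_size_um,
                 width_px = ncol(intensities),
                 height_px = nrow(intensities)),
            class = "confocal_section")
}

#' @export
print.confocal_section <- function(x, ...) {
  cat(sprintf("confocal_section: %d x %d px, %.5f um/px (%.1f x %.1f um)\n",
              x$width_px, x$height_px, x$pixel_size_um,
              x$width_px * x$pixel_size_um, x$height_px * x$pixel_size_um))
  invisible(x)
}

#' Write a section to a 16-bit TIFF with a pixel-size sidecar
#'
#' Intensities are clipped to [0, 1], quantised to 16 bits (so a
#' write-then-read round trip reproduces the stored grid exactly) and
#' written as a single-channel TIFF. Pixel size and dimensions go to a YAML
#' sidecar `<path>.yaml`, the structured-text metadata that [read_section()]
#' consumes.
#'
#' @param section A `confocal_section`.
#' @param path Output TIFF path.
#' @param sidecar Write the YAML sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path, sidecar = TRUE) {
  stopifnot(inherits(section, "confocal_section"))
  img <- pmin(pmax(section$intensities, 0), 1)
  img <- round(img * 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  if (sidecar)
    yaml::write_yaml(list(pixel_size_um = section$pixel_size_um,
                          width_px = section$width_px,
                          height_px = section$height_px),
                     paste0(path, ".yaml"))
  invisible(path)
}

#' Write ground truth tables to CSV
#'
#' Centroids (`x_um,y_um`), epithelium vertices (`x_um,y_um`) and the layer
#' profile (`x_um,height_um`) as three CSV files with a common stem.
#'
#' @param truth The `truth` element returned by [simulate_section()].
#' @param stem Path stem; files are `<stem>_centroids.csv`,
#'   `<stem>_epithelium.csv`, `<stem>_profile.csv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  paths <- c(centroids = paste0(stem, "_centroids.csv"),
             epithelium = paste0(stem, "_epithelium.csv"),
             profile = paste0(stem, "_profile.csv"))
  utils::write.csv(truth$centroids, paths["centroids"], row.names = FALSE)
  utils::write.csv(data.frame(x_um = truth$epithelium$x_um,
                              y_um = truth$epithelium$y_um),
                   paths["epithelium"], row.names = FALSE)
  utils::write.csv(truth$layer_profile, paths["profile"], row.names = FALSE)
  invisible(paths)
}
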