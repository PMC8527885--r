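#' Read a confocal section from TIFF
#'
#' Pixel size is taken from the YAML sidecar written by [write_section()]
#' (`<path>.yaml`), or from `pixel_size_um` when no sidecar exists; with
#' neither, this is a metadata error.
#'
#' @param path TIFF path.
#' @param pixel_size_um Optional pixel-size override in microns.
#' @return A [confocal_section()].
#' @export
read_section <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("unreadable TIFF: ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  sidecar <- paste0(path, ".yaml")
  px <- NULL
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    px <- meta$pixel_size_um
  }
  if (is.null(px)) px <- pixel_size_um
  if (is.null(px))
    stop("pixel size absent from metadata; pass pixel_size_um explicitly")
  confocal_section(img, px)
}

#' Spot-detector parameters
#'
#' Tunables of the multiscale Laplacian-of-Gaussian (LoG) blob detector that
#' stands in for a learned bacteria detector.
#'
#' @param spot_sigma_um Expected spot sigma in microns (the detector also
#'   probes 0.8x and 1.25x this scale).
#' @param min_separation_um Minimum centre-to-centre distance between
#'   reported detections; closer candidates are suppressed in favour of the
#'   stronger response.
#' @param response_threshold Minimum LoG response, as a fraction of the image
#'   dynamic range. The kernels are calibrated so a scale-matched Gaussian
#'   spot of unit amplitude yields a response of 0.5.
#' @param min_intensity_quantile Candidate peaks must exceed this quantile of
#'   a robust background model (median + z * MAD of the image).
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(spot_sigma_um = 0.5, min_separation_um = 1.0,
                            response_threshold = 0.1,
                            min_intensity_quantile = 0.99) {
  stopifnot(spot_sigma_um > 0, min_separation_um > 0,
            response_threshold > 0, response_threshold < 1,
            min_intensity_quantile > 0, min_intensity_quantile < 1)
  structure(list(spot_sigma_um = spot_sigma_um,
                 min_separation_um = min_separation_um,
                 response_threshold = response_threshold,
                 min_intensity_quantile = min_intensity_quantile),
            class = "detector_params")
}

# Zero-mean LoG kernel at sigma (px), sign-flipped so bright blobs respond
# positively, and self-calibrated: response to a matched unit-amplitude
# Gaussian equals 0.5 (the analytic scale-normalised LoG optimum).
.log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  u <- (-half):half
  r2 <- outer(u^2, u^2, "+")
  k <- (2 * sigma_px^2 - r2) * exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k)
  cal <- sum(k * exp(-r2 / (2 * sigma_px^2)))
  k / cal * 0.5
}

#' Detect bacterial spots in a section
#'
#' Deterministic multiscale LoG blob detection: the image is convolved with
#' self-calibrated LoG kernels at three scales around `spot_sigma_um`, local
#' maxima of the per-pixel maximum response are thresholded on response
#' (relative to the image dynamic range) and on raw intensity (against a
#' median + MAD background model), and surviving candidates are greedily
#' pruned so no two detections lie closer than `min_separation_um`.
#'
#' @param section A [confocal_section()].
#' @param params A [detector_params()].
#' @return A data frame of class `detections` with columns `x_um`, `y_um`,
#'   `score`, sorted by decreasing score. Constant (featureless) images
#'   yield zero rows.
#' @export
detect_spots <- function(section, params = detector_params()) {
  stopifnot(inherits(section, "confocal_section"))
  if (!inherits(params, "detector_params"))
    stop("params must be a detector_params object")
  img <- section$intensities
  px <- section$pixel_size_um
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      score = numeric(0))
  class(empty) <- c("detections", "data.frame")
  rng <- range(img)
  if (diff(rng) == 0) return(empty)

  sigma_px <- params$spot_sigma_um / px
  resp <- NULL
  for (s in sigma_px * c(0.8, 1, 1.25)) {
    r <- EBImage::filter2(img, .log_kernel(s), boundary = "replicate")
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }

  h <- nrow(img); w <- ncol(img)
  core <- resp[2:(h - 1), 2:(w - 1)]
  is_max <- core >= resp[1:(h - 2), 2:(w - 1)] &
            core >= resp[3:h,       2:(w - 1)] &
            core >= resp[2:(h - 1), 1:(w - 2)] &
            core >= resp[2:(h - 1), 3:w] &
            core >= resp[1:(h - 2), 1:(w - 2)] &
            core >= resp[1:(h - 2), 3:w] &
            core >= resp[3:h,       1:(w - 2)] &
            core >= resp[3:h,       3:w]

  thr <- max(params$response_threshold * diff(rng), 1e-12)
  bg_cut <- stats::median(img) +
    stats::qnorm(params$min_intensity_quantile) * stats::mad(img)
  keep <- is_max & core > thr & img[2:(h - 1), 2:(w - 1)] > bg_cut
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)

  rows <- idx[, 1] + 1L
  cols <- idx[, 2] + 1L
  score <- resp[cbind(rows, cols)]
  ord <- order(-score, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; score <- score[ord]
  x <- (cols - 0.5) * px
  y <- (rows - 0.5) * px

  # greedy non-maximum suppression by descending response
  min_sep2 <- params$min_separation_um^2
  n <- length(x)
  kept <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0 ||
        min((kx - x[i])^2 + (ky - y[i])^2) >= min_sep2) {
      kept[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  out <- data.frame(x_um = x[kept], y_um = y[kept], score = score[kept])
  class(out) <- c("detections", "data.frame")
  out
}

#' Score detections against ground-truth centroids
#'
#' Greedy one-to-one matching by ascending distance within `radius_um`:
#' each truth point and each detection is used at most once. With no
#' detections, precision is reported as 0 by convention.
#'
#' @param detections Data frame with `x_um`, `y_um` (e.g. from
#'   [detect_spots()]).
#' @param truth Data frame of true centroids with `x_um`, `y_um`.
#' @param radius_um Matching radius in microns.
#' @return A list with `precision`, `recall`, `f1`, `n_matched`.
#' @export
evaluate_detections <- function(detections, truth, radius_um = 1) {
  stopifnot(radius_um > 0)
  nd <- nrow(detections); nt <- nrow(truth)
  n_matched <- 0L
  if (nd > 0 && nt > 0) {
    d2 <- outer(detections$x_um, truth$x_um, "-")^2 +
          outer(detections$y_um, truth$y_um, "-")^2
    cand <- which(d2 <= radius_um^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ti <- cand[i, 2]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  precision <- if (nd > 0) n_matched / nd else 0
  recall <- if (nt > 0) n_matched / nt else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_matched)
}

#' Write detections to CSV
#'
#' @param detections Output of [detect_spots()].
#' @param path CSV path (columns `x_um,y_um,score`).
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(as.data.frame(detections)[c("x_um", "y_um", "score")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV
#' @param path CSV path with columns `x_um,y_um` (optionally `score`).
#' @return A `detections` data frame.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(df)))
  if (is.null(df$score)) df$score <- NA_real_
  class(df) <- c("detections", "data.frame")
  df
}
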