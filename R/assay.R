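#' Assay scoring configuration
#'
#' @param former_threshold OD595/OD600 ratio above which (strictly) a
#'   strain is a biofilm former (default 5).
#' @param aggregation Replicate aggregation of per-well ratios: `"mean"`
#'   (default) or `"median"`.
#' @param blank_od595 Optional blank OD595 subtracted from every well
#'   before the ratio (default 0, i.e. off).
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(former_threshold = 5.0,
                         aggregation = c("mean", "median"),
                         blank_od595 = 0) {
  aggregation <- match.arg(aggregation)
  stopifnot(former_threshold > 0, blank_od595 >= 0)
  structure(list(former_threshold = former_threshold,
                 aggregation = aggregation, blank_od595 = blank_od595),
            class = "assay_config")
}

#' Score one strain's assay wells
#'
#' The OD595/OD600 ratio is computed per well and then aggregated across
#' replicates (the per-well ratio is the plotted assay quantity). Wells
#' with OD600 = 0 are dropped with a warning; the replicate SD is `NA` for
#' a single well.
#'
#' @param wells Data frame with `od595`, `od600` (and optionally
#'   `strain_id`) for one strain.
#' @param cfg An [assay_config()].
#' @return A list `strain_id`, `mean_ratio`, `sd_ratio`, `n`, `is_former`.
#' @export
score_strain <- function(wells, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"),
            all(c("od595", "od600") %in% names(wells)))
  bad <- wells$od600 <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with non-positive OD600 dropped")
    wells <- wells[!bad, , drop = FALSE]
  }
  if (nrow(wells) == 0) stop("no usable wells for strain")
  ratio <- (wells$od595 - cfg$blank_od595) / wells$od600
  agg <- if (cfg$aggregation == "mean") mean(ratio) else
    stats::median(ratio)
  list(strain_id = if (!is.null(wells$strain_id)) wells$strain_id[1]
                   else NA_character_,
       mean_ratio = agg,
       sd_ratio = if (nrow(wells) > 1) stats::sd(ratio) else NA_real_,
       n = nrow(wells),
       is_former = classify_former(agg, cfg))
}

#' Classify a strain as biofilm former
#'
#' Strictly greater than the threshold ratio (the published ">5" rule).
#'
#' @param mean_ratio Aggregated OD595/OD600 ratio, >= 0.
#' @param cfg An [assay_config()].
#' @return Logical.
#' @export
classify_former <- function(mean_ratio, cfg = assay_config()) {
  stopifnot(all(mean_ratio >= 0))
  mean_ratio > cfg$former_threshold
}

#' Score a whole assay plate
#'
#' @param plate Data frame `strain_id`, `replicate`, `od595`, `od600`.
#' @param cfg An [assay_config()].
#' @return Data frame `strain_id`, `mean_ratio`, `sd_ratio`, `n`,
#'   `is_former`, one row per strain (in order of first appearance).
#' @export
score_plate <- function(plate, cfg = assay_config()) {
  stopifnot(all(c("strain_id", "od595", "od600") %in% names(plate)))
  ids <- unique(plate$strain_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- score_strain(plate[plate$strain_id == id, , drop = FALSE], cfg)
    data.frame(strain_id = id, mean_ratio = s$mean_ratio,
               sd_ratio = s$sd_ratio, n = s$n, is_former = s$is_former,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
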