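#' Canonical cohort and center labels
#' @keywords internal
.cohort_levels <- c("IBS", "UC", "Crohn", "post-transplant", "adenoma",
                    "portal-hypertension", "CRC", "diverticular",
                    "GI-bleeding", "other", "healthy-control")
.center_levels <- c("Austria", "Germany")
.segment_levels <- c("terminal ileum", "cecum", "ascending", "transverse",
                     "descending", "sigmoid", "rectum")

#' Default per-cohort, per-center cohort counts
#'
#' The analyzed per-cohort, per-center sample sizes and endoscopic biofilm
#' counts of the two-center (Austria/Germany) screening study that the
#' cohort simulator reproduces by default.
#'
#' @return Data frame with columns `cohort`, `center`, `bf_pos`, `total`.
#' @export
default_cohort_counts <- function() {
  data.frame(
    cohort = rep(c("IBS", "UC", "post-transplant", "Crohn", "other",
                   "adenoma", "portal-hypertension", "CRC", "diverticular",
                   "GI-bleeding", "healthy-control"), each = 2),
    center = rep(c("Austria", "Germany"), 11),
    bf_pos = c(52, 13, 30, 16, 6, 3, 10, 20, 7, 0,
               24, 2, 6, 2, 4, 0, 3, 1, 2, 1, 8, 2),
    total = c(86, 28, 102, 34, 28, 11, 82, 52, 49, 1,
              142, 66, 48, 19, 26, 13, 29, 63, 52, 26, 112, 43),
    stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Describes a simulated multicenter endoscopy cohort: per-cohort,
#' per-center sample sizes with biofilm prevalences (defaults are the
#' analyzed counts of the two-center screening study,
#' [default_cohort_counts()]), pre-exclusion quality fractions, the
#' R. gnavus bloom rates by biofilm status, and the rates at which the
#' volumetric microscopic-biofilm criterion is met by endoscopic status.
#'
#' @param counts Data frame `cohort`, `center`, `bf_pos`, `total`;
#'   prevalence per cell is `bf_pos / total`.
#' @param counts_are `"analyzed"` (default): `total` is the post-exclusion
#'   sample size and enrolment is inflated by
#'   1 / ((1-f_bbps)(1-f_prep)(1-f_cecum)) so the kept cohort matches it in
#'   expectation. `"enrolled"`: `total` records are generated and the
#'   exclusions thin them.
#' @param bloom_rate_bfpos,bloom_rate_bfneg Probability of an R. gnavus
#'   bloom given endoscopic biofilm status (defaults 0.51 / 0.18).
#' @param micro_rate_bfpos,micro_rate_bfneg Probability that the
#'   microscopic density criterion is met given status (defaults
#'   0.89 / 0.40).
#' @param frac_low_bbps,frac_nonpeg,frac_cecum_missed Independent
#'   pre-exclusion fractions of records with BBPS < 6, non-PEG preparation,
#'   and cecum not reached (defaults 0.1 each).
#' @param location_rates Named per-segment probabilities that a biofilm
#'   location set of a BF+ patient contains each colonic segment.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(counts = default_cohort_counts(),
                              counts_are = c("analyzed", "enrolled"),
                              bloom_rate_bfpos = 0.51,
                              bloom_rate_bfneg = 0.18,
                              micro_rate_bfpos = 0.89,
                              micro_rate_bfneg = 0.40,
                              frac_low_bbps = 0.1,
                              frac_nonpeg = 0.1,
                              frac_cecum_missed = 0.1,
                              location_rates = c(
                                "terminal ileum" = 0.71, cecum = 0.72,
                                ascending = 0.45, transverse = 0.18,
                                descending = 0.11, sigmoid = 0.08,
                                rectum = 0.06),
                              seed = NULL) {
  counts_are <- match.arg(counts_are)
  stopifnot(is.data.frame(counts),
            all(c("cohort", "center", "bf_pos", "total") %in% names(counts)),
            all(counts$bf_pos >= 0), all(counts$total >= counts$bf_pos))
  bad <- setdiff(counts$cohort, .cohort_levels)
  if (length(bad) > 0)
    stop("unknown cohort name(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(counts$center, .center_levels)
  if (length(bad) > 0)
    stop("unknown center name(s): ", paste(bad, collapse = ", "))
  rates <- c(bloom_rate_bfpos, bloom_rate_bfneg, micro_rate_bfpos,
             micro_rate_bfneg, frac_low_bbps, frac_nonpeg,
             frac_cecum_missed, location_rates)
  stopifnot(all(rates >= 0), all(rates <= 1),
            all(.segment_levels %in% names(location_rates)))
  structure(list(counts = counts, counts_are = counts_are,
                 bloom_rate_bfpos = bloom_rate_bfpos,
                 bloom_rate_bfneg = bloom_rate_bfneg,
                 micro_rate_bfpos = micro_rate_bfpos,
                 micro_rate_bfneg = micro_rate_bfneg,
                 frac_low_bbps = frac_low_bbps,
                 frac_nonpeg = frac_nonpeg,
                 frac_cecum_missed = frac_cecum_missed,
                 location_rates = location_rates, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a multicenter patient cohort
#'
#' One record per simulated endoscopy: center, cohort, a BBPS score
#' (integer 0-9, below 6 with probability `frac_low_bbps`), preparation
#' type, cecum-reached flag, endoscopic biofilm status drawn Bernoulli at
#' the configured per-cell prevalence, a multi-label biofilm location set
#' for BF+ records (guaranteed non-empty), an R. gnavus bloom flag and a
#' microscopic-biofilm flag at the status-conditional rates.
#'
#' @param cfg A [cohort_sim_config()].
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return A data frame of patient records (see [patient_record_columns()]);
#'   `biofilm_locations` is a `";"`-separated string, empty for BF-.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  keep_prob <- (1 - cfg$frac_low_bbps) * (1 - cfg$frac_nonpeg) *
    (1 - cfg$frac_cecum_missed)
  rows <- vector("list", nrow(cfg$counts))
  for (i in seq_len(nrow(cfg$counts))) {
    cell <- cfg$counts[i, ]
    if (cell$total == 0) next
    n <- if (cfg$counts_are == "analyzed")
      round(cell$total / keep_prob) else cell$total
    prev <- cell$bf_pos / cell$total
    bbps <- ifelse(stats::runif(n) < cfg$frac_low_bbps,
                   sample(0:5, n, replace = TRUE),
                   sample(6:9, n, replace = TRUE))
    status <- ifelse(stats::runif(n) < prev, "BF+", "BF-")
    bloom <- stats::runif(n) < ifelse(status == "BF+",
                                      cfg$bloom_rate_bfpos,
                                      cfg$bloom_rate_bfneg)
    micro <- stats::runif(n) < ifelse(status == "BF+",
                                      cfg$micro_rate_bfpos,
                                      cfg$micro_rate_bfneg)
    loc <- character(n)
    for (j in which(status == "BF+")) {
      hit <- stats::runif(length(cfg$location_rates)) < cfg$location_rates
      if (!any(hit)) hit[which.max(cfg$location_rates)] <- TRUE
      loc[j] <- paste(names(cfg$location_rates)[hit], collapse = ";")
    }
    rows[[i]] <- data.frame(
      patient_id = sprintf("%s-%s-%03d", substr(cell$center, 1, 2),
                           gsub("[^A-Za-z]", "", cell$cohort), seq_len(n)),
      center = cell$center, cohort = cell$cohort, bbps = bbps,
      prep_type = ifelse(stats::runif(n) < cfg$frac_nonpeg,
                         "non-PEG", "PEG"),
      cecum_reached = stats::runif(n) >= cfg$frac_cecum_missed,
      biofilm_status = status, biofilm_locations = loc,
      microscopic_biofilm = micro, bloom = bloom,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Expand aggregated prevalence counts into patient records
#'
#' Deterministically turns a `cohort`/`center`/`bf_pos`/`total` table into
#' one record per case (all passing the exclusion filters: BBPS 9, PEG
#' preparation, cecum reached), with the first `bf_pos` records of each
#' cell BF+. Useful for re-analysing published aggregate tables with the
#' record-level pipeline.
#'
#' @param counts Data frame `cohort`, `center`, `bf_pos`, `total`.
#' @return Patient-record data frame.
#' @export
cohort_from_counts <- function(counts = default_cohort_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cell <- counts[i, ]
    if (cell$total == 0) return(NULL)
    data.frame(
      patient_id = sprintf("%s-%s-%03d", substr(cell$center, 1, 2),
                           gsub("[^A-Za-z]", "", cell$cohort),
                           seq_len(cell$total)),
      center = cell$center, cohort = cell$cohort, bbps = 9L,
      prep_type = "PEG", cecum_reached = TRUE,
      biofilm_status = rep(c("BF+", "BF-"),
                           c(cell$bf_pos, cell$total - cell$bf_pos)),
      biofilm_locations = "", microscopic_biofilm = NA, bloom = NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Patient-record column names
#'
#' The documented header of the patient CSV consumed and produced by the
#' cohort functions.
#' @return Character vector of column names.
#' @export
patient_record_columns <- function() {
  c("patient_id", "center", "cohort", "bbps", "prep_type", "cecum_reached",
    "biofilm_status", "biofilm_locations", "microscopic_biofilm", "bloom")
}

#' Simulate a crystal-violet assay plate
#'
#' OD595 (crystal-violet stain) and OD600 (culture density) per well.
#' Planted biofilm-former strains have per-strain mean OD595/OD600 ratios
#' drawn uniformly in `former_ratio_range` (above the >5 classification
#' threshold), non-formers in `nonformer_ratio_range` (below it); replicate
#' ratios vary around the strain mean with 10% relative noise.
#'
#' @param n_strains Number of strains on the plate (default 15).
#' @param n_replicates Wells per strain (default 8).
#' @param former_fraction Fraction of strains planted as biofilm formers
#'   (default 6/15, the proportion of strong producers among the isolates
#'   the assay emulates).
#' @param former_ratio_range,nonformer_ratio_range Per-strain mean ratio
#'   ranges.
#' @param seed Integer seed.
#' @return A list: `plate` (data frame `strain_id`, `replicate`, `od595`,
#'   `od600`) and `truth` (data frame `strain_id`, `is_former`).
#' @export
simulate_assay_plate <- function(n_strains = 15, n_replicates = 8,
                                 former_fraction = 6 / 15,
                                 former_ratio_range = c(7, 14),
                                 nonformer_ratio_range = c(0.5, 3),
                                 seed = NULL) {
  stopifnot(n_strains >= 1, n_replicates >= 1,
            former_fraction >= 0, former_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_formers <- round(former_fraction * n_strains)
  is_former <- rep(c(TRUE, FALSE), c(n_formers, n_strains - n_formers))
  strain_mean <- ifelse(is_former,
                        stats::runif(n_strains, former_ratio_range[1],
                                     former_ratio_range[2]),
                        stats::runif(n_strains, nonformer_ratio_range[1],
                                     nonformer_ratio_range[2]))
  ids <- sprintf("strain_%02d", seq_len(n_strains))
  plate <- do.call(rbind, lapply(seq_len(n_strains), function(i) {
    od600 <- pmax(0.05, stats::rnorm(n_replicates, 0.5, 0.05))
    ratio <- pmax(0.01, stats::rnorm(n_replicates, strain_mean[i],
                                     0.1 * strain_mean[i]))
    data.frame(strain_id = ids[i], replicate = seq_len(n_replicates),
               od595 = ratio * od600, od600 = od600,
               stringsAsFactors = FALSE)
  }))
  rownames(plate) <- NULL
  list(plate = plate,
       truth = data.frame(strain_id = ids, is_former = is_former,
                          stringsAsFactors = FALSE))
}
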