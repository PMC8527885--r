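#' Exclusion rules for the screening cohort
#'
#' The study's inclusion filters: sufficient bowel preparation
#' (BBPS >= `min_bbps`), PEG-based preparation, and a completed colonoscopy
#' reaching the cecum.
#'
#' @param min_bbps Minimum Boston Bowel Preparation Scale score (default 6,
#'   inclusive).
#' @param require_peg Exclude non-PEG preparations (default `TRUE`).
#' @param require_cecum Exclude endoscopies not reaching the cecum
#'   (default `TRUE`).
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_bbps = 6, require_peg = TRUE,
                            require_cecum = TRUE) {
  stopifnot(min_bbps >= 0, min_bbps <= 9)
  structure(list(min_bbps = min_bbps, require_peg = require_peg,
                 require_cecum = require_cecum),
            class = "exclusion_rules")
}

#' Apply the exclusion rules to patient records
#'
#' A record is kept iff its BBPS is at least `min_bbps`, its preparation is
#' PEG (when required) and the cecum was reached (when required). Rules are
#' evaluated in that fixed order and each excluded record is logged with its
#' first failing rule.
#'
#' @param records Patient-record data frame (see
#'   [patient_record_columns()]).
#' @param rules An [exclusion_rules()].
#' @return A list with `kept` (data frame) and `excluded` (data frame with
#'   an extra `reason` column: `"bbps"`, `"prep"` or `"cecum"`).
#' @export
apply_exclusions <- function(records, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"),
            all(c("bbps", "prep_type", "cecum_reached") %in% names(records)))
  if (any(records$bbps < 0 | records$bbps > 9, na.rm = TRUE))
    warning("records with BBPS outside 0-9")
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$bbps < rules$min_bbps] <- "bbps"
  if (rules$require_peg)
    reason[is.na(reason) & records$prep_type != "PEG"] <- "prep"
  if (rules$require_cecum)
    reason[is.na(reason) & !records$cecum_reached] <- "cecum"
  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

# round half away from zero (the convention that reproduces every checkable
# published percentage)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-cohort biofilm prevalence table
#'
#' Counts of endoscopically biofilm-positive cases by cohort (and center),
#' with the percentage rounded to the nearest integer, half away from zero.
#' A row with `center = "all"` pools the centers, and `cohort = "all"` rows
#' give the overall prevalence.
#'
#' @param records Patient records (already filtered with
#'   [apply_exclusions()]).
#' @param by_center Also emit per-center rows (default `TRUE`).
#' @return Data frame `cohort`, `center`, `bf_pos`, `total`, `percent`
#'   (percent is `NA` for empty cells).
#' @export
prevalence_table <- function(records, by_center = TRUE) {
  stopifnot(all(c("cohort", "center", "biofilm_status") %in% names(records)))
  centers <- if (by_center) c("all", unique(records$center)) else "all"
  cohorts <- c(unique(records$cohort), "all")
  rows <- list()
  for (co in cohorts) {
    sub_co <- if (co == "all") records else
      records[records$cohort == co, , drop = FALSE]
    for (ce in centers) {
      sub <- if (ce == "all") sub_co else
        sub_co[sub_co$center == ce, , drop = FALSE]
      total <- nrow(sub)
      pos <- sum(sub$biofilm_status == "BF+")
      rows[[length(rows) + 1]] <- data.frame(
        cohort = co, center = ce, bf_pos = pos, total = total,
        percent = if (total > 0) .round_half_up(100 * pos / total)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cohort odds ratios versus a reference cohort
#'
#' Crude mode computes each cohort's 2x2 odds ratio against the reference
#' cohort with [odds_ratio_2x2()]. Adjusted mode fits a grouped-binomial
#' logistic regression with a center covariate via
#' [fit_grouped_logistic()], either pairwise (one fit per cohort vs the
#' reference, the default) or jointly (all cohorts in one model with the
#' reference as baseline).
#'
#' @param records Patient records.
#' @param reference_cohort Reference cohort label (default
#'   `"healthy-control"`); must contain both outcomes.
#' @param adjust_for_center Adjusted (logistic) instead of crude ORs.
#' @param model `"pairwise"` or `"joint"` (adjusted mode only).
#' @return Data frame `cohort`, `bf_pos`, `total`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `or_rounded` (1 decimal, the reporting convention),
#'   `adjusted`.
#' @export
or_report <- function(records, reference_cohort = "healthy-control",
                      adjust_for_center = FALSE,
                      model = c("pairwise", "joint")) {
  model <- match.arg(model)
  ref <- records[records$cohort == reference_cohort, , drop = FALSE]
  if (nrow(ref) == 0 || length(unique(ref$biofilm_status)) < 2)
    stop("degenerate reference cohort: needs both BF+ and BF- records")
  cohorts <- setdiff(unique(records$cohort), reference_cohort)
  cell <- function(sub) c(pos = sum(sub$biofilm_status == "BF+"),
                          neg = sum(sub$biofilm_status == "BF-"))
  res <- list()
  if (adjust_for_center && model == "joint") {
    records$cohort <- factor(records$cohort,
                             levels = c(reference_cohort, cohorts))
    agg <- stats::aggregate(
      cbind(pos = biofilm_status == "BF+", n = 1) ~ cohort + center,
      data = records, FUN = sum)
    X <- stats::model.matrix(~ cohort + center, data = agg)
    fit <- fit_grouped_logistic(X, agg$pos, agg$n)
    for (co in cohorts) {
      k <- paste0("cohort", co)
      cc <- cell(records[records$cohort == co, , drop = FALSE])
      res[[co]] <- data.frame(cohort = co, bf_pos = cc["pos"],
                              total = sum(cc),
                              odds_ratio = fit$odds_ratio[[k]],
                              ci_low = fit$ci_low[[k]],
                              ci_high = fit$ci_high[[k]])
    }
  } else {
    rc <- cell(ref)
    for (co in cohorts) {
      sub <- records[records$cohort == co, , drop = FALSE]
      cc <- cell(sub)
      if (adjust_for_center) {
        both <- rbind(sub, ref)
        agg <- stats::aggregate(
          cbind(pos = biofilm_status == "BF+", n = 1) ~ cohort + center,
          data = transform(both, cohort = factor(cohort,
            levels = c(reference_cohort, co))), FUN = sum)
        X <- stats::model.matrix(~ cohort + center, data = agg)
        fit <- fit_grouped_logistic(X, agg$pos, agg$n)
        k <- paste0("cohort", co)
        or <- fit$odds_ratio[[k]]
        lo <- fit$ci_low[[k]]; hi <- fit$ci_high[[k]]
      } else {
        orr <- odds_ratio_2x2(cc["pos"], cc["neg"], rc["pos"], rc["neg"])
        or <- orr$odds_ratio; lo <- orr$ci_low; hi <- orr$ci_high
      }
      res[[co]] <- data.frame(cohort = co, bf_pos = cc[["pos"]],
                              total = sum(cc), odds_ratio = or,
                              ci_low = lo, ci_high = hi)
    }
  }
  out <- do.call(rbind, res)
  out$or_rounded <- round(out$odds_ratio, 1)
  out$adjusted <- adjust_for_center
  rownames(out) <- NULL
  out
}

#' Biofilm location distribution
#'
#' For each colonic segment, the percentage of BF+ patients whose biofilm
#' location set contains it. Locations are multi-label, so percentages need
#' not sum to 100.
#'
#' @param records Patient records; `biofilm_locations` is a `";"`-separated
#'   string.
#' @return Data frame `segment`, `n`, `percent` (empty when there are no
#'   BF+ records).
#' @export
location_distribution <- function(records) {
  pos <- records[records$biofilm_status == "BF+", , drop = FALSE]
  if (nrow(pos) == 0)
    return(data.frame(segment = character(0), n = integer(0),
                      percent = numeric(0)))
  sets <- strsplit(pos$biofilm_locations, ";", fixed = TRUE)
  out <- data.frame(
    segment = .segment_levels,
    n = vapply(.segment_levels,
               function(s) sum(vapply(sets, function(v) s %in% v,
                                      logical(1))),
               integer(1)))
  out$percent <- 100 * out$n / nrow(pos)
  rownames(out) <- NULL
  out
}

#' Endoscopic vs microscopic biofilm concordance
#'
#' Builds the 2x2 confusion table between the endoscopic biofilm call
#' (prediction) and the microscopic density criterion (reference) and
#' summarises it with [confusion_metrics()]. Records missing either status
#' are skipped and counted.
#'
#' @param records Patient records with `biofilm_status` and
#'   `microscopic_biofilm`.
#' @return A list: `table` (named counts `tp`, `fn`, `fp`, `tn`), `metrics`
#'   (see [confusion_metrics()]), `n_skipped`.
#' @export
concordance_report <- function(records) {
  stopifnot(all(c("biofilm_status", "microscopic_biofilm") %in%
                  names(records)))
  ok <- !is.na(records$microscopic_biofilm) &
    records$biofilm_status %in% c("BF+", "BF-")
  sub <- records[ok, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records with both statuses")
  endo <- sub$biofilm_status == "BF+"
  micro <- sub$microscopic_biofilm
  tab <- c(tp = sum(endo & micro), fn = sum(!endo & micro),
           fp = sum(endo & !micro), tn = sum(!endo & !micro))
  list(table = tab,
       metrics = confusion_metrics(tab[["tp"]], tab[["fn"]], tab[["fp"]],
                                   tab[["tn"]]),
       n_skipped = sum(!ok))
}

#' Read / write patient record CSVs
#'
#' @param path CSV path with the [patient_record_columns()] header.
#' @return `read_patient_records`: the records data frame.
#' @export
read_patient_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(patient_record_columns(),
                             c("microscopic_biofilm", "bloom")), names(df))
  if (length(missing) > 0)
    stop("patient CSV missing columns: ", paste(missing, collapse = ", "))
  if (is.null(df$microscopic_biofilm)) df$microscopic_biofilm <- NA
  if (is.null(df$bloom)) df$bloom <- NA
  if (is.character(df$biofilm_locations))
    df$biofilm_locations[is.na(df$biofilm_locations)] <- ""
  df
}

#' @rdname read_patient_records
#' @param records Patient-record data frame.
#' @return `write_patient_records`: `path`, invisibly.
#' @export
write_patient_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
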