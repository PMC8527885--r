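make_record <- function(bbps = 9, prep = "PEG", cecum = TRUE,
                        status = "BF-", cohort = "IBS") {
  data.frame(patient_id = "p1", center = "Austria", cohort = cohort,
             bbps = bbps, prep_type = prep, cecum_reached = cecum,
             biofilm_status = status, biofilm_locations = "",
             microscopic_biofilm = NA, bloom = NA,
             stringsAsFactors = FALSE)
}

test_that("exclusions apply in fixed order with first-failure reasons", {
  recs <- rbind(make_record(bbps = 5),
                make_record(bbps = 5, prep = "non-PEG"),
                make_record(prep = "non-PEG", cecum = FALSE),
                make_record(cecum = FALSE),
                make_record(bbps = 6))
  out <- apply_exclusions(recs)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$bbps, 6)  # boundary BBPS 6 is kept
  expect_equal(out$excluded$reason, c("bbps", "bbps", "prep", "cecum"))
  # conservation and idempotence on the kept set
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(recs))
  again <- apply_exclusions(out$kept)
  expect_equal(nrow(again$excluded), 0)
  expect_equal(again$kept, out$kept)
})

test_that("independent 10% failures keep about 0.9^3 of records", {
  cfg <- cohort_sim_config(counts_are = "enrolled")
  fracs <- vapply(1:10, function(s) {
    rec <- simulate_cohort(cfg, seed = s)
    nrow(apply_exclusions(rec)$kept) / nrow(rec)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.9^3),
            3 * sqrt(0.729 * 0.271 / (10 * 1112)))
})

test_that("prevalence percentages recompute from counts", {
  recs <- cohort_from_counts()
  tab <- prevalence_table(recs)
  pick <- function(co, ce = "all")
    tab[tab$cohort == co & tab$center == ce, ]
  expect_equal(pick("IBS")$percent, 57)
  expect_equal(pick("IBS")$bf_pos, 65)
  expect_equal(pick("IBS")$total, 114)
  expect_equal(pick("IBS", "Austria")$percent, 60)
  expect_equal(pick("all")$bf_pos, 212)
  expect_equal(pick("all")$total, 1112)
  expect_equal(pick("all")$percent, 19)
  # percents recompute exactly from emitted counts
  has_n <- tab$total > 0
  expect_equal(tab$percent[has_n],
               floor(100 * tab$bf_pos[has_n] / tab$total[has_n] + 0.5))
  # degenerate cohorts
  zero <- rbind(make_record(status = "BF-"), make_record(status = "BF-"))
  expect_equal(prevalence_table(zero, by_center = FALSE)$percent, c(0, 0))
})

test_that("crude cohort odds ratios reproduce the published estimates", {
  recs <- cohort_from_counts()
  rep <- or_report(recs)
  or_of <- function(co) rep$or_rounded[rep$cohort == co]
  expect_equal(or_of("IBS"), 19.2)
  expect_equal(or_of("UC"), 7.4)
  expect_equal(or_of("Crohn"), 4.2)
  expect_equal(or_of("post-transplant"), 4.3)
  # a cohort identical to the reference has OR 1
  recs2 <- cohort_from_counts(data.frame(
    cohort = c("IBS", "healthy-control"), center = "Austria",
    bf_pos = c(10, 10), total = c(100, 100)))
  expect_equal(or_report(recs2)$odds_ratio, 1)
  # degenerate reference
  allneg <- cohort_from_counts(data.frame(
    cohort = c("IBS", "healthy-control"), center = "Austria",
    bf_pos = c(10, 0), total = c(100, 100)))
  expect_error(or_report(allneg), "degenerate")
})

test_that("center-adjusted odds ratios stay near the crude estimates", {
  recs <- cohort_from_counts()
  adj <- or_report(recs, adjust_for_center = TRUE)
  expect_lt(abs(adj$odds_ratio[adj$cohort == "IBS"] - 19.2), 0.5)
  joint <- or_report(recs, adjust_for_center = TRUE, model = "joint")
  expect_lt(abs(joint$odds_ratio[joint$cohort == "IBS"] - 19.2), 2)
  expect_true(all(joint$adjusted))
})

test_that("location distributions are multi-label percentages of BF+", {
  recs <- rbind(make_record(status = "BF+"), make_record(status = "BF+"))
  recs$biofilm_locations <- c("cecum", "cecum;rectum")
  dist <- location_distribution(recs)
  expect_equal(dist$percent[dist$segment == "cecum"], 100)
  expect_equal(dist$percent[dist$segment == "rectum"], 50)
  expect_equal(dist$percent[dist$segment == "sigmoid"], 0)
  none <- location_distribution(make_record(status = "BF-"))
  expect_equal(nrow(none), 0)
})

test_that("concordance reports score endoscopy against the microscopic call", {
  rec <- concordance_records(n_pos = 5, micro_pos = 5, n_neg = 5,
                             microneg_pos = 0)
  expect_equal(concordance_report(rec)$metrics$accuracy, 1)
  rec <- concordance_records(n_pos = 5, micro_pos = 0, n_neg = 5,
                             microneg_pos = 5)
  expect_equal(concordance_report(rec)$metrics$accuracy, 0)
  full <- concordance_records()
  out <- concordance_report(full)
  expect_equal(unname(out$table), c(33, 19, 4, 28))
  expect_equal(out$metrics$accuracy, 61 / 84)
  # NA microscopic statuses are skipped, not fatal
  full$microscopic_biofilm[1:3] <- NA
  expect_equal(concordance_report(full)$n_skipped, 3)
})

test_that("patient records survive a CSV round trip", {
  rec <- simulate_cohort(cohort_sim_config(counts = data.frame(
    cohort = "IBS", center = "Austria", bf_pos = 20, total = 40)),
    seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_records(rec, path)
  back <- read_patient_records(path)
  expect_equal(back$biofilm_status, rec$biofilm_status)
  expect_equal(back$biofilm_locations, rec$biofilm_locations)
  expect_error(read_patient_records(file.path(tempdir(), "absent.csv")),
               "no such file")
})
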