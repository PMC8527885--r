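test_that("section simulation is deterministic per seed and config", {
  cfg <- coarse_cfg(seed = 42, bf_status = "BF+")
  a <- simulate_section(cfg)
  b <- simulate_section(cfg)
  expect_identical(a$section$intensities, b$section$intensities)
  expect_identical(a$truth$centroids, b$truth$centroids)
  expect_identical(a$truth$epithelium$y_um, b$truth$epithelium$y_um)
  c <- simulate_section(coarse_cfg(seed = 43, bf_status = "BF+"))
  expect_false(identical(a$truth$centroids, c$truth$centroids))
})

test_that("zero bacterial rate gives a constant image and no centroids", {
  cfg <- coarse_cfg(seed = 1, mean_count_bfneg = 0, noise = "none")
  sim <- simulate_section(cfg)
  expect_equal(nrow(sim$truth$centroids), 0)
  expect_equal(diff(range(sim$section$intensities)), 0)
})

test_that("per-field counts are Poisson at the configured rate", {
  # 20-field BF+ sum: mean 20 * 12 * 10 = 2400
  cfg <- coarse_cfg(seed = 5, bf_status = "BF+", n_fields = 20)
  sim <- simulate_section(cfg, render = FALSE)
  n <- nrow(sim$truth$centroids)
  expect_lt(abs(n - 2400), 3 * sqrt(2400))
  # 200-field BF-: empirical per-field mean and variance near 12
  cfg2 <- coarse_cfg(seed = 6, bf_status = "BF-", n_fields = 200)
  sim2 <- simulate_section(cfg2, render = FALSE)
  counts <- tabulate(floor(sim2$truth$centroids$x_um / 144.72) + 1L,
                     nbins = 200)
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 200))
  expect_lt(abs(var(counts) - 12), 3 * sqrt((2 * 144 + 12) / 200))
})

test_that("BF+ bacteria concentrate at the epithelium, BF- keep the gap", {
  sim <- simulate_section(coarse_cfg(seed = 9, bf_status = "BF+",
                                     n_fields = 4), render = FALSE)
  d <- dist_to_trace(sim$truth$centroids$x_um, sim$truth$centroids$y_um,
                     sim$truth$epithelium)
  expect_gte(mean(d <= 15), 0.8)
  simn <- simulate_section(coarse_cfg(seed = 9, bf_status = "BF-",
                                      n_fields = 4), render = FALSE)
  dn <- dist_to_trace(simn$truth$centroids$x_um, simn$truth$centroids$y_um,
                      simn$truth$epithelium)
  # standoff is enforced vertically; perpendicular distance is marginally
  # smaller on sloped stretches of the border
  expect_true(all(dn >= 29))
})

test_that("centroids stay inside the image and profiles are non-negative", {
  for (status in c("BF+", "BF-")) {
    sim <- simulate_section(coarse_cfg(seed = 3, bf_status = status),
                            render = FALSE)
    w <- 128 * (144.72 / 128)
    expect_true(all(sim$truth$centroids$x_um >= 0 &
                      sim$truth$centroids$x_um <= w))
    expect_true(all(sim$truth$centroids$y_um >= 0 &
                      sim$truth$centroids$y_um <= w))
    expect_true(all(sim$truth$layer_profile$height_um >= 0))
  }
})

test_that("layer profiles honour amplitude, shape and status contrast", {
  zero <- simulate_layer_profile(coarse_cfg(layer_amp_um = 0, seed = 1))
  expect_true(all(zero$height_um == 0))
  const <- simulate_layer_profile(coarse_cfg(layer_amp_um = 20,
                                             layer_shape = "constant",
                                             seed = 1))
  expect_equal(max(const$height_um), mean(const$height_um))
  pos <- simulate_layer_profile(coarse_cfg(bf_status = "BF+", seed = 4))
  neg <- simulate_layer_profile(coarse_cfg(bf_status = "BF-", seed = 4))
  expect_gt(max(pos$height_um), max(neg$height_um))
})

test_that("config validation rejects bad parameters", {
  expect_error(section_sim_config(fold_change = 0.5))
  expect_error(section_sim_config(field_size_um = -1))
  expect_error(cohort_sim_config(counts = data.frame(
    cohort = "IBSX", center = "Austria", bf_pos = 1, total = 2)),
    "unknown cohort")
  expect_error(cohort_sim_config(bloom_rate_bfpos = 1.5))
})

test_that("cohort simulation respects degenerate prevalences", {
  cts <- data.frame(cohort = c("IBS", "UC"), center = "Austria",
                    bf_pos = c(0, 0), total = c(40, 30))
  rec <- simulate_cohort(cohort_sim_config(counts = cts, seed = 1))
  expect_equal(sum(rec$biofilm_status == "BF+"), 0)
  cts$bf_pos <- cts$total
  rec <- simulate_cohort(cohort_sim_config(counts = cts, seed = 1))
  expect_true(all(rec$biofilm_status == "BF+"))
  expect_true(all(rec$biofilm_locations[rec$biofilm_status == "BF+"] != ""))
})

test_that("bloom rates follow the status-conditional defaults", {
  cts <- data.frame(cohort = "IBS", center = "Austria",
                    bf_pos = 1000, total = 2000)
  rec <- simulate_cohort(cohort_sim_config(counts = cts, seed = 12))
  pos <- rec$bloom[rec$biofilm_status == "BF+"]
  neg <- rec$bloom[rec$biofilm_status == "BF-"]
  expect_lt(abs(mean(pos) - 0.51), 3 * sqrt(0.51 * 0.49 / length(pos)))
  expect_lt(abs(mean(neg) - 0.18), 3 * sqrt(0.18 * 0.82 / length(neg)))
})

test_that("assay plate simulation plants recoverable former labels", {
  none <- simulate_assay_plate(former_fraction = 0, seed = 1)
  expect_true(all(score_plate(none$plate)$mean_ratio < 5))
  all_f <- simulate_assay_plate(former_fraction = 1, seed = 1)
  expect_true(all(score_plate(all_f$plate)$mean_ratio > 5))
  hits <- vapply(seq_len(100), function(s) {
    sim <- simulate_assay_plate(n_strains = 15, n_replicates = 8,
                                former_fraction = 6 / 15, seed = s)
    scored <- score_plate(sim$plate)
    all(scored$is_former ==
          sim$truth$is_former[match(scored$strain_id,
                                    sim$truth$strain_id)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
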