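# Independent oracles used across the suite. Kept deliberately naive so
# they share no code with the implementation they check.

# Two-sided Fisher exact p by full enumeration of all tables with the
# observed margins (minimum-likelihood rule, 1e-7 relative tolerance).
fisher_enum_oracle <- function(a, b, c, d) {
  k <- a + c
  lo <- max(0, k - (c + d))
  hi <- min(k, a + b)
  probs <- vapply(lo:hi, function(x) dhyper(x, a + b, c + d, k), numeric(1))
  p_obs <- dhyper(a, a + b, c + d, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct arithmetic.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Render Gaussian spots onto a background with plain dnorm arithmetic
# (independent of the package's renderer); returns a confocal_section.
render_test_section <- function(centroids, pixel_size_um, size_px,
                                sigma_um = 0.5, background = 0.05,
                                peak = 0.6) {
  img <- matrix(background, nrow = size_px[1], ncol = size_px[2])
  u <- (seq_len(size_px[2]) - 0.5) * pixel_size_um
  v <- (seq_len(size_px[1]) - 0.5) * pixel_size_um
  for (j in seq_len(nrow(centroids))) {
    gx <- exp(-(u - centroids$x_um[j])^2 / (2 * sigma_um^2))
    gy <- exp(-(v - centroids$y_um[j])^2 / (2 * sigma_um^2))
    img <- img + peak * outer(gy, gx)
  }
  confocal_section(img, pixel_size_um)
}

# A coarse-pixel config for fast simulation in tests (counts and geometry
# are independent of pixel size).
coarse_cfg <- function(...) {
  section_sim_config(pixel_size_um = 144.72 / 128, ...)
}

# Patient records reconstructing the endoscopic-vs-microscopic follow-up
# group: n_pos BF+ of whom micro_pos meet the density criterion, n_neg BF-
# of whom microneg_pos meet it.
concordance_records <- function(n_pos = 37, micro_pos = 33,
                                n_neg = 47, microneg_pos = 19) {
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n_pos + n_neg)),
    center = "Austria", cohort = "IBS", bbps = 9L, prep_type = "PEG",
    cecum_reached = TRUE,
    biofilm_status = rep(c("BF+", "BF-"), c(n_pos, n_neg)),
    biofilm_locations = "",
    microscopic_biofilm = c(rep(c(TRUE, FALSE), c(micro_pos,
                                                  n_pos - micro_pos)),
                            rep(c(TRUE, FALSE), c(microneg_pos,
                                                  n_neg - microneg_pos))),
    bloom = NA, stringsAsFactors = FALSE)
}
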