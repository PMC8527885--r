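---
title: "Quantifying endoscopically visible mucosal biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endoscopically visible mucosal biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

## The problem

During colonoscopy, some patients — most often those with irritable bowel
syndrome (IBS) or ulcerative colitis (UC) — show adherent yellow-green
layers on the ileocecal mucosa that resist jet washing. Microscopy of
biopsies from such areas shows densely packed bacteria in direct contact
with the epithelium: mucosal biofilms. biofilmq implements the
quantitative backbone of a study of this phenotype, in three layers:

1. **Microscopy**: detect bacteria in single-channel (DAPI-like) confocal
   sections, and quantify their number and spatial arrangement relative to
   a traced epithelial border.
2. **Cohort screening**: apply the study's exclusion rules to multicenter
   endoscopy records and estimate per-diagnosis biofilm prevalences and
   odds ratios.
3. **In vitro**: score crystal-violet biofilm-formation assays.

Because the original patient data are not redistributable, the package
ships a first-class synthetic-data generator for each layer. Every
downstream function is exercised against planted ground truth.

## Microscopy model

A section is modelled as a horizontal strip of `n_fields` contiguous
square imaging fields (default side 144.72 µm at 0.14133 µm/px, i.e.
1024 px), with the epithelial border a smooth polyline near the lower
edge. The geometry of the original image acquisition is not specified
anywhere, so this layout is a modelling choice; it has the convenient
property that the "maximum count in one imaging field" statistic becomes
a tile maximum over the fixed, origin-anchored partition of the strip.

Bacterial counts per field are Poisson. The biofilm-negative (BF−) rate
defaults to 12 bacteria per field; biofilm-positive (BF+) sections
multiply this by `fold_change` (default 10, the approximate contrast
reported between BF+ and BF− biopsies). Spatial structure encodes the
histology: in BF+ sections 90% of bacteria sit within a 15-µm band
adjacent to the epithelium (dense adherent layers), while BF− bacteria
keep a ≥ 30-µm standoff, emulating an intact mucus layer with scattered
luminal bacteria. The per-field count distributions of real sections are
not published; all of these are placeholders exposed in
`section_sim_config()`, chosen to be realistic for colonic biopsy
sections rather than fitted to any data.

Each bacterium is rendered as a Gaussian spot (σ = 0.5 µm, roughly a
diffraction-limited bacterium at 63×), on a constant background, with
optional Poisson shot noise at `photons_per_unit` (default 200) photons
per intensity unit. Surface-layer height profiles are smooth bump
mixtures normalised so the profile maximum equals `layer_amp_um`
(defaults 40 µm for BF+, 12 µm for BF−, reproducing the reported
direction of the contrast: higher maxima in BF+, with means free to
overlap).

What the generator does **not** emulate: tissue autofluorescence texture,
nuclei and debris, out-of-focus light, multi-channel FISH, or 3-D stacks.
A detector that performs well here is validated for geometry and
counting logic, not certified for real histology.

## Detection

The study's original detector is a trained U-Net; its weights are
published separately and are deliberately out of scope. `detect_spots()`
substitutes a deterministic, parameter-documented multiscale
Laplacian-of-Gaussian (LoG) blob detector with the same input/output
contract:

* LoG kernels at 0.8×, 1×, 1.25× the nominal spot scale, each
  self-calibrated so a scale-matched unit-amplitude Gaussian yields a
  response of exactly 0.5 — this makes `response_threshold` (default 0.1
  of the image dynamic range) interpretable across images;
* local maxima of the per-pixel maximum response, additionally gated by a
  robust background model (pixel intensity must exceed the
  `min_intensity_quantile` = 0.99 quantile of a median + MAD Gaussian
  background);
* greedy suppression so no two detections lie within `min_separation_um`
  (default 1 µm).

Raising the response threshold provably never adds detections (candidates
are processed in descending response order, so a higher threshold only
truncates the candidate list). On noiseless renderings the detector
recovers isolated spots to sub-pixel-scale accuracy (< 0.5 µm); on
default-noise BF− sections precision and recall against planted truth
exceed 0.9. In crowded BF+ bands spots closer than the separation limit
merge, costing roughly 10–15% recall — the main known bias of the
classical detector, and the reason recovered BF+/BF− fold changes sit
slightly below the planted value. No numeric parity with the original
U-Net is claimed; the study reports no precision/recall figures to
compare against.

Coordinates are continuous microns, origin at the image's top-left pixel
corner; pixel index *i* maps to (*i* − 0.5) × pixel size.

## Quantification

`section_metrics()` assembles the per-section readouts:

* **total_per_mm, adherent_per_mm** — counts normalised to the traced
  epithelium arc length, reported per millimetre (the study's figure axes
  are unlabelled; per-mm gives readable magnitudes). Adherent means
  within 3 µm of the epithelial polyline, boundary inclusive ("within"
  read inclusively).
* **max_window_count** — maximum count over the origin-anchored partition
  into 144.72-µm tiles, half-open so boundary points belong to exactly
  one tile. A sliding-window variant (`sliding = TRUE`, brute force over
  the offsets that matter) is available and can only be larger.
* **max_density_per_ml** — the field-maximum count divided by the field
  volume. The study never states how 2-D field counts map onto the
  literature's volumetric criterion (> 10⁹ bacteria · mL⁻¹ invading the
  mucus); we take density = count / (window² × section thickness) with a
  configurable thickness defaulting to 5 µm, a typical histological
  section. At these defaults the criterion crosses at ≈ 104.7 bacteria
  per field. Whether the original analysis applied the criterion to the
  maximum field or whole-biopsy volume is unstated; the maximum field is
  the default because it matches the "densest invasion" reading.
* **is_microscopic_biofilm** — strictly greater than 10⁹ mL⁻¹ (the
  printed ">" taken literally, so exactly 10⁹ is negative).
* **layer_max_um / layer_mean_um** — maximum and mean of the per-column
  surface-layer profile. Heights are vertical (per image column), not
  normal to the epithelium; with the near-horizontal simulated border the
  difference is ≤ ~2%.

## Cohort statistics

`apply_exclusions()` implements the screening filters — BBPS ≥ 6,
PEG-based preparation, cecum reached — in that fixed order, logging each
exclusion with its first failing rule (the study implies no order; fixing
one makes the log deterministic). `prevalence_table()` rounds percentages
half-away-from-zero, the convention that reproduces every published
percentage recomputable from its counts.

Odds ratios versus the healthy-control cohort come in two modes: crude
(2×2, `odds_ratio_2x2()`) and center-adjusted via a grouped-binomial
logistic regression fitted by iteratively reweighted least squares
(`fit_grouped_logistic()`, tolerance 1e-8, ≤ 50 iterations, explicit
errors on separation or non-convergence). Whether the original adjusted
model was joint over all cohorts or pairwise per cohort is unstated; both
are provided (`model = "pairwise"` is the default). Confidence intervals
are Wald on the log-OR scale; the study's CI method is unknown and its
printed intervals differ slightly from Wald intervals recomputed from the
counts, so point estimates — which reproduce exactly — are the quantities
asserted in tests.

The cohort simulator draws biofilm status Bernoulli at the configured
per-cohort, per-center prevalence. Its default counts are the *analyzed*
(post-exclusion) sample sizes of the two-center study; since 10% each of
low-BBPS, non-PEG and incomplete colonoscopies are planted upstream of
the exclusions, enrolment is inflated by 1/0.9³ so the analyzed cohort
matches those sizes in expectation (the study enrolled 1426 and analyzed
1112, the same structure). Set `counts_are = "enrolled"` to treat the
counts as enrolment instead. Bloom flags (R. gnavus overgrowth) are
Bernoulli at 51% (BF+) / 18% (BF−), microscopic-criterion flags at
89% / 40% — which makes the simulated endoscopic-vs-microscopic
concordance land at the reported ≈ 72% accuracy.

## Assay scoring

Crystal-violet assays are scored per well as OD595/OD600, then aggregated
across replicates (mean by default; the per-well ratio is the plotted
assay quantity, so aggregation happens after the ratio). A strain is a
biofilm former iff its aggregate ratio strictly exceeds 5. Whether blanks
were subtracted before the ratio in the original assay is unstated; a
blank-correction option exists and defaults to off.

## Numerical and testing choices

* RNG: every simulator takes one integer seed and draws all its
  sub-streams sequentially from it; identical config + seed gives
  byte-identical output within this implementation. No cross-language
  stream equality is promised, only distributional equivalence.
* Test problem sizes: microscopy tests run at a coarse 128-px field where
  only counts and geometry matter, and at the full 1024-px field (1–4
  fields) where detector fidelity matters; the end-to-end cohort check
  uses 50 simulated two-center cohorts (~1500 enrolments each). These
  sizes keep the suite comfortably converged — e.g. 2 binomial SE for
  pooled prevalences — while staying quick to run.
* Degenerate inputs: empty detection sets quantify to zeros (not errors);
  zero epithelium length is an error (normalisation undefined); zero
  OD600 wells are dropped with a warning; all-zero 2×2 margins are
  errors, single zero cells get the Haldane–Anscombe 0.5 correction and a
  flag.
* Known limitations: detector recall degrades in spot clusters denser
  than the 1-µm separation limit; the volumetric criterion inherits the
  unverifiable section-thickness assumption; simulated cohorts share none
  of the covariate structure (age, sex, medication) of real endoscopy
  populations, so the adjusted-OR machinery is validated only for the
  center covariate it models.
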