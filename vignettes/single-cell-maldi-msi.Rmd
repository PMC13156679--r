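---
title: "Single-cell lipidomic analysis of MALDI-MSI data: methods and design"
author: "scLipidMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell lipidomic analysis of MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLipidMSI)
```

## The analysis problem

MALDI mass spectrometry imaging of adherent cell cultures yields one mass
spectrum per 10 µm pixel over a slide, plus brightfield micrographs of the
same fields. At this pitch a single carcinoma cell spans only a handful of
pixels, so extracting *single-cell* lipid profiles requires a chain of
decisions: which pixels contain cells at all, which m/z features are
cell-derived rather than MALDI-matrix clusters, which cell areas are single
dispersed cells rather than cohesive multi-cell groups, how to remove the
strong technical effect of the matrix-application round shared by a pair of
slides, and finally how many lipid phenotypes the single-cell population
supports. scLipidMSI implements this chain end to end, with a synthetic-data
generator that provides exact ground truth for every stage.

The intended experimental design is a paired treatment/control comparison
(labels `CTR` and `EGF` throughout, after the growth-factor EMT-induction
setting the pipeline emulates): each matrix-application round processes one
slide of each arm, making the round (`pair_id`) both the pairing key for
sample-level tests and the batch variable for single-cell correction.

## Preprocessing model

**TIC normalization.** Every pixel spectrum is scaled so its total ion
current equals the dataset's *mean raw TIC* — not 1. The common target is a
free choice mathematically, but using the mean TIC preserves the intensity
scale, so the later cell/background ratio filter operates on numbers
commensurate with the raw data. The per-pixel raw TIC is kept: it is the
quantity that identifies the cell cluster later. The operation is
idempotent, and zero-TIC pixels are left untouched but counted.

**Peak picking.** The noise scale of a spectrum is estimated robustly as
1.4826 × MAD of the residual after subtracting a running median (window 101
points); local maxima at a signal-to-noise ratio of at least 6 are kept and
centroided by three-point parabolic interpolation. The 6× threshold is the
assay's standard operating point; it is a parameter (`snrMin`).

**Alignment.** Picked peaks from all pixels are pooled, sorted, and split
into features wherever the gap between consecutive m/z values exceeds a
tolerance (default 0.1 Da — a typical reflector-TOF peak width over m/z
500–1000). This greedy 1-D clustering is order-independent by construction.
Features seen in under 1% of pixels are dropped.

**Cell-pixel detection.** We implement spatial k-means as plain k-means
(k-means++ style restarts, fixed seed, pixels processed in canonical
raster order so input order is irrelevant) on z-scored feature vectors
augmented with Gaussian-weighted neighbourhood means of radius 1 pixel.
This smooth-augmentation variant is an approximation chosen for testability
rather than a replica of any particular toolbox's algorithm. The cluster
with the highest mean *raw* TIC is declared the cell cluster — cells
dominate ion yield — with ties broken towards the larger cluster. The
number of clusters defaults to k = 2 (cells vs background); a sweep is
available when slides carry more classes.

**Cell-specific peaks.** A feature is cell-specific when its mean over cell
pixels is at least 5× (inclusive — "minimum 5 times" reads as ≥) its mean
over cell-free pixels. A zero background mean with positive cell signal is
retained. The retained set shrinks weakly as the threshold grows.

## Segmentation model

Brightfield images are blurred with a Gaussian of σ = 5 px (separable
kernel truncated at 3σ, unit sum, mirror-reflected borders) and binarized
with Otsu's threshold computed on a 256-bin histogram. Candidate contours
are 8-connected foreground components; holes are ignored. A contour is a
single-cell candidate iff its area lies in 100–2500 µm² and its bounding-box
aspect ratio (width/height, matching the symmetric interval) lies in
0.75–1.25, both inclusive.

Accepted contours are mapped onto the MSI grid through an axis-aligned
scale-plus-translation registration (optional flips; no rotation — slide
scanner geometry). Cell pixels covered by exactly one accepted contour take
its id; remaining cell pixels 4-connected to a unique id are flood-filled.
A cell id is *dispersed* iff its pixels form one whole 4-connected component
that received exactly that one id; everything else cell-like is *cohesive*.
The original workflow this emulates ended in manual curation; we replace
that with the deterministic rules above plus an optional override table
(`cell_id` → `organization`), which records exactly what would have been
manual.

## Batch correction

Single-cell spectra are corrected across matrix-application rounds with the
classic parametric empirical-Bayes location/scale model (the ComBat model),
re-implemented here: intensities are logged (`log(x + eps)`, eps = half the
smallest positive value, avoiding log 0 while hugging the data scale),
standardized per feature using a design containing batch indicators and the
treatment covariate (so treatment differences are protected), per-batch
location and scale deviations are shrunk towards normal / inverse-gamma
priors with method-of-moments hyperparameters, and the conditional
posterior means are iterated to an absolute tolerance of 1e-6 (at most 500
iterations) before back-transforming. Single-unit batches fall back to
location-only correction with a warning. Whether the original analysis
included treatment as a covariate is not documented; we default to yes and
expose `covariates = NULL` to disable.

Recovery behaviour worth knowing: with two batches of 500 cells and a
planted ×2 scale factor on log intensities, the *mean* per-feature variance
ratio returns to 1 within a few percent, but individual features fluctuate
by roughly ±10% — the sampling SD of a variance ratio at n = 500 is ≈ 0.09,
and EB shrinkage adds a small bias for extreme features. Aggregate summaries
are therefore the meaningful check, and that is what the tests assert.

## Consensus clustering

Cells are z-scored per feature (denominator n − 1) and clustered by the
subsampled consensus procedure: in each of `nIter` iterations (default 500;
heavy validation runs use 100) a fraction 0.8 of cells is drawn without
replacement; for every combination of 8 neighbour counts
({5, 10, 15, 20, 25, 30, 40, 50}) and 19 resolutions (0.1–1.9 in steps of
0.1) an SNN graph is built and partitioned by Leiden (modularity objective).
The counts 8 and 19 are the procedure's signature; the specific values are
our choice, spanning under- to over-clustering, and are configurable. The
SNN edge weight is the Jaccard index of self-inclusive k-NN sets — simpler
and exactly oracle-testable, a documented divergence from rank-based
weighting schemes. Each partition is binned by its *realized* cluster count
K; the consensus matrix for K averages co-clustering over co-sampled pairs.
Candidates with fewer than 10 supporting partitions are discarded; pairs
never co-sampled (rare at 500 × 0.8² ≈ 320 expected co-occurrences) are
imputed with the matrix mean and counted.

Each candidate K is cut by hierarchical clustering with McQuitty (WPGMA)
linkage on 1 − consensus and scored by the mean silhouette on a 10-PC PCA
embedding (dimension configurable; the embedding dimension was not
documented in the emulated workflow). The ranking is reported in full and
any retained K can be forced — deliberately choosing a runner-up (e.g. 7
clusters over a dominant 2-group split) is a legitimate way to expose
heterogeneity, and the API records it as an override rather than a
re-ranking. Seeds are derived from one master seed by counter per
(iteration, neighbour value, resolution), so results are independent of
execution order. t-SNE (an exact O(n²) implementation; no approximation) is
provided for visualization only.

## Marker calling and sample-level tests

A lipid is a marker between two cell groups iff all three hold: fold change
above 1.5 or below 0.667 on linear-scale mean intensities, Welch t-test
Bonferroni-adjusted p below 0.01, and non-overlapping interquartile ranges
(type-7 quantiles). Markers surviving p < 0.001 are additionally flagged
`strong`, the tier used for highlighting. Whether fold changes should be
computed on linear or log scale was left open in the emulated workflow;
linear means are the default (`useLog` records the choice). When a group is
a set of clusters, its cells are pooled as individual datapoints, so larger
clusters weigh more. Removing any one criterion can only enlarge the marker
set; the tests assert this conjunction property and the null calibration
(≈ no markers under label permutation).

Sample-level comparisons use paired t-tests (pairing by matrix-application
round, or by sample for cohesive-vs-dispersed pools) with Bonferroni
correction; group percentages (cell-containing pixels, dispersed share) use
Welch tests. qPCR tables are analyzed by ΔΔCt with per-gene Bonferroni
adjustment across treatment groups.

## The synthetic-data generator

The generator emulates the study conditions, and its defaults *are* those
conditions: 10 µm pixel pitch, m/z 500–1000, a 60-feature panel of which 46
are cell-specific lipid features in the class proportions of the emulated
panel (2 PA, 3 PS, 5 PE, 14 PI, 2 PG, 1 LPI carrying treatment effects;
the remainder unaffected), with PA/PS/PE/PI-like features decreasing about
two-fold under treatment and PG/LPI-like features increasing — so 21 of 46
features change, as in the emulated panel. The other 14 features emulate
MALDI-matrix clusters: they dominate the cell-free background and fall well
below the 5× ratio on cells, giving the filter something real to reject.
Background matrix intensity is scaled so cell pixels carry about 2× the raw
TIC of background pixels; planted normalized cell/background ratios for
lipid features are drawn from [6, 15], keeping a safety margin around the
5× boundary under noise and treatment-induced TIC shifts. No published
background/matrix peak statistics exist for this assay configuration, so
these background levels are the generator's own calibrated choice.

Geometry: brightfield images are rendered at 0.65 µm/px, a typical slide
scanner scale (and the scale at which the σ = 5 px blur corresponds to a
physically modest 3.25 µm). Dispersed cells are single discs with areas
drawn inside 250–650 µm² — comfortably within the 100–2500 µm² filter
window, so that the area *measured* after blurring and thresholding (always
a little smaller than the planted disc) never straddles the filter
boundary; cells near that boundary are exactly the cases the emulated
workflow resolved by manual curation, which the generator deliberately does
not plant. Singleton centres are snapped near pixel centres so even the
smallest disc covers an MSI pixel; cohesive colonies
are unions of 2–4 overlapping discs of radius 30–45 µm, which makes every
colony jointly larger than 2500 µm² — so the dispersed/cohesive ground
truth is unambiguous by construction. Objects are placed with at least ~2
pixels of clearance, and configurations that cannot fit are rejected.
Intensity noise is mean-preserving log-normal at a coefficient of variation
of 0.2 by default (a realistic shot-to-shot spread for centroided MALDI
peak intensities); batch effects are per-round multiplicative factors, i.e.
location shifts on the log scale, with scale effects expressible through a
batch-specific noise CV. Spectra are generated directly as centroided peak
heights; profile-mode spectra with Gaussian peak shapes (stated FWHM) are
generated separately to exercise the peak picker, keeping the stages
decoupled.

What the generator does *not* emulate — isotope envelopes, adducts, mass
drift, ionization suppression gradients, partial-volume mixing at cell
borders, focus artefacts in brightfield — bounds what a passing test suite
shows: the pipeline's logic is correct under the modelled data structure,
not that the assay's physics are free of surprises.

## Numerical choices and problem sizes

Otsu uses a 256-bin histogram with the threshold at a bin edge; k-means uses
10 restarts at fixed seed; Leiden runs 2 refinement sweeps standalone and a
single sweep inside the consensus loop, where averaging over thousands of
partitions makes further refinement redundant; WPGMA ties are
resolved by `stats::hclust`'s deterministic ordering; silhouette uses the
a = b = 0 → s = 0 convention for coincident points and s = 0 for
singletons; PCA components are sign-fixed by making each component's
largest-magnitude loading positive. The validation suite runs planted-truth
problems at the scale of the emulated study where it matters — 1339 cells,
46 features and 7 subpopulations for cluster recovery (100 consensus
iterations), two batches of 500 cells per group for batch correction,
120 × 120-pixel slides for segmentation — and smaller instances elsewhere,
chosen so the whole suite completes comfortably on a single CPU.

## Known limitations

Registration supports scale, translation and flips only; vendor imzML files
must be converted to the package's TSV grid format upstream (no binary
reader is bundled); the non-parametric ComBat variant and FDR procedures
other than Bonferroni are intentionally absent; normalization methods other
than TIC are not validated. The consensus procedure's memory grows with the
square of the cell count times the number of realized K bins — fine into the
low thousands of cells, not designed for 10⁵.
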