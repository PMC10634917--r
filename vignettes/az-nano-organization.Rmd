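---
title: "Quantifying the nanoscale organization of active zone proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the nanoscale organization of active zone proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Presynaptic active zones concentrate two functions in a footprint a few
hundred nanometers across: clustering voltage-gated Ca^2+^ channels and
priming synaptic vesicles for release. Whether the proteins executing these
functions (for example the channel Ca~V~2.1 and the priming factor Munc13-1)
sit in one shared protein complex or in separate nanoclusters is a question
about tens-of-nanometer spatial organization, answerable with multiplexed
single-molecule localization microscopy (DNA Exchange-PAINT): four targets
are imaged sequentially — two scaffold markers that delimit the synapse
(a presynaptic mask such as Bassoon and a postsynaptic marker such as
PSD-95) and the two analysis targets.

`aznano` implements the full analysis chain from raw localization tables to
population statistics:

1. **Quality filtering** of localizations by PSF-fit sigma, localization
   error, and a photon-count mode rule.
2. **Drift correction** by redundant cross-correlation (RCC) over temporal
   segments.
3. **Chromatic registration** with a degree-2 polynomial fitted to fiducial
   bead pairs, plus residual translational offset correction between
   targets.
4. **Temporal linking** of blinking events that persist across frames.
5. **Synapse selection**: DBSCAN on the scaffold targets, rejection of
   nonspecific clusters by frame statistics, alpha-shape boundaries, an
   en-face roundness/overlap criterion, and restriction of the analysis
   targets to the active-zone boundary.
6. **Nanocluster analysis**: DBSCAN nanocluster detection, alpha-shape
   geometry, robust area-outlier filtering, and pair autocorrelation.
7. **Cross-statistics**: randomization-normalized cross-enrichment of one
   protein around the other's nanocluster centers, a 1.96-SD enrichment
   classification, and the separation index SI = d / (r~1~ + r~2~).

Because no public dataset accompanies this type of experiment, the package
ships a first-class synthetic-data generator that plants known nanocluster
architectures, blinking, drift, chromatic warp and nonspecific binders, so
every stage is verifiable against ground truth.

## A worked example

```{r, eval = FALSE}
library(aznano)

field <- simulate_field(field_params("co_organized", n_frames = 3000L),
                        seed = 11)
cfg <- az_config(seed = 5, synapse = list(frame_sd_bounds = c(250, 1100)))
res <- analyze_field(field$tables, cfg)
res$summary$a$enriched_fraction     # fraction of A nanoclusters enriched in B
res$summary$a$median_si             # median separation index
```

## The model and its stages

### Localization tables and units

The canonical internal unit is nm. Camera-pixel quantities (the PSF-fit
sigma, the 0.3-px linking radius) are converted at their use sites through
the table-level `pixel_size_nm` (default 160 nm, the conventional camera
pixel behind 20-nm rendering at magnification 8). Pixel (i, j) covers the
half-open square [i, i+1) x [j, j+1) in pixel units, so binning is
unambiguous. Frames are 0-based.

### Quality filters

Localizations are removed when the fit sigma is below 0.3 or above 1.6
camera pixels (strict inequalities), when the localization error exceeds
20 nm, or when the photon count exceeds the *modal bin* of the photon
histogram. The histogram rule needs a binning convention, which is not part
of the stated filter: we use fixed 50-photon bins starting at zero, ties
resolved toward the lower bin, and the threshold at the modal bin's *upper*
edge (lower edge and center are available through
`filter_quality(photon_mode_edge=)`). Removal causes are counted with the
precedence sigma → precision → photons; the precedence affects only the
per-cause bookkeeping, never the surviving set.

### Temporal linking

A binding event persists for several frames, possibly with short dark gaps.
Localizations within 0.3 px that reappear with at most 5 dark frames merge
into one event: photon-weighted mean position, summed photons, first frame,
and the minimum member precision (a conservative choice; the combination
rule is not standardized). Matching is greedy in frame order with
nearest-candidate assignment and ties broken by lower event index, so the
result is deterministic.

Strict idempotence of linking is not attainable on dense data for *any*
greedy linker that outputs mean positions: two simultaneous nearby events
must remain separate in a first pass (one fluorophore cannot be fit twice
in a frame), yet their merged rows carry different first frames and nearby
means, so a second pass may merge them. The tests therefore assert exact
idempotence in the separated-event regime and a small fixed-point residual
(under 3% of rows) on dense fields.

### Drift correction

The acquisition is cut into 1000-frame segments; all segment pairs are
cross-correlated on 30-nm rendering pixels and per-segment offsets are
solved by least squares (redundant cross-correlation), then interpolated
linearly between segment midpoints with linear extrapolation at the ends.
Two conventions matter:

* **Mean-zero drift.** A global constant offset is unobservable to RCC (it
  shifts every segment equally), so estimated trajectories are normalized
  to mean zero and comparisons against planted trajectories are made after
  mean removal.
* **Accuracy floor.** Each segment samples a random subset of binding
  sites, and this sampling noise offsets all of that segment's pairwise
  correlations coherently; redundancy cannot average it away. Drift
  accuracy therefore improves with localizations per segment, not with the
  number of pairs. The packaged recovery checks use dense fields
  (~15,000 localizations per segment) where a 90-nm linear drift endpoint
  is recovered within 10%.

### Chromatic correction

A degree-2 polynomial in (x, y) — six coefficients per axis, hence at least
six bead pairs — is fitted both ways: the forward fit (moving regressed on
fixed) recovers planted warp coefficients exactly on noise-free pairs; the
least-squares inverse fit is what corrects localization tables, with its
RMS residual at the control points reported as `fit_rmse_nm`. Residual
translational offsets between targets are then measured by image
cross-correlation against the reference target. On fields without many
synapses a measured offset can be spurious (the correlation surface is a
plateau when one pattern lies inside the other, and cluster-to-cluster
alignments give sharp but meaningless peaks), so the shift is applied only
when the peak is strong (prominence ≥ 20), compact, and away from the
±100-nm search-window edge; otherwise the measurement is reported but not
applied.

### Synapse selection

Scaffold clusters come from DBSCAN at 48 nm / 10 points with clusters under
75 localizations discarded. Nonspecific binding produces clusters visible
only over a short stretch of the movie: a cluster is rejected when its
frame standard deviation falls below 2500 or above 11,000 (values stated
for a 30,000-frame acquisition — a uniformly visible cluster has frame SD
≈ n/√12 ≈ 8,660 — and should be scaled for shorter ones), or when its mean
frame lies outside μ ± 2σ of a Gaussian fit (sample mean/SD) over all
clusters' mean frames (skipped below 3 clusters).

The en-face criterion needs two interpretations that the available
description leaves open, both config-exposed and flagged here:

* The "smoothed boundary ≤ 2" condition is read as a *roundness*
  constraint: the ratio of major to minor axes of the second-moment
  ellipse of the mask cluster's alpha-shape boundary after a 3-vertex
  moving-average smoothing. En-face synapses are approximately round
  (ratio near 1); side-view synapses are elongated (≈ 3).
* The 70% area-overlap denominator is the smaller of the two scaffold
  shapes (100% is then achievable for nested shapes); the mask-shape
  denominator is available as an alternative. Overlap areas are computed
  on a 2-nm raster.

Synapse-scale alpha shapes use a 150-nm alpha radius — the same physical
value as the 0.9375-px nanocluster radius at 160-nm pixels — since only the
nanocluster value is stated. Accepted synapses then restrict each analysis
target (and the postsynaptic target) to the mask boundary
(boundary-inclusive point-in-polygon) and are dropped when any target keeps
fewer than 25 localizations.

### Alpha shapes

No Delaunay or alpha-shape library is part of the package's dependency
stack; the package implements Bowyer–Watson triangulation with an
alpha-complex filter: triangles with circumradius ≤ α survive, the area is
their summed area, and the boundary is the set of edges belonging to
exactly one surviving triangle, assembled into rings. A deterministic
relative 10^-9^ jitter guards against exactly co-circular inputs; its
effect on areas is orders of magnitude below all tolerances. The α → ∞
limit equals the convex hull (tested against `grDevices::chull`), and the
area of a densely sampled disc matches πr² within 5%.

### Nanoclusters and autocorrelation

Nanocluster DBSCAN parameters are deliberately *mandatory configuration*
(defaults ε = 25 nm, 5 points, consistent with the ≥5-localization filter)
because no stated values exist; absolute nanocluster counts and areas are
therefore not comparable across parameter choices, and the tests check
recovery of *planted* structure instead. Cluster geometry: centroid =
unweighted mean, area from the 150-nm alpha shape, effective radius
√(area/π). Across the dataset, clusters whose area exceeds the largest
non-outlier area under a univariate ROUT (Q = 0.1%, high side) are removed.

The pair correlation g(r) divides observed pair counts per 10-nm annulus
(0–200 nm) by their expectation for a homogeneous pattern of the same
intensity in the ROI. The expectation uses the ROI's isotropized set
covariance computed by FFT on a 2-nm raster; per annulus we take the mean
covariance over lattice samples times the exact annulus area, which removes
the lattice-measure bias that otherwise inflates the smallest annulus by
~15%. Calibration: for CSR points in a 200-nm disc, the mean g over 200
fields is within 1 ± 0.05 in every bin.

### Cross-enrichment, classification, separation

For each nanocluster of protein A, the density of protein B per annulus
(clipped to the ROI) is normalized by the same quantity averaged over 100
uniform randomizations of B inside the mask boundary. Classification uses
the mean enrichment over bins with outer edge ≤ 60 nm, compared with the
same statistic from 50 *independent* randomizations: enriched above
mean + 1.96 SD, de-enriched below mean − 1.96 SD (strict inequalities).
Under a CSR null the two-sided tail calibrates to ≈ 5% (within 2–10% over
500 synthetic nanoclusters). The SD is taken across the 50 randomization
statistics (not pooled per bin). Population-level curves are smoothed by
replacing per-bin high outliers (ROUT Q = 0.1%) with the highest
non-outlier value at that bin.

The separation index for a nanocluster and the nearest opposite-protein
nanocluster is SI = d / (r~1~ + r~2~), with d the centroid distance and
r~1~, r~2~ the centroid-to-border distances along the connecting line,
taken to the outermost boundary crossing of each alpha-shape polygon.
SI < 1 flags overlap; coincident centroids give SI = 0 with the effective
radii reported and a degenerate flag. Ties in the nearest-neighbor choice
break toward the lower index.

### Randomization seeds

Every randomization seed derives from the master seed by a stable string
hash over (synapse, protein, purpose), so adding a synapse to a dataset
never perturbs another synapse's draws, and two runs with equal configs are
byte-identical.

## The synthetic-data generator

`simulate_field()` emulates: a synapse of 200-nm active-zone radius whose
mask target fills the footprint and whose postsynaptic target fills a
concentric (optionally scaled/offset) footprint; analysis targets drawing
binding events from planted Gaussian nanoclusters (3 per target by
default, sd 15 nm for A and 20 nm for B, 60 events each, 10% uniform
background) under three architectures (`co_organized`: shared centers;
`segregated`: B centers ≥ 100 nm from A centers; `independent`);
DNA-PAINT-like blinking (events start uniformly in time, geometric run
length with mean 3 frames, occasional 1–3-frame dark gaps, per-frame
positions jittered by a ~8-nm lognormal localization precision); planted
quality violations (2% of rows per cause) so the filters have work to do;
and nonspecific binders planted as two tight clusters away from the
synapse whose frames concentrate in a window with SD = 5% of the
acquisition, making them detectable by the frame-statistics filter.
`corrupt_field()` adds a per-frame drift trajectory and a degree-2
chromatic warp on chosen targets; `simulate_bead_pairs()` produces matching
fiducial control points.

Deliberate generator conventions, fixed once:

* **Planted cluster separation ≥ 100 nm.** Plants closer than roughly two
  detected diameters are not distinct objects under any density-based
  definition — adjacent Gaussian plants simply bridge and merge — so
  recovery of a closer ground truth would be unidentifiable rather than
  hard. 100 nm makes "K planted clusters" a well-posed target at the
  ~30-nm detected-radius scale.
* **Planted effective radius.** Ground truth records the Gaussian spread
  sd; recovery checks compare the detected alpha-shape effective radius to
  2·sd (the two-sigma radius containing ~86% of binding sites).
* **Nonspecific plants must survive linking.** Short-lived binders
  concentrated in time get chain-merged by temporal linking; the defaults
  (500 events, 60-nm spread, 5%-of-acquisition frame window) leave > 75
  linked rows so the frame filter — not an accident of linking — is what
  removes them.
* **Scaled-down acquisitions.** Tests use 3,000 frames; the frame-SD
  bounds, stated for 30,000 frames, are scaled by the same factor
  (250/1,100) in those configurations.

What the generator does *not* emulate: imager-concentration kinetics and
triplet-state photophysics, 3D structure, astigmatic PSFs,
field-dependent (non-rigid) chromatic error, and multiple synapses per
field of view. Passing the packaged tests therefore demonstrates that the
chain recovers planted structure under this model, not that any specific
biological dataset would yield particular numbers; in particular, absolute
enriched fractions and SI distributions depend on the unstated nanocluster
DBSCAN parameters and on acquisition details, and are not comparable
across studies.

## STED side-view profiles

The companion module quantifies 2D STED images of side-view synapses: a
750-nm-long, 250-nm-wide profile is drawn perpendicular to the
postsynaptic-marker bar (bilinear interpolation, sampling step = the
22.7-nm pixel), smoothed with a 5-sample rolling average (shrinking
windows at the edges), aligned so the postsynaptic peak sits at offset 0
(non-unique maxima break toward the profile center), and averaged with SEM
across synapses. Peak intensities are normalized per culture to the mean
of the control condition, which is 100% by construction; averaged profile
peaks sit below the mean individual peak whenever peak positions jitter
across synapses (peak-spread attenuation). Profiles are normalized before
averaging. The packaged chain recovers a planted +40-nm trans-synaptic
offset within one pixel.

## Numerical choices and degenerate inputs

* Point-in-polygon is boundary-inclusive (even-odd rule over rings), so
  edge localizations are counted deterministically.
* ROUT (univariate): robust center = median, RSDR = 68.27th percentile of
  |residuals| with an n/(n−1) small-sample factor, candidates = the most
  extreme 30%, step-up FDR thresholds Q·i/n on t statistics with n−1
  degrees of freedom; `side = "high"` restricts to the upper tail. The
  procedure is calibrated by its specificity (≤1% false flags at
  Q = 0.1% on clean normal samples) and sensitivity (10-SD contaminants
  ≥95% flagged) rather than by value-matching any proprietary
  implementation.
* Gaussian fits of cluster mean-frames are maximum-likelihood
  (sample mean/SD).
* Empty tables, all-removed filters, sub-3-cluster frame statistics,
  degenerate polygons and coincident centroids all take defined branches
  (warnings or flagged results, never silent NaN).
* Averaged-shifted-histogram rendering uses m = 4 shifts per axis by
  default (the method's shift count is conventionally tied to the
  magnification; it is exposed as a parameter), conserves mass exactly,
  and is translation-equivariant under whole-pixel shifts.

## Problem sizes in the packaged checks

The test-suite and acceptance studies run single-synapse fields at 3,000
frames (the generator's default acquisition length is 30,000), 50 seeds
for count recovery, 20 paired seeds for architecture discrimination, 200
CSR fields for g(r) calibration and 500 synthetic nanoclusters for the
classification-tail calibration; drift recovery uses 10,000-frame dense
fields. These sizes give stable statistics for every calibration band
while keeping a full run in the minutes range on one core.

## Known limitations

* The en-face "≤ 2" criterion is an interpretation (axis ratio of the
  smoothed boundary); acceptance fractions under other readings of that
  condition would differ.
* Nanocluster DBSCAN parameters are unstated upstream; results always
  record them, and cross-study comparability of absolute counts is
  explicitly out of reach.
* Residual-offset correction needs consensus structure; it declines to act
  (flagged low-confidence) on sparse or single-synapse fields.
* The alpha-shape boundary of a sparse cluster can underestimate area;
  with the 150-nm alpha radius this matters only below ~10 points.
* HDF5 I/O shells out to the system Python's h5py; the CSV dialect is the
  self-contained path.
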