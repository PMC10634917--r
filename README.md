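# aznano

Nanoscale organization analysis of presynaptic active-zone proteins from
multiplexed single-molecule localization data (DNA Exchange-PAINT), with a
companion module for STED side-view line-profile quantification.

## What it does, and for whom

Active zones cluster voltage-gated Ca²⁺ channels (e.g. Ca_V2.1) and prime
synaptic vesicles (via Munc13-1) within a few hundred nanometers. Whether
these two machineries share one protein complex or form separate
nanoclusters is a question about the relative sub-synaptic organization of
two proteins. `aznano` is for microscopists and analysts who have
localization tables for four targets per field of view — two scaffold
markers delimiting the synapse (presynaptic mask, e.g. Bassoon, and a
postsynaptic marker, e.g. PSD-95) plus two analysis targets — and want a
tested, reproducible pipeline from raw localizations to population
statistics.

The chain: quality filters (PSF sigma 0.3–1.6 px, localization error
≤ 20 nm, photon-mode rule) → redundant cross-correlation drift correction
(1000-frame segments) → degree-2 polynomial chromatic registration from
bead fiducials plus residual offset correction → temporal linking of
blinking events (0.3 px, 5 dark frames) → synapse selection (DBSCAN
48 nm/10 pts, ≥ 75 localizations, frame-statistics rejection of
nonspecific clusters, alpha-shape boundaries, en-face roundness ≤ 2 and
scaffold overlap ≥ 70%, ≥ 25 in-boundary localizations per target) →
nanocluster detection (DBSCAN, 150-nm alpha-shape geometry, ≥ 5
localizations, ROUT Q = 0.1% area filter) → pair autocorrelation g(r) →
randomization-normalized cross-enrichment with 1.96-SD classification
(enriched / indistinguishable / de-enriched within 60 nm, against 100 + 50
randomized placements) → the separation index

    SI = d / (r1 + r2)

where `d` is the centroid distance between a nanocluster and the nearest
nanocluster of the other protein and `r1`, `r2` are the centroid-to-border
distances along the connecting line; SI < 1 means the borders overlap.

A first-class synthetic-data generator plants known synapse geometry,
nanocluster architectures (co-organized / segregated / independent),
DNA-PAINT blinking, nonspecific binders, drift and chromatic warp, with a
ground-truth sidecar — every stage of the pipeline is verifiable without
proprietary data. The methods vignette
(`vignettes/az-nano-organization.Rmd`) documents the model, conventions
and limitations.

## Worked example

```r
library(aznano)

field <- simulate_field(field_params("co_organized", n_frames = 3000L),
                        seed = 11)
cfg <- az_config(seed = 5, synapse = list(frame_sd_bounds = c(250, 1100)))
res <- analyze_field(field$tables, cfg)

res$summary$n_accepted_synapses
#> [1] 1
res$summary$a[c("n_nanoclusters", "median_effective_radius_nm",
                "enriched_fraction", "median_si")]
#> $n_nanoclusters             [1] 3
#> $median_effective_radius_nm [1] 28.5
#> $enriched_fraction          [1] 1
#> $median_si                  [1] 0.14
head(res$separation[, c("target", "nc", "d_nm", "si", "overlap")], 3)
#>   target nc      d_nm        si overlap
#> 1      a  1  6.970263 0.1105159    TRUE
#> 2      a  2  7.997425 0.1399562    TRUE
#> 3      a  3 11.257814 0.1836378    TRUE
```

The single planted en-face synapse is accepted; the three planted A
nanoclusters are recovered with ~28-nm effective radii. Because the field
is co-organized (A and B share cluster centers), every A nanocluster is
classified enriched in B and every separation index is far below 1
(overlapping). A `"segregated"` field gives the opposite pattern
(enriched fraction near 0, SI > 1). The `frame_sd_bounds` override scales
the nonspecific-cluster frame-SD filter, whose defaults are stated for
30,000-frame acquisitions, to this 3,000-frame example.

A thin command-line front end is installed with the package:

```sh
Rscript inst/scripts/aznano.R simulate --architecture co_organized \
    --seed 1 --n-frames 3000 --out field/
Rscript inst/scripts/aznano.R analyze --mask field/mask.csv \
    --post field/post.csv --a field/a.csv --b field/b.csv --out results/
```

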