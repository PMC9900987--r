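---
title: "Serial multiplexed smFISH analysis with MuxFISH"
author: "MuxFISH authors"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial multiplexed smFISH analysis with MuxFISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MuxFISH)
library(SummarizedExperiment)
```

# Scope

MuxFISH implements the image-analysis core of a serial (sequential)
multiplexed single-molecule FISH workflow: a gene panel is read out one
gene per imaging channel per hybridization round, so a 30-gene panel
needs 6 rounds of 5 readout channels, each round also carrying a
membrane immunostain and a DAPI channel for registration and
segmentation. The package covers the path from raw multi-round image
stacks to spatially mapped transcriptional subpopulations:

1. **Illumination correction** — retrospective flat-field estimation.
2. **Denoising** — true 3D median filtering.
3. **Registration** — integer-voxel alignment of rounds.
4. **Segmentation** — seeded 3D watershed on the membrane channel.
5. **Spot calling** — Laplacian-of-Gaussian detection.
6. **Signal gating** — k-means intensity separation of unspecific spots.
7. **Decoding** — codebook (round, channel) → gene lookup.
8. **Quantification** — per-cell gene counts as a
   `SingleCellExperiment`.
9. **Normalisation, clustering, gating** — grouped z-scores,
   hierarchical clustering, strict z > 0 co-expression gates.
10. **Back-mapping** — pseudo-colour rendering of cell groups onto the
    section.

Because no public raw data accompany this kind of acquisition at desk
scale, the package ships a synthetic-data generator with complete
ground truth (true spots, true counts, true segmentation, true shifts,
true shading fields), and the whole pipeline is validated against that
truth plus independent brute-force oracles.

# The generative model

`simulateSection()` renders one synthetic section per config:

* **Geometry.** Each FOV is an array of `volumeShape` voxels in
  (z, y, x) order, default 16 × 100 × 100 at 0.5 × 0.21 × 0.21 µm —
  0.5 µm optical sectioning and a camera-limited lateral pitch. A
  section is `nFOVs` FOVs tiled along x (default 3).
* **Cells.** `nCells` centroids (default 36) are placed by rejection
  sampling with a 2.5 µm minimum spacing, each inside the spatial band
  of its expression program; cell shapes are anisotropic Voronoi
  regions of the centroids (distance scaled by voxel size), so cells
  tile space without gaps, as in dense embryonic tissue.
* **Expression.** Four programs emulate an early ectoderm cross
  section: a spatially unrestricted *stem* program co-expressing PouV,
  Nanog, Klf4, Tfap2a and Sox2, and *neural*, *neural crest* and
  *epidermal* programs in medial-to-lateral thirds. Per-gene counts are
  negative binomial with three mean tiers (12 / 6 / 1) and size 8 —
  overdispersed as real transcript counts are.
* **Optics.** Each transcript is rendered as a 3D Gaussian of sigma
  `spotSigma` = 0.25 µm (isotropic in µm, so anisotropic in voxels)
  with amplitude drawn from N(1000, 100²); unspecifically bound probe
  appears as Poisson-placed spots of amplitude N(200, 25²) at
  `backgroundSpotRate` = 2 per 1000 µm³ per channel. The membrane
  channel is a blurred ridge image of the label boundaries; DAPI is a
  blurred nuclear blob per cell.
* **Nuisances.** Per-round integer drift (uniform within `driftMax`,
  round 1 fixed), per-channel smooth quadratic multiplicative shading
  (peak ±30 %) with spatial mean 1, a camera baseline of 100, and
  additive Gaussian noise (sd 10), applied in that order. Ground truth
  stays *observable*: a signal spot whose drift-displaced peak falls
  outside the imaged volume is never rendered, so it is removed from
  `trueSpots` and decremented from `trueCounts` rather than left as an
  unfindable phantom.

All randomness derives from the single `seed` in the `SimConfig`; two
calls with the same config are identical.

## Presets

* `"default"` — the study conditions above. These parameters were fixed
  up front as the simulated acquisition; analysis quality numbers are
  measured *at* these settings, never the other way round.
* `"noiseless"` — no camera noise, no background spots, no shading, no
  drift, and a minimum spot separation of 4 voxels (Chebyshev) with a
  2-voxel border margin. This is the *resolvable-spot* regime used for
  exact-equality validation: spots closer than the PSF are physically
  unresolvable by any detector, and border-truncated spots are not
  reliably localizable, so exactness can only be demanded when the
  scene excludes both. If a crowded cell draws more spots than its
  volume can pack at that separation, the surplus spots are dropped
  *and the true count decremented*, keeping `trueCounts` equal to what
  is actually rendered (a mild truncation of negative-binomial tails in
  very small cells).
* `"tiny"` — one small FOV, 6 genes, 2 rounds; smoke tests only.

# Numerical choices

* **Array convention.** Volumes are base-R arrays indexed
  `[z, y, x]`, 1-based, column-major. All coordinates in spot tables
  are 1-based voxel indices.
* **Flat-field** (`estimateFlatfield`): the per-pixel median across
  many planes cancels plane-varying content and retains the static
  shading, which is smoothed with a wide Gaussian (sigma = min
  dimension / 8) and normalised to spatial mean 1. Correction is
  `(image − darkfield) / flatfield`. This is the classic retrospective
  (calibration-free) estimator; it assumes shading is smooth and
  content is uncorrelated across planes — it cannot recover abrupt
  vignetting and needs ≥ 8 planes to be stable.
* **Median filter** (`medianFilter3D`): a hand-written true 3D kernel
  with reflected borders (validated voxel-exactly against a
  brute-force oracle). Note that a 3×3×3 median strongly attenuates
  structures thinner than ~1.5 voxels along any axis; with the
  simulator's 0.25 µm spots and 0.5 µm z-pitch the axial profile is
  exactly such a structure, so spot detection is measured both with
  and without it (see the acceptance notes below).
* **Registration** (`registerRounds`): exhaustive search over integer
  shifts within `maxShift`, maximising the Pearson correlation over the
  overlap region; ties break toward the smaller shift. Integer search
  is exact and deterministic — subpixel registration is out of scope
  because the generator's drift is integer by construction (as is the
  common practice of nearest-voxel resampling). Rounds are registered
  to round 1's membrane channel; the negated shift is applied to every
  channel.
* **Segmentation** (`segmentCells`): nuclear seeds are local maxima of
  the smoothed DAPI channel above an Otsu threshold of that smoothed
  volume (robust to the nuclear fill fraction), the foreground mask
  is Otsu on the smoothed membrane+DAPI sum, and cells grow by a
  priority-queue seeded watershed on the membrane image (6-connected,
  FIFO tie-breaking, deterministic). Labels are renumbered in seed
  (z, y, x) order so output is reproducible.
* **Spot detection** (`detectSpots`): negated Laplacian of Gaussian at
  the spot scale; peaks are strict local maxima above
  median + 8 MAD of the response (with a small relative floor so a
  featureless volume yields nothing). The multiplier 8 was fixed a
  priori from the design SNR (amplitude 1000 vs noise sd 10), not fit
  to outcomes.
* **Intensity gating** (`kmeansSignalGate`): 1-D k-means on
  log10 intensity per (FOV, round, channel). The 1-D optimum is always
  a contiguous partition of the sorted values, so we solve it *exactly*
  by dynamic programming — deterministic and globally optimal, with no
  seeding heuristics. The highest-mean cluster is "signal". Spots are
  labelled, never deleted.
* **z-scores** (`zscoreCounts`): population sd (divide by n), so a
  two-cell group yields −1 / +1 exactly; zero-variance genes get an
  all-zero row segment and a flag rather than NaN. `per_stage` pools
  all FOVs of a stage; `cross_stage` pools everything ("through
  genes").
* **Clustering** (`hierarchicalCluster`): `stats::hclust` + `cutree`;
  default 1 − Pearson correlation with average linkage; Ward is
  restricted to euclidean (Ward on non-euclidean dissimilarities is not
  well-formed).
* **Co-expression gates** (`gateCoexpression`): strict z > 0
  intersection across the module's genes; zero is excluded.
* **Back-mapping** (`backmap`): label → colour LUT, either one z-plane
  or a full-footprint projection that prefers coloured labels so a
  highlighted cell is never hidden by an unhighlighted one above it.

# What the validation does and does not show

The acceptance suite demonstrates *internal correctness* — each stage
recovers what the generator planted, and algorithmic steps match
independent oracles — at desk scale (tens of cells, 10⁵–10⁶ voxels per
FOV). It does not show biological findings: headline numbers from real
tissue studies (thousands of cells per stage, specific module-overlap
percentages, differential-expression counts) depend on real data and
are out of scope. Specific limitations:

* The simulator's cells are convex Voronoi polyhedra; real cells are
  not, and watershed quality on real membranes will be worse.
* Spot collisions: at the default density ~3 % of spots fall within the
  match radius of another spot of the same channel and are
  fundamentally unresolvable; exact counting is therefore only claimed
  in the resolvable-spot preset.
* Illumination recovery assumes smooth shading; the quadratic planted
  field matches that assumption by design.
* Registration is integer-voxel, matching the generator's drift model.

# Worked example

```{r example}
cfg <- simPreset("tiny", seed = 1)
sim <- simulateSection(cfg)
length(sim$stacks)            # FOVs
dim(sim$stacks[[1]][[1]])     # (z, y, x, channel)
sim$codebook
```

Run the full pipeline on a simulated section and inspect the products:

```{r pipeline}
out <- file.path(tempdir(), "muxfish-demo")
man <- runPipeline(list(seed = 1, simulate = list(preset = "tiny"),
                        cluster = list(k = 2)), out)
man$stages
counts <- readCountsMTX(file.path(out, "counts"))
counts
```

Normalise, cluster and gate:

```{r analyse}
counts <- zscoreCounts(counts, mode = "per_stage")
cl <- hierarchicalCluster(counts, k = 2)
table(clusterLabels(cl))
gate <- gateCoexpression(counts, GeneModule("demo", c("PouV", "Nanog")))
gate
```

Back-map the clusters onto the section:

```{r render}
labs <- loadLabels(file.path(out, "labels_fov1.tif"))
img <- backmap(labs, cellColoring(cl, fov = 1))
dim(img)
```

# Session info

```{r session}
sessionInfo()
```
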