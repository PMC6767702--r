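---
title: "Quantifying cochlear innervation in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cochlear innervation in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaq)
```

## The problem

Afferent ribbon synapses of cochlear inner hair cells (IHCs) are routinely
counted and measured from 3D confocal stacks of immunolabeled organs of
Corti: CTBP2 marks presynaptic ribbons, synapsin marks efferent terminals,
and hair-cell nuclei give the denominator for per-cell densities. Three
quantitative questions recur:

1. How many puncta per hair cell, and how does that density change across
   development (pruning) and between groups?
2. How are IHC ribbons distributed along the **pillar–modiolar axis** of the
   cell, and do modiolar ribbons carry larger volumes than pillar ribbons
   (the volume gradient that correlates with afferent fiber physiology)?
3. How far is each afferent ribbon from its nearest efferent terminal, and
   does that distance increase as efferent innervation consolidates below
   the IHCs with maturation?

`cochleaq` implements these analyses on exported point tables, and — because
raw micrographs for published studies of this kind are rarely deposited —
pairs them with a synthetic scene generator carrying complete ground truth,
so that every stage is validated by parameter recovery rather than by
eyeballing.

## Pillar–modiolar classification

The classifier works per stack:

1. Fit the first principal axis (centroid + dominant eigenvector of the
   centered covariance) to the ribbon cloud, and separately to the nuclei
   cloud.
2. Take the two *extent points* of the ribbon axis — the projections onto
   the fitted line of the data points with minimal and maximal scalar
   projection — plus the centroid of the nuclei axis. These three points
   define the separating plane. A coordinatewise min/max of a general 3D
   line has no unique meaning, so the extreme-projection reading is used: it
   is the only construction that yields two well-defined points lying on the
   fitted line.
3. Orient the plane's unit normal so that a caller-supplied **landmark
   point** lies on the positive side; that side is *pillar*. Anatomically
   the landmark should be a structure known to sit on the pillar side, e.g.
   the OHC-region centroid (the generator emits exactly that); a spiral
   ganglion direction point would mark the modiolar side and must then be
   mirrored by the caller. Making the landmark explicit keeps orientation
   decidable and auditable instead of implicit in sign conventions.
4. Label each ribbon by the sign of its signed distance to the plane.
   A distance of exactly 0 is labelled pillar and flagged: the event has
   measure zero, and determinism matters more than the choice.

Eigenvector sign is made deterministic by forcing a positive component along
+x (falling back to +y, then +z), so results do not depend on the
linear-algebra backend. Degenerate inputs — fewer than 3 points, a
numerically coincident cloud, a nuclei centroid on the ribbon axis, a
landmark on the plane — raise errors rather than guessing; the nuclei-on-axis
case advises a wider field of view because the plane is genuinely undefined
there.

Ribbon volumes are normalized per stack by the **median volume over all
ribbons of that stack** (not per side), which makes volume gradients
comparable across stacks acquired with different gain. Normalization is
idempotent and refuses non-positive medians. No ribbons are excluded prior
to normalization.

## Densities, fold changes, distances

Per-cell density is the exact rational `puncta / cells`; printed one-decimal
values are presentation only. Developmental fold change is the young/old
density ratio, also reported as the nearest integer fold. Nearest-neighbor
distances are directional (each *source* punctum to its nearest *target*
punctum, within one stack only — coordinate frames differ across stacks).
The accelerated search bins targets into a uniform grid and expands
Chebyshev rings until the running minimum is provably optimal; because
candidate distances use the same arithmetic as the all-pairs scan and always
include the true nearest neighbor, it equals brute force bit for bit —
exactness is the contract, approximate NN is deliberately not offered at
these problem sizes. The maturation comparison reports the difference of
mean distances with its standard error and a pointwise ECDF dominance flag
(mature curve at or below immature everywhere within a small tolerance,
default 0.02) marking a rightward shift.

## Group statistics

Independent samples are compared with a one-way fixed-effects ANOVA
(`stats::lm`/`anova`). For repeated measurements within individuals, the
individual is the inferential unit: measurements are aggregated to
per-subject means and the one-way ANOVA runs on those means. A full
random-effects likelihood (e.g. `lme4`) is a documented extension point; the
aggregation route was chosen because it is transparent, conservative, needs
no covariance-structure assumptions, and matches reporting conventions in
which n is the number of individuals. Groups retaining a single subject are
kept but flagged, with degrees of freedom reduced accordingly. Post hoc
pairwise tests use t statistics on the pooled within-group mean square with
Bonferroni multiplication (raw p times the number of pairs, capped at 1);
planned comparisons skip the correction. Stars: `*` p < 0.05, `**` p < 0.01.

## The synthetic scene generator

`generate_scene()` emulates a mid-cochlear field of view in µm coordinates
(z = optical axis): one row of IHC nuclei along x (optionally on a circular
arc; default straight, appropriate for short segments), 1–4 OHC rows offset
to the pillar side, ribbons in a band below each IHC displaced by
±`pm_offset_um` along the local pillar–modiolar normal, log-normal ribbon
volumes with modiolar draws scaled by `modiolar_pillar_volume_ratio`, and
efferent terminals placed by developmental stage: *mature* terminals
consolidated in a sub-nuclear band, *immature* terminals split between an
axosomatic band above the nuclei and a band overlapping the ribbons.
Identical configurations (including the seed) generate identical scenes, and
the caller's RNG stream is untouched.

Choices worth stating explicitly:

* **Counts are Poisson, volumes log-normal.** Published tables report
  means ± SEM only; these are the minimal generative assumptions that
  reproduce mean/SEM structure.
* **Side labels use exact allocation**, `round(n × pillar_fraction)` pillar
  labels randomly permuted, rather than i.i.d. Bernoulli draws. Binomial
  sampling noise at n = 2000 (SD ≈ 0.011) would otherwise dominate the
  ±0.01 fraction-recovery tolerance the recovery tests check; exact
  allocation makes those tests measure the classifier, not the generator.
* **Volume dispersion defaults to `volume_log_sd = 0.8`.** Published
  per-side SEMs at their N imply a coefficient of variation near 0.8, and a
  log-normal with σ = 0.8 reproduces the published normalized side means
  (≈0.95 pillar / 1.77 modiolar at ratio 1.86 and 44/56 fractions) under
  median normalization. The volume-ratio *recovery* tests instead use
  σ = 0.3, chosen by power analysis so that the Monte Carlo error of the
  check (≈2.6% at n = 1000) sits below the 5% recovery tolerance being
  verified; at σ = 0.8 the sampling error of the ratio estimator alone is
  ≈6% and no implementation could pass robustly.
* **`pm_offset_um` (default 3 µm) is a parameter, not a biological claim** —
  the physical pillar–modiolar displacement of ribbon positions is not well
  established. Note that when the pillar fraction p is unbalanced, the
  fitted ribbon axis shifts toward the majority side, so the minority-side
  margin against jitter is `pm_offset_um × (1 − |2p − 1|)`: recovery tests
  targeting perfect agreement use offset/jitter = 10 so the worst-case
  margin across the tested fraction grid stays near 6σ.
* **Gerbil-like presets** (`scene_config_gerbil()`) carry per-cell ribbon
  and efferent counts from the published gerbil ages and efferent placement
  calibrated by bisection — against 60 replicate 20-IHC scenes per
  evaluation — so the ribbon→efferent mean nearest-neighbor distance matches
  the published immature/mature means (1.61/2.15 µm). At the 20-IHC field
  size, the immature target is not reachable by shifting the sub-nuclear
  z-band alone (the response is non-monotone with a minimum near 1.64 µm),
  so the immature preset calibrates the lateral efferent scatter
  (1.5832 µm) at a fixed band; the mature preset calibrates the z-band
  (−9.96 to −5.94 µm) at the default scatter. These presets are calibration
  targets, not blind predictions.

What the generator does *not* emulate: stereocilia geometry, tonotopic
gradients within a field, anisotropic or spatially varying noise, nucleus
shape (nuclei are points), ribbon clustering within a cell, or real
microscope optics. Passing recovery tests therefore demonstrates that the
*algorithms* are correct under the stated geometric assumptions — not that
segmentation of real micrographs is solved.

## Rendering and spot detection

`render_stack()` draws each punctum as a 3D Gaussian whose per-axis sigma
combines the PSF with an object sigma derived from the punctum volume (the
half-maximum ellipsoid of the object Gaussian has exactly that volume) and
whose summed intensity equals the volume. Gaussian or Poisson noise is
seeded separately from the scene, so noiseless renders are bitwise
deterministic.

`detect_spots()` is a scale-space Laplacian-of-Gaussian detector:
geometrically spaced scales between `sigma_min_um` and `sigma_max_um`
(default 5 scales, 0.25–0.9 µm), per-axis sigmas divided by the voxel size
so anisotropic sampling is handled, scale-normalized responses, 3×3×3 local
maxima that also dominate across scales, a peak threshold at 10% of the
global maximum response, and greedy non-maximum suppression at the detected
scale. LoG was preferred over intensity thresholding because the scenes
deliberately contain a within-stack volume (hence brightness) gradient.
`measure_volumes()` grows, per seed, the 6-connected region above 50% of the
seed's peak intensity, resolves contested voxels to the nearest seed
(watershed-free: adequate at fixture densities), and converts voxel counts
to µm³; seeds with empty regions get one voxel volume and a flag. No attempt
is made to match any commercial package's numbers; the detector exists so
the pipeline can be exercised end-to-end from images with known truth.

## Problem sizes and tolerances used in validation

The test suite and acceptance script run at deliberately moderate sizes:
recovery grids at ~2000 ribbons per fraction (120 IHCs), ratio recovery at
~1000 ribbons, 50 random scenes (n ≤ 200) for the exact-equality check of
the accelerated distance search, 20 random rigid motions at tolerance 1e-9,
six replicate individuals per efferent stage for the distance-shift check
(tested against the calibration targets with a t-based 95% interval on the
per-individual means), a 100-blob rendered fixture for detection
(recall = precision = 1, Spearman ρ > 0.95 on volume ranks), and 2000–5000
null replicates for ANOVA calibration (type-I error ≤ 0.06 at α = 0.05).
These sizes give stable Monte Carlo behavior while keeping a full run in the
order of half a minute.

## Known limitations

* The separating boundary is a plane; strongly curved fields should be cut
  into shorter segments first (per-stack analysis does this naturally).
* Classification is per stack, not per cell.
* Subject-aware ANOVA by aggregation discards within-subject information;
  with very unbalanced designs a mixed-effects model would be more
  efficient.
* The detector is not a segmentation tool for real, noisy, touching puncta;
  it is a validated stand-in with honest behavior on well-separated blobs.
* Printed group means from real animals cannot be recomputed from scratch
  here (no micrographs are deposited); they enter only as generator
  calibration values and as worked-example arithmetic.
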