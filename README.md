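# cochleaq

Quantitative 3D analysis of cochlear hair-cell innervation from
immunofluorescence point clouds.

Auditory researchers count and measure synaptic immunopuncta — CTBP2-labeled
presynaptic afferent ribbons, synapsin-labeled efferent terminals, BK-channel
puncta — in confocal stacks of the organ of Corti, and export their 3D
coordinates and volumes from reconstruction software. `cochleaq` takes those
point tables and computes the standard quantities of this literature:

* **puncta-per-hair-cell densities** and developmental **fold changes**
  (pruning of supernumerary synapses);
* **pillar–modiolar classification** of IHC afferent ribbons with per-stack
  median-normalized volumes, quantifying the modiolar > pillar ribbon volume
  gradient;
* **afferent-to-efferent nearest-neighbor distances** and their cumulative
  distributions, quantifying the developmental consolidation of efferent
  terminals below the IHCs;
* group comparisons by one-way and subject-aware ANOVA with
  Bonferroni-corrected post hoc tests.

Because raw micrographs for studies of this kind are generally not deposited,
the package also ships a **synthetic organ-of-Corti scene generator** with
complete ground truth (true side labels, true volumes, true placements), a
Gaussian stack renderer and a Laplacian-of-Gaussian spot detector, so the
entire pipeline is testable by parameter recovery.

## The core algorithm

For each stack, principal axes are fit (PCA) to the ribbon cloud and to the
nuclei cloud. The separating plane of the pillar–modiolar axis is the plane
through three points: the two extreme projections of the data onto the
ribbon axis, and the centroid of the nuclei axis. Its normal is oriented by
an anatomical landmark known to lie on the pillar side (e.g. the OHC-region
centroid), and each ribbon is classified by the sign of its signed distance
d(x) = n·x − n·a:

    side(x) = pillar   if d(x) ≥ 0
              modiolar if d(x) < 0

Ribbon volumes are normalized to the median volume of their own stack before
per-side means ± SEM and the modiolar/pillar ratio are reported. Euclidean
nearest-neighbor distances use an exact grid-accelerated search that equals
the all-pairs computation bit for bit.

## Worked example

```r
library(cochleaq)

cfg <- scene_config(n_ihc = 20, pillar_fraction = 0.44,
                    modiolar_pillar_volume_ratio = 1.86, seed = 42)
scene <- generate_scene(cfg)
scene
#> <synthetic_scene> 20 IHC, 60 OHC; 285 IHC ribbons (125 pillar / 160 modiolar),
#>   139 OHC ribbons, 599 efferent terminals (mature stage)

res <- classify_stack(scene$ribbons, scene$ihc_nuclei, scene$landmark_point)
res$summary
#>      side   n  fraction mean_volume sem_volume
#>    pillar 125 0.4385965    1.061247 0.08549752
#>  modiolar 160 0.5614035    1.843944 0.11973000
#> modiolar/pillar mean volume ratio: 1.738

mean(res$partition$side == scene$ribbons$annotations$true_side)
#> [1] 1

density_per_cell(scene$ribbons, scene$ihc_nuclei)
#> <density_summary> 285 puncta / 20 IHC = 14.2 per cell

nn_distances(scene$ribbons, scene$efferents)
#> <distance_distribution> CTBP2 -> synapsin: n = 285, mean 2.199 um (SEM 0.046)
```

The classifier recovers every ground-truth side label; the recovered pillar
fraction (43.9%) matches the configured 0.44 up to integer rounding; the
recovered volume ratio (1.74) estimates the configured 1.86 at this sample
size; and the mean ribbon→efferent distance (2.20 µm) reflects the mature,
consolidated efferent placement. Real data enter the same way via
`read_puncta_table()` / `read_hair_cell_table()` on CSV exports (columns
`stack_id, channel, x_um, y_um, z_um[, volume_um3]`).

Thin command-line wrappers over these functions live in `inst/scripts/`
(`simulate.R`, `classify.R`, `distances.R`).

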