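# smfish3d

3D analysis of single-molecule RNA FISH (smFISH) z-stacks: per-channel
spot detection with automatic threshold selection, object-based
dual-channel co-localization, and per-region transcript quantification —
with a seeded synthetic-scene generator so every stage is validated
against known ground truth.

## Who this is for

smFISH renders each mRNA molecule as one diffraction-limited fluorescent
dot. In thick specimens (organoids, tissue) dots must be segmented and
counted in 3D, and the standard specificity control — two probe sets with
distinct fluorophores tiling different regions of the *same* transcript —
requires pairing dots across channels in 3D rather than on projections.
This package is for anyone quantifying smFISH z-stacks who needs
reproducible spot counts, dual-channel co-localization ratios, and the
derived per-ROI quantities (mRNA per cell, normalized expression,
regional count ratios).

## The method

Per channel, the raw stack is binarized at a channel-specific threshold
*t*; connected components of the binary volume (26-connectivity) are
taken as candidate dots and filtered by voxel volume,
*V*<sub>min</sub> ≤ |*c*| ≤ *V*<sub>max</sub>. The threshold is chosen
from the curve *N*(*t*) of detected-dot count versus threshold: *N*(*t*)
falls steeply through the background and plateaus where every true dot is
segmented, and *t*\* is placed at the flattest point (minimum
|d*N*/d*t*| of the smoothed curve) of the decaying branch — the curve's
inflection/plateau point.

Dots in channels A and B co-localize when the Euclidean distance between
their intensity-weighted centroids is strictly below *d*<sub>max</sub> = 3
voxels (z counted in plane indices). Each dot pairs with at most one dot
in the other channel (greedy, ascending distance), and both directional
ratios |pairs|/|A| and |pairs|/|B| are reported. Derived quantities are
exact quotients of integer counts: mRNA/cell = spots / nuclei per ROI,
normalized expression = target / reference counts, regional ratio =
counts in two named ROIs.

## Worked example

Simulate a ground-truth scene in which half the spots are shared between
the two channels, detect spots in both, and match them:

```r
library(smfish3d)

scene <- simulate_scene(scene_params(coloc_fraction = 0.5, seed = 7))
det_a <- detect_spots(scene$a)
det_b <- detect_spots(scene$b)
det_a
#> <spot_set> channel 'A': 200 spots (threshold 64.68)

evaluate_detection(det_a, scene$truth$spots_a)[c("recall", "precision", "rmse")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
#> $rmse
#> [1] 0.08968733

m <- match_spots(det_a, det_b, d_max = 3)
m
#> <match_result> 101 pairs (d < 3 voxels); A 'A': 200 spots, B 'B': 200 spots
#>   A-in-B: 0.505   B-in-A: 0.505
```

All 200 true spots per channel are recovered (recall and precision 1)
with centroids ~0.09 voxels from their true subvoxel positions, and the
matcher recovers the designed 50% shared fraction (101/200 = 0.505; the
one extra pair is a chance pairing). Quantification is then plain
arithmetic on the counts:

```r
mrna_per_cell(nrow(det_a$spots), nucleus_count = 25)
#> [1] 8
coloc_ratio(m, "a_in_b")
#> [1] 0.505
```

For real data, `read_stack()` loads grayscale TIFF z-stacks,
`extract_roi()` cuts 300×300-pixel regions of interest through the full
z-range, and `run_pipeline()` drives the whole analysis from a YAML
config over a batch of samples, writing spot tables, pair tables,
quantifications and a JSON summary (including the selected per-channel
thresholds) per ROI. A thin command-line wrapper with subcommands
`simulate`, `detect`, `coloc`, `quantify` and `run` is installed at
`inst/cli/smfish3d`.

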