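---
title: "Methods: 3D smFISH spot detection and co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D smFISH spot detection and co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfish3d)
```

## The problem

Single-molecule RNA FISH (smFISH) tiles a transcript with dozens of singly
labeled oligonucleotide probes, so each mRNA molecule appears as one
diffraction-limited fluorescent dot in a 3D z-stack. Counting those dots
counts molecules. When two probe sets with distinct fluorophores target
different regions of the *same* transcript, a genuine molecule should
produce a dot in both channels at (nearly) the same position — so the
fraction of dots in one channel that pair one-to-one with a dot in the
other channel is a stringent, built-in specificity control. This package
implements that analysis for thick specimens such as intestinal organoids:
per-channel 3D spot segmentation, object-based dual-channel
co-localization, and the per-region quantities derived from the counts.

Working in 3D matters. Quantifying a single plane undercounts molecules,
and matching dots on a maximum-intensity projection pairs dots that are
far apart axially; both biases disappear when segmentation and matching
use the full volume.

## Spot detection

For one channel the detector is fully deterministic:

1. **Threshold scan.** For each of `n_threshold_levels` (default 100)
   evenly spaced intensities strictly between the stack minimum and
   maximum, the stack is binarized (foreground strictly greater than the
   threshold), 3D connected components are labeled, components outside
   the volume window are dropped, and the surviving component count is
   recorded. Counts reflect the *final* spot definition — the volume
   filter is applied before counting — so the curve is the number of
   spots the pipeline would report at each threshold.
2. **Threshold selection.** The count-versus-threshold curve falls
   steeply while the threshold ascends through background noise, then
   flattens into a plateau where every true dot and nothing else is
   segmented, and finally decays as dim dots are lost. The working
   threshold is the inflection/plateau point: after smoothing the counts
   with a centered moving average (window 5 levels), the level with the
   smallest absolute slope is selected. Two guards make this robust.
   Candidates are restricted to the decaying branch at or after the
   curve's maximum, because below the background level the entire
   foreground fuses into one oversized component which the volume filter
   removes — a meaningless zero-count flat that would otherwise win.
   Zero-count levels on the decaying branch itself remain eligible, so a
   stack with no real spots selects a threshold above the noise and
   correctly reports zero detections. The outer 5% of levels on each side
   is excluded, ties break toward the lower threshold (which lands a tied
   plateau at its lowest level), and a completely flat interior is
   flagged. A `manual_threshold` overrides the scan entirely.
3. **Segmentation and measurement.** Connected components are computed
   under 26-connectivity by default — diagonal-touching voxels of one
   point-spread function belong to one dot; 6-connectivity is available.
   Components with volume outside `[min_volume, max_volume]` (defaults 2
   and 200 voxels) are discarded: the lower bound removes single-voxel
   noise, the upper bound implausibly large blobs. Survivors are measured:
   volume, total and peak intensity, and centroid. Centroids are
   intensity-weighted by default, giving subvoxel accuracy that the
   3-voxel matching rule benefits from; plain binary-mask centroids are a
   config switch for strict parity with unweighted pipelines.

Foreground is *strictly* greater than the threshold; ties go to
background. This makes results reproducible across platforms regardless
of how intensity grids interact with the threshold grid.

## Co-localization

Spots in two channels co-localize when the Euclidean distance between
their centroids is strictly below `d_max` = 3 voxels, with the z axis
counted in plane indices (one unit per plane, no physical anisotropy
correction — the cutoff is stated in voxels; an optional per-axis scale
exists for users who want micrometre distances). To avoid overestimating
co-localization, each spot pairs with at most one spot in the other
channel. Pairing is greedy in ascending distance: all candidate pairs
below the cutoff are sorted by distance (ties by lower id in channel A,
then B) and accepted unless either member is already taken. The pair set
is symmetric under swapping the channels, and the test suite keeps an
independent maximum-cardinality matching oracle alongside the greedy
matcher to quantify any shortfall (on random small instances it is
essentially nil). Both directional ratios — pairs/|A| and pairs/|B| —
are always reported, since the two probe sets need not be equally
specific. Empty reference channels raise an error rather than reporting
a silent 0.

## Quantification

All derived quantities are plain quotients of integer counts and are
reproducible bit-for-bit: mRNA per cell (spot count over nucleus count in
the same ROI), normalized expression (target channel count over reference
channel count, same ROI for both channels), and regional ratios (counts
in two named ROIs of one channel, e.g. organoid body over crypt).
Undefined ratios (zero or missing denominators) raise errors; the batch
driver records the error for that ROI and continues. Nucleus counts are
an input: manual counts from the ROI table always take precedence, and
the optional automatic counter (Otsu threshold taken as the median of
per-plane Otsu levels, 3D components, size filter 100–10,000 voxels) is
flagged `"automatic"` in every output so the two are never conflated.
The upper size bound is what lets a spot-free noisy counterstain report
zero nuclei: near-unimodal noise histograms make Otsu cut inside the
noise, producing one percolating foreground mass far larger than any
nucleus.

Quality control mirrors what one checks in a real experiment: across the
spots of a channel, volume should correlate linearly with integrated
intensity (Pearson r; diffraction-limited dots differ mainly in
brightness, and brighter dots threshold to slightly larger components),
and the volume distribution should be unimodal (a second mode suggests
doublets or debris). The volume histogram is reported at a fixed bin
width of 1 voxel for plotting. The *mode count*, however, is computed on
a Sturges-binned histogram lightly smoothed with a 3-point moving
average: with a few hundred spots, width-1 bins hold single-digit counts
whose sampling noise creates spurious local maxima. The choice was
validated against known truth — unimodal detected-volume samples and
synthetic two-component mixtures (30 seeds each): the smoothed-Sturges
counter read 29/30 unimodal samples as one mode and 30/30 bimodal
mixtures as two, while KDE-based counting and heavier smoothing both
misread substantially.

## The synthetic-data generator

Every stage is validated on simulated scenes with exact ground truth,
because the method's claims (recall, precision, recovered co-localization
fractions) are only checkable when the true catalog is known.

A scene renders each spot as an anisotropic 3D Gaussian (truncated at 3
sigma) at a continuous subvoxel position, adds a uniform background and
i.i.d. Gaussian noise (a light-weight approximation to Poisson shot
noise), and renders ellipsoidal dome-profile nuclei in a counterstain
channel. A fraction `f` of channel-B spots sit at channel-A positions
plus per-axis Gaussian jitter, emulating two probe sets on one
transcript; `round(f * n_spots)` are shared, and the catalog records the
pairing. Defaults, chosen once as a realistic organoid acquisition:

| parameter | default | rationale |
|---|---|---|
| shape | 12 × 300 × 300 | a 300 × 300-pixel ROI through a ~18 µm stack at ~1.5 µm steps |
| spot sigma (z, y, x) | 1.0, 1.5, 1.5 voxels | diffraction-limited dot, axially coarse sampling |
| amplitude | N(200, 20) over background 20 | peak SNR 20 at noise sd 10 |
| noise sd | 10 | moderate camera/shot noise |
| jitter sd | 0.5 voxel | sub-voxel probe-set offset |
| min separation | 7 voxels | neighboring PSFs stay resolvable at plateau thresholds; keeps density below ~5 × 10⁻⁴ /voxel |
| nuclei | 25 ellipsoids, semi-axes (2.5, 9, 9) | tens of cells per ROI |

Spot placement is uniform within a 3-sigma margin with rejection sampling
under the minimum separation (bounded retries, then an explicit
placement error). Identical parameters and seed give bit-identical
stacks and catalogs, and the generator restores the session RNG state.

What the generator does **not** emulate: optical aberrations and depth-
dependent attenuation, true Poisson statistics, autofluorescent debris,
clustered transcription sites, organoid geometry (lumen/crypt shapes),
and touching nuclei. Passing tests therefore demonstrate the
*algorithmic* contracts — thresholding, segmentation, matching,
bookkeeping — under controlled conditions, not performance on any
particular microscope's data. Regional-ratio tests use two independently
parameterized ROIs rather than simulated organoid morphology.

## Numerical and design choices

- **Axis order and indexing.** All arrays are `(z, y, x)`; all
  coordinates are 1-based voxel indices (R convention), with ROIs given
  as origin plus per-axis extent. One global, documented convention
  prevents silent axis swaps; channel pairing is likewise by explicit
  label, never file order.
- **Threshold grid.** 100 levels balances curve resolution against
  runtime; the grid excludes the exact min and max (both degenerate).
- **Connected components in compiled code.** The scan labels the stack
  at ~100 thresholds, so labeling is implemented in C++ (stack-based
  flood fill; for the scan, voxels are pre-sorted by intensity so each
  level only visits its own foreground). An independent brute-force R
  flood fill serves as the oracle in the tests.
- **Strictness.** Both the binarization (`> threshold`) and the matching
  cutoff (`< d_max`) are strict, documented, and boundary-tested.
- **Exactness.** Distances use per-axis differences (identical points
  give exactly zero); derived ratios are exact quotients.
- **Degenerate inputs.** Constant stacks are errors for detection and
  nucleus counting; empty spot sets make ratios errors (undefined), not
  zeros; curves that are entirely flat are flagged.

## Problem sizes used in validation

The shipped validation uses 12 × 300 × 300 scenes with 200 spots per
channel (peak SNR 20) across 10 seeds for detection recovery and
threshold-plateau checks; a five-point grid of shared fractions
f ∈ {0, 0.25, 0.5, 0.75, 1} at 10 seeds per point for co-localization
recovery (the f = 0 point uses 108 spots, i.e. 10⁻⁴ spots/voxel, the
regime for assessing chance pairing); 500 random small instances for
matching-rule fidelity; and 200 random 8 × 8 × 8 masks per connectivity
for the labeling oracle. Interior grid points are judged against three
binomial standard errors of the designed fraction; the endpoints have
zero binomial width and are judged by their own bounds (chance pairing
at most 0.05 at f = 0; at least 0.95 recovered at f = 1, reflecting that
a shared spot must be detected in both channels to be paired).

## Known limitations

- Overlapping or near-touching dots merge into one component; the
  detector performs no declumping or Gaussian fitting, so counts
  saturate at high transcript density.
- The threshold plateau assumes a reasonable separation of background
  and signal; very low SNR produces a curve without a flat region, and
  the flagged selection should then be reviewed (or overridden manually).
- The automatic nucleus counter is deliberately simple plumbing; it
  undercounts touching nuclei and is no substitute for manual counts,
  which always take precedence.
- Group-level statistics (ANOVA, t-tests) are out of scope; the CSV
  outputs are designed to drop into any statistics environment.
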