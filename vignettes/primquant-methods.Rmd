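---
title: "Measuring the lateral line primordium: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the lateral line primordium: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primquant)
```

## The measurement problem

The zebrafish posterior lateral line primordium (pLLP) is a migrating
cluster of roughly 120 epithelial cells, labeled in vivo by a membrane
GFP (*cldnb:lynGFP*) and imaged as anisotropic confocal Z-stacks. The
quantities of interest are organ-scale: how many cells the primordium
contains, how large it is, how elongated its footprint is, how many
epithelial rosettes it has formed and how cleanly, how active a
transcriptional reporter is inside it, what fraction of its cells are in
S phase, and how neuromast deposition is spaced along the trunk.
Genotype comparisons (Hippo-pathway mutants and overexpression
conditions) are then differences of cohort means, tested
nonparametrically.

`primquant` implements that measurement cascade — registration, 3D
single-cell segmentation, morphometrics, intensity quantification,
statistics — together with a synthetic-data generator that produces
primordium stacks with exact per-cell ground truth, so every stage can
be validated by recovery rather than by eye.

## The synthetic primordium

`simulate_primordium()` builds a tissue from the inside out:

1. **Geometry.** Cell centers are sampled inside an ellipsoid whose
   volume scales linearly with `n_cells` (three times the nominal
   cell-sphere volume of diameter `cell_diameter_um`, default 5.5 µm),
   with in-plane elongation `elongation` (default 2.5) and a depth
   semi-axis at 0.8 of the minor semi-axis. Centers keep a minimum
   spacing of 0.85 diameters (rejection sampling with a bounded attempt
   budget; infeasible requests error out). Because the tissue volume
   scales with the cell count, packing density — and therefore
   segmentation difficulty — is the same for a 96-cell mutant and a
   225-cell overexpression arm.
2. **Rosettes.** Each rosette is a ring of cells around a center
   (`rosette_radius_um`, default 8 µm; the ring pitch gives 12 members
   at defaults). Rosette cells model apically constricted wedges: filler
   cells are excluded from the central half-depth of the rosette
   cylinder, so the radial walls project coherently, without inflating
   member volumes to implausible sizes.
3. **Partition and membrane.** The ellipsoid interior is partitioned by
   anisotropy-aware nearest-center assignment; this Voronoi partition
   *is* the ground truth, so per-cell volumes are exact by construction.
   Interior walls are rendered analytically: a Gaussian intensity
   profile of width `membrane_width_um` centred exactly on the bisector
   between the two nearest centers, weighted by the membrane area a
   plane of that orientation sweeps through one voxel. At the default
   (1, 0.4, 0.4) µm spacing this makes lateral walls about 2.5 times
   brighter per voxel than flat apical caps — the reason maximum
   projections of real membrane labels show crisp cell outlines. The
   outer surface is rendered from boundary faces and blurred. The sum is
   normalized against its 99.5th percentile (detector-saturation style)
   so typical walls sit near 1 on the [0, 1] intensity scale.
4. **Nuclei and EdU.** Nuclear channels are Gaussian blobs at the cell
   centers; an optional EdU channel marks a random subset of nuclei
   (`edu_fraction`).
5. **Noise.** Poisson shot noise at `photon_scale` (default 120 photons
   per unit intensity) followed by additive Gaussian read noise
   (`noise_sd`, default 0.03). `noise_sd = 0` switches the generator to
   a fully deterministic, noise-free mode used by exactness tests.

What the generator does **not** emulate: a realistic PSF (walls have a
fixed Gaussian cross-section rather than a diffraction-limited one),
depth-dependent attenuation, migration dynamics, or biological shape
irregularity beyond Voronoi geometry. Passing recovery tests on these
synthetics therefore demonstrates that the pipeline is unbiased when its
geometric assumptions hold — not that it would be unbiased on any real
stack. The same caveat applies to the paper-anchored effect sizes: the
generator injects them by construction; recovery tests validate the
measurement chain, not the biology.

## Genotype presets

`genotype_presets()` encodes each experimental condition as a
multiplier on the wild-type mean of 120 cells, a reporter-intensity
multiplier, and a "diving" (mispositioned migration) probability:
−20% for *yap1* loss, +35% for *vgll4b* loss, +50% for the
*vgll4b;vgll4l* double, −20% for *vgll4b* overexpression, a further
+25% for *yap1* overexpression on the double-mutant background, and
−10% for the triple mutant; reporter changes of +70% (*yap1* OE),
−12% (*yap1* knockdown) and +27% (*vgll4b* knockdown); diving rates of
1.29% (wild type), 16% (*yap1*), 68% and 25% for *vgll4b*/*vgll4l*
overexpression in *yap1* mutants. The printed triple-mutant numbers
(−10% vs wild type, ~+30% vs *yap1*) are mutually inconsistent with the
−20% *yap1* effect under exact arithmetic; the preset anchors to the
wild-type-relative value, and comparisons against the *yap1* arm follow
from the multipliers (0.90/0.80 ≈ +12.5%).

The cohort generator draws per-embryo counts from a rounded normal with
coefficient of variation `count_cv = 0.08`. No dispersion is stated for
the real cohorts (plots show SD only); 8% keeps 20-embryo arms tight
enough to resolve a 10-percentage-point effect, which is what the
smallest printed contrast requires. Each embryo also receives a
uniform ±15° mounting tilt so that cohort-level runs genuinely exercise
the registration stage.

## Registration

The footprint mask comes from a maximum Z-projection, a 2 µm Gaussian
blur, and the classic bimodal-minimum histogram threshold (256 bins
smoothed with a 3-bin running mean until exactly two maxima remain;
threshold at the valley). The second-central-moment ellipse of the mask
gives the orientation; every slice is rotated by the negated angle with
bilinear interpolation (nearest-neighbour for label volumes), cropped in
X/Y to the rotated mask bounding box plus 5 µm.

The Z-crop keeps the contiguous slice range whose in-mask upper-decile
intensity clears the out-of-mask background mean by two SDs, padded by
one slice. Two deliberate departures from the naive rule are worth
recording: the criterion uses the upper decile rather than the mean
(edge slices hold tissue in only part of the footprint, and a mean-based
rule amputates the outer cell layer), and zero-filled pixels introduced
by rotation are excluded from the background statistics. Thresholding is
performed once, before rotation; the mask is carried through the
transform rather than re-estimated on the cropped stack, whose histogram
is often no longer bimodal.

## Segmentation

The blurred membrane channel (default σ = 0.5 µm, anisotropy-corrected)
is treated as a topographic relief. Minima shallower than `h_depth` are
suppressed by morphological reconstruction (h-minima); the surviving
regional minima become markers; minima components touching the stack
border seed the background; and a priority-flood (Meyer) watershed
assigns every voxel, so there are no zero-width boundary lines. Two
tie-break rules matter at membrane crests: proposals arriving from the
darker side win exact-value ties (a crest voxel belongs to the side of
the midplane it sits on), and background proposals carry an epsilon
handicap so the bright outer shell stays with the cells.

`h_depth` defaults to 0.03 on the [0, 1] scale. At 0.05 the
register-then-segment pipeline under-segments by 4–5%: bilinear
rotation attenuates obliquely oriented membrane ridges, and moderately
weakened walls fall below the deeper tolerance. At 0.03 the full
pipeline recovers cohort means within ~1–2% at realistic tilts while
remaining robust to the default noise level. The monotonicity of label
count in `h_depth` is tested, so the trade this parameter makes is
explicit.

Volume gates (`v_min_um3 = 30`, `v_max_um3 = 3000`) remove debris and
fused segments; the thresholds bracket the plausible single-cell volume
range at this stage (median ≈ 250 µm³) by roughly an order of magnitude
either way. Outlier removal applies `median ± 3.5 × MAD` fences to cell
volume and surface-to-volume ratio — the two features that identify
wrongly segmented skin cells — on the **log** scale, because both are
positive ratio-scale quantities with right-skewed distributions;
linear-scale fences systematically clip the genuine upper volume tail
(3–4% of true cells on synthetic cohorts) and bias counts downward.
Surface areas are exposed-face counts weighted by physical face areas:
exact on rectilinear oracles, biased high against smooth surfaces by a
known factor (≈ 1.5 for a sphere), which is irrelevant for its use as a
relative outlier feature.

## Morphometrics

Shape descriptors follow the particle-analysis conventions: aspect
ratio and roundness from the moment ellipse (axis = 4√eigenvalue),
circularity from a sub-pixel boundary contour whose vertices are
smoothed over a 5-point window (the raw marching-squares polygon
staircases along oblique edges and overestimates smooth perimeters by
~6%), solidity against the pixel-centre convex hull.

The rosette detector replaces a learned scorer with a transparent
geometric one: normalized cross-correlation, on a disk support, between
a maximum projection of the central 30–70% of slices (where apical
constrictions live) and a radial-spoke template, maximized over template
rotations within one spoke period. Twelve spokes match the wall count of
an 8 µm ring at the default cell diameter; the detection floor of 0.4
sits between the scores of true rosettes (≥ 0.5 on clean synthetics) and
of ordinary three-wall junctions (≤ 0.35). The rosettiness statistic —
the sum of detection scores over the number of detections — is preserved
exactly as defined, accepts any external score list, and is deliberately
*undefined* (not zero) when there are no detections. Detection counts
include only supra-floor candidates.

Deposition analysis thresholds a trunk overview (same bimodal-minimum
algorithm), keeps components of at least 20 pixels, sorts centroids
along the anteroposterior axis and subtracts the first (ganglion)
position. The stained-area readout applies the threshold with inverted
polarity for dark chromogenic stain and reports the largest component's
physical area.

## Intensity quantification

`mean_gray()` implements the two published measurement modes (mean of
the average Z-projection over the whole image, which equals the
full-stack mean exactly, and the in-ROI single-plane mean).
Reporter-positive cells and EdU-positive nuclei use the same
operationalization of "significantly higher than surrounding tissue":
mean above background mean + *k* × background SD, with *k* = 2 by
default and per-embryo background (the source gives no explicit rule;
both choices are exposed). Line profiles sample a 3-pixel band at 100
stations, normalize each channel to its own maximum, and the
nuclear-enrichment readout interpolates the target/reference ratio at
relative distance 0.5.

## Statistics

The group test is the two-tailed Mann–Whitney U: midranks for ties;
exact p from the full U distribution (computed by the classic
two-sample recurrence) for untied samples whose labeling table does not
exceed 10⁶; otherwise a normal approximation with tie-corrected
variance and continuity correction; two-tailed p = min(1, 2 × one-tail).
The exact path is verified against brute-force enumeration for all
sample sizes up to 6, and the test's type-I error at α = 0.05 is checked
over 10⁴ null simulations. A Welch t-test is available behind a flag as
a sensitivity check, since the source describes its test ambiguously;
the rank test is the default everywhere. ΔΔCt fold changes average
technical replicates before any statistics (the convention when the
source is silent), and the Wilson score interval backs proportion
readouts such as diving penetrance. No multiple-testing correction is
applied, matching the analysis being reproduced.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state. Default stacks are ~30 × 90 × 210 voxels at
(1, 0.4, 0.4) µm — large enough that a 120-cell tissue is sampled at
~14 voxels per cell diameter in-plane, small enough that a full
register-segment-measure pass takes a few seconds on one core. Recovery
studies in the tests and the acceptance script use 20 embryos per
genotype arm, 10 reporter image pairs, and 50 qPCR plates; these sizes
resolve 5-percentage-point questions without heroic compute. Cohort
contrasts use common random numbers — all genotype arms share one
cohort seed, pairing the per-embryo draws — so a measured percent
change reflects the preset effect rather than two independent
20-sample means (whose difference alone carries a ~2.5-point standard
error at the default dispersion). The
segmentation-oracle test uses near-isotropic (0.5, 0.3, 0.3) µm sampling
and no pre-blur, isolating algorithmic error from voxel quantization;
at the default anisotropic spacing roughly half the per-cell boundary
shell is a quantization effect shared by any voxel-wise assignment.

## Known limitations

- The watershed assigns whole voxels; at strongly anisotropic spacing
  the per-cell Jaccard against sub-voxel ground truth saturates around
  0.9 even for a perfect count, which is why count recovery and overlap
  are tested separately.
- The rosette detector's score scale is template-specific; scores are
  comparable across images analysed with one template, not across
  templates, and the detector is a stand-in wherever a trained scorer
  is available (the rosettiness statistic accepts external scores).
- The bimodal-minimum threshold fails loudly on unimodal histograms
  rather than guessing; pipelines treat that as a per-embryo failure and
  continue.
- Diving classification is an annotation (or the synthetic truth flag),
  not an image classifier; the upstream study classified trajectories
  manually.
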