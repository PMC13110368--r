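# primquant

Quantitative morphometrics of the zebrafish posterior lateral line
primordium (pLLP) — the migrating cluster of ~120 membrane-labeled
epithelial cells that deposits the neuromasts of the lateral line. The
package is aimed at developmental biologists who quantify organ size and
composition from confocal Z-stacks: it measures **how many cells a
primordium contains**, how large and how elongated it is, how many
epithelial rosettes it has formed, how bright a transcriptional reporter
is inside it, and whether genotype cohorts differ.

The measurement cascade mirrors the standard imaging practice for this
tissue:

1. **Registration** — maximum Z-projection, Gaussian blur,
   bimodal-minimum auto-threshold, moment-ellipse fit; the stack is
   rotated so the long axis is horizontal and cropped in X, Y and Z.
2. **3D segmentation** — the membrane channel is a topographic relief:
   anisotropy-corrected Gaussian blur, h-minima suppression of shallow
   basins, marker-controlled (Meyer priority-flood) watershed with the
   border-connected minima as background.
3. **Per-cell measurement and cleanup** — physical volumes, face-weighted
   surface areas, centroids, per-channel means; volume gates; robust
   `median ± k·MAD` outlier fences on volume and surface/volume ratio
   (log scale, `k = 3.5`).
4. **Morphometrics** — cell count and total volume over kept cells;
   aspect ratio, circularity, roundness, solidity of the footprint;
   rosette detection by rotation-searched radial-spoke template
   correlation, with *rosettiness* = sum of detection scores / number of
   detections; neuromast deposition positions normalized to the
   ganglion; stained-area readouts.
5. **Intensity** — whole-image and in-ROI mean gray values,
   reporter-positive and EdU-positive cells (background mean + 2 SD
   rule), line profiles with midpoint nuclear-enrichment ratios.
6. **Statistics** — two-tailed Mann–Whitney U (exact from the U
   distribution for small untied samples, tie-corrected normal
   approximation otherwise), ΔΔCt fold changes (`2^-ΔΔCt` against a
   reference gene and control group), signed percent effects, `mean ± SD
   / SEM` group summaries, Wilson intervals for proportions, and the
   usual `ns/*/**/***/****` labels.

A first-class synthetic-data generator (`simulate_primordium()`,
`simulate_cohort()`, `simulate_reporter_image()`,
`simulate_qpcr_plate()`, `simulate_overview()`) produces primordium
stacks with *exact* per-cell ground truth and genotype presets carrying
the published effect sizes (e.g. −20% cells for *yap1* loss, +50% for
the *vgll4b;vgll4l* double mutant, +70% reporter for *yap1*
overexpression), so the whole pipeline is validated by recovery.

## Worked example

Simulate a wild-type and a double-mutant cohort, run the full pipeline,
and test the contrast:

```r
library(primquant)

cfg <- pipeline_config()
cohort <- run_cohort(c("wt", "vgll4b_vgll4l"), n_embryos = 4,
                     seed = 11, config = cfg)
dplyr::select(cohort, genotype, true_n_cells, cell_count, aspect_ratio)
#> # A tibble: 8 x 4
#>   genotype      true_n_cells cell_count aspect_ratio
#>   <chr>                <dbl>      <int>        <dbl>
#> 1 wt                     114        113         2.46
#> 2 wt                     120        120         2.47
#> 3 wt                     105        105         2.44
#> 4 wt                     107        107         2.48
#> 5 vgll4b_vgll4l          158        158         2.49
#> 6 vgll4b_vgll4l          176        176         2.49
#> 7 vgll4b_vgll4l          163        162         2.49
#> 8 vgll4b_vgll4l          180        180         2.49

cohort_tests(cohort, cell_count, genotype, ref_group = "wt")
#> # A tibble: 1 x 10
#>   group             n ref_n  mean ref_mean percent_change statistic p.value label method
#>   <chr>         <int> <int> <dbl>    <dbl>          <dbl>     <dbl>   <dbl> <chr> <chr>
#> 1 vgll4b_vgll4l     4     4   169     111.           51.9        16  0.0286 *     mann_whitney
```

Per-embryo `cell_count` tracks the generator's ground truth
(`true_n_cells`) to within a cell or two; the cohort contrast recovers
the +50% preset effect (+51.9% at n = 4), and the exact Mann–Whitney p for 4-vs-4 embryos
is 0.029 (`*`). A ΔΔCt example:

```r
plate <- simulate_qpcr_plate(true_fold = 0.35, ct_noise_sd = 0.15,
                             n_biological = 6, seed = 1)
delta_delta_ct(plate, target_gene = "target", ref_gene = "rpl13",
               control_group = "control")
#> # A tibble: 1 x 4
#>   group  n_samples delta_delta_ct fold_change
#>   <chr>      <int>          <dbl>       <dbl>
#> 1 mutant         6           1.58       0.335
```

i.e. a recovered ~66.5% expression reduction against the injected 65%.
`plot_cohort()` and `autoplot()` methods draw the standard
jitter-with-mean-bars and profile figures.

A thin command-line front end ships in `inst/cli/primquant`
(subcommands `simulate`, `segment`, `qpcr`, `stats`, `run-all`) for
batch use outside R.

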