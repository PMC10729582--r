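# microvam

Quantification of microglial phenotypes, their vascular association and
blood-brain-barrier leakage in multi-channel fluorescence microscopy —
the image-analysis and statistics chain used in studies of hypertensive
cerebral small vessel disease, reimplemented as a tested, reusable R
package with a ground-truth synthetic data generator.

**Who it is for.** Groups quantifying IBA1-labeled microglia together with
lectin-labeled vessels (and optionally IgG leakage) in confocal z-stacks or
2D sections, who want the measurement chain — not a GUI — with every stage
testable against planted truth.

## What it computes

| Stage | Method |
|---|---|
| Vessel segmentation | Multi-scale Frangi filter (scales 1–5 px), contrast parameter self-tuned to 40% of the image's maximum absolute Hessian eigenvalue; hysteresis thresholding with low/high cuts from three-class Otsu on the vesselness distribution |
| Soma counting / sizing | Automatic thresholding (Otsu; Triangle for inverted 2D material) + strict > 60 µm² size filter |
| Barrier leakage | Fixed threshold (> 25 on the 8-bit scale), strict > 5 µm² component filter, % of FOV area |
| Single-cell morphometrics | Topology-preserving 3D/2D thinning; skeleton graph with anisotropic µm edge lengths; endpoints, branch points, branch lengths, convex-hull (territorial) volume and ramification index RI = cell volume / hull volume (2D: solidity) |
| Vascular-associated microglia | Soma-to-vessel minimum distance via exact anisotropic distance transform; densities standardized to 1 mm² |
| Morphology clustering | z-scored 8-feature matrix, Ward-linkage hierarchical clustering (default k = 4, dendrogram + silhouettes always returned), deterministic UMAP embedding, cluster frequencies per stratum |
| Statistics | Shapiro–Wilk, Welch *t*, two-way ANOVA (type III) + Holm–Šídák step-down post hoc, Spearman matrices (exact permutation p for n ≤ 10), comparative 2^−ΔΔCt qPCR quantification |
| Synthetic data | Confocal FOV generator (tubes, branched cells, perivascular leakage, Poisson + Gaussian noise) with complete ground-truth tables |

The ramification index is the solidity-style measure
`cell volume / convex hull volume` (lower = more ramified); the Frangi
vesselness is the standard line-structure response
`(1 − e^{−R_A²/2α²}) · e^{−R_B²/2β²} · (1 − e^{−S²/2γ²})` for bright tubes,
maximized over scales. See the methods vignette
(`vignettes/microvam-methods.Rmd`) for the full model and design rationale.

## Worked example

```r
library(microvam)

## one synthetic field of view with known ground truth
cfg <- fov_config(seed = 42)          # 160 x 160 x 24 um counting stack
fov <- simulate_fov(cfg, "demo")

## vessel segmentation (self-tuned Frangi + 3-class Otsu + hysteresis)
seg <- segment_vessels(fov$volume)
round(unlist(seg$thresholds), 4)
#>    low   high
#> 0.1170 0.4032

## soma detection and VAM classification
som <- segment_somata(fov$volume)
vam <- classify_vam(som$labels, seg$mask, cfg$voxel_size)
vam_summary(vam, fov$volume$dim, cfg$voxel_size)
#>   n_cells n_vam vam_frequency microglia_per_mm2 vam_per_mm2
#> 1      12     3          0.25            468.75    117.1875

## barrier leakage
quantify_igg(fov$volume)
#> [1] 5.065664
```

Twelve somata were detected in the 0.0256 mm² field (469 cells/mm²), three
of them with their soma in contact with the segmented vessels (VAM
frequency 0.25), and 5.07% of the field lies above the leakage threshold —
all within measurement error of what the generator planted (12 cells,
Bernoulli-planted VAM at 30%, 5% leakage).

Single-cell morphometrics on a high-resolution cell:

```r
hi <- fov_config_morphology(voxel_size = c(0.32, 0.32, 0.6),
                            shape = c(176, 176, 64),
                            branch_length_range = c(10, 20), seed = 3)
cell <- generate_microglia(hi)
feats <- compute_features(list(mask = cell$truth$masks[[1]],
                               soma_mask = cell$truth$soma_masks[[1]]),
                          hi$voxel_size, prune_um = 3)
round(feats, 2)
#>          soma_area_um2            n_endpoints         n_branchpoints
#>                  58.57                   4.00                   2.00
#>   max_branch_length_um total_branch_length_um            cell_volume
#>                  19.47                  60.49                 393.95
#>            hull_volume     ramification_index
#>                3150.55                   0.13
```

The generator's tree for this cell has 4 endpoints and a longest branch of
18.47 µm; the skeleton recovered 4 endpoints and 19.47 µm, and the low
ramification index (0.13) identifies a highly ramified cell.

End to end, `simulate_dataset()` writes a multi-FOV TIFF dataset with truth
tables and `run_pipeline()` produces per-FOV summaries, per-cell features,
cluster labels, group statistics and a JSON run manifest. A thin CLI wraps
the same functions (`inst/cli/microvam.R` with `simulate`, `run-all`,
`segment-vessels` subcommands).

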