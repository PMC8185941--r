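# PDL1score

Automated PD-L1 tumor proportion scoring on bright-field IHC image tiles,
for computational pathology developers who want an end-to-end, fully
testable reference implementation of multistage ensemble scoring.

## What it computes

The clinical read-out is the **tumor proportion score**

```
TPS = 100 · nTC+ / (nTC+ + nTC−)
```

— the percentage of viable tumor cells with partial or complete membranous
PD-L1 (DAB) staining — plus the **immune cell proportion score** (IPS), the
percentage of intratumoral immune cells with membranous or cytoplasmic
staining, and the expression category (negative < 1 %, low 1–25 %,
moderate 25–50 %, high ≥ 50 %).

The method is a two-network ensemble:

1. **C-Net** — point-supervised cellular localization. Point annotations
   are dilated to per-class binary disks and a compact fully convolutional
   network with five sigmoid heads (TC(+), TC(−), lymphocyte, histocyte,
   fibrocyte) plus a deep-supervision head is trained with a *weighted
   pixel-wise cross-entropy*

   ```
   φ = λ·|p − t|^γ ,   L = −mean( φ · ( t·log p + (1−t)·log(1−p) ) )
   ```

   with λ = 3, γ = 3, which concentrates gradient on hard pixels — the
   boundaries of close and adhesive tumor cells that plain cross-entropy
   merges into single detections. Local-maximum extraction with greedy
   non-maximum suppression turns the maps into point detections.

2. **R-Net** — low-magnification (¼ scale) tumor-region segmentation with
   a 3-class softmax. Its tumor-probability map multiplicatively
   suppresses the TC(+)/TC(−) channels of C-Net, so stromal DAB-positive
   mimics (macrophage-like histocytes) cannot be counted as tumor cells.

Counts are aggregated over tiles by summing (never by averaging per-tile
TPS) and the package ships the complete concordance battery used to
evaluate such systems: object-level F1 with optimal point matching, count
MAE/RMSE/MAPE, ICC(2,1) with F-based confidence intervals, Fleiss' kappa
at the 1/5/10/25/50 % clinical cutoffs, Pearson/Spearman, Mann–Whitney U
and chi-square association tests.

Because the underlying clinical slides are proprietary, the package
includes a seed-deterministic synthetic IHC tile generator with exact
ground truth (stain-vector color model, tumor nests, five cell classes,
deliberately adjacent cell pairs, PD-L1-positive stromal confounders) as a
first-class, tested module. The networks are trained from scratch on CPU —
the convolution primitives and hand-derived backpropagation live in
`src/`, verified against finite differences.

## Worked example

```r
library(PDL1score)

tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                               nTumorCells = 20, nImmuneCells = 10,
                               nFibrocytes = 5, plannedTPS = 40, seed = 7))
truthScore(tile)
#> SlideScore
#>   TC(+): 8  TC(-): 12  IC: 6 (PD-L1+: 1)
#>   TPS: 40.00%  category: MODERATE
#>   IPS: 16.67%
```

Exactly `round(20 × 40/100) = 8` of the 20 tumor cells are rendered with a
brown membranous ring, so recomputing TPS from the annotations returns the
planned 40 % — the generator's ground truth is exact, which is what makes
end-to-end testing meaningful.

The full pipeline (simulate → train C-Net and R-Net → score slides →
concordance report):

```r
cfg <- pipelineConfig(seed = 1, outDir = "pdl1_run")
res <- runPipeline(cfg)    # ~10 min on one CPU at the default desk scale
res$report
```

which prints the ICC of recovered vs planned TPS over 15 synthetic slides
with the per-cutoff kappas. A thin command-line wrapper with
`fixtures | simulate | run | score | concord` subcommands is installed at
`inst/scripts/pdl1pipe`.

## Scope

The package implements the scoring mechanism, not a clinical device:
absolute accuracy on real slides, pyramidal WSI I/O, and the published
baseline comparisons are out of scope. See the methods vignette
(`vignettes/pdl1-scoring-methods.Rmd`) for the model, parameter and
design-decision documentation.
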