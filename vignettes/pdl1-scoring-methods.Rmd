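---
title: "Automated PD-L1 tumor proportion scoring: models and methods"
author: "PDL1score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PD-L1 tumor proportion scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scoring problem

PD-L1 expression on tumor cells guides checkpoint-inhibitor therapy in
non-small cell lung cancer. The clinical read-out is the **tumor proportion
score** (TPS): the percentage of viable tumor cells showing partial or
complete membranous PD-L1 staining on a DAB/hematoxylin IHC slide,

$$\mathrm{TPS} = 100\cdot\frac{n_{TC^+}}{n_{TC^+}+n_{TC^-}},$$

and, secondarily, the **immune cell proportion score** (IPS): the percentage
of intratumoral immune cells (lymphocytes, histocytes) with membranous or
cytoplasmic staining. Manual estimation is coarse and rater-dependent,
especially near the clinical cutoffs (1, 5, 10, 25, 50&nbsp;%), so this
package implements a counting approach: detect and classify every cell,
then compute TPS as a count ratio.

Scoring by counting has two failure modes that the package's two-network
ensemble addresses:

1. **Close and adhesive tumor cells** merge into single detections under a
   plain dense-prediction loss. The localization network (*C-Net*) is
   trained with a *weighted pixel-wise cross-entropy* that concentrates
   gradient on hard pixels (below).
2. **Stromal DAB-positive mimics** — macrophage-like histocytes most
   prominently — are counted as PD-L1-positive tumor cells by a purely
   cellular model. A low-magnification region segmenter (*R-Net*) produces
   a tumor-probability map that multiplicatively suppresses the tumor-cell
   channels outside tumor nests.

## Point supervision and the weighted loss

Cell annotations are points, not masks. Each point is dilated into a
binary disk (channel per class; five classes: TC(+), TC(−), lymphocyte,
histocyte, fibrocyte) to give the dense sigmoid heads spatial support. The
disk radius defaults to 9 px — the nominal nuclear radius at 40×, and
large enough to cover the membranous DAB ring (which sits 5–11 px from the
center) for most nuclei. That coverage matters: the ring is the feature
separating TC(+) from TC(−), and supervising a disk that excludes it makes
the distinction purely contextual, which a compact network learns far more
slowly. Disks of the deliberately adjacent cell pairs (11.2 px apart)
overlap and union in the targets; the pairs stay countable because peak
extraction separates maxima at least 9 px apart.

The loss re-weights every pixel by
$$\varphi_i = \lambda\,\lvert p_i - t_i\rvert^{\gamma},\qquad
L = -\frac{1}{N}\sum_i \varphi_i\,\bigl(t_i\log p_i + (1-t_i)\log(1-p_i)\bigr),$$
with defaults $\lambda = 3$, $\gamma = 3$. Setting $\lambda=1,\gamma=0$
recovers plain binary cross-entropy, which is how the ablation in the test
suite trains its baseline. Two readings of the printed loss required a
decision:

* The published form places the binary ground truth inside the logarithms;
  with hard 0/1 targets that expression is undefined, so the standard
  orientation (target multiplying the log-prediction) is implemented.
* The norm in the weight is read as the per-pixel absolute difference —
  the only reading under which $\varphi$ is a per-pixel weight matrix.

The gradient is taken through the weight $\varphi$ as well (as focal-style
losses do); the analytic gradient is verified against finite differences in
the test suite.

## Network architecture

No deep-learning framework is assumed: the convolution, pooling and
upsampling primitives live in `src/` (Armadillo im2col matrix products) and
backpropagation is derived by hand, with a finite-difference gradient check
as a unit test. Both networks share a compact fully convolutional
encoder–decoder: per stage a 3×3 convolution + ReLU, a transition block
(1×1 convolution + 2×2 average pool) between stages, a 3×3 bottleneck,
and a decoder of nearest-neighbour upsampling + 3×3 convolutions with
1×1-projected additive skips. Heads are 1×1 convolutions: five sigmoid
channels for C-Net (one-vs-rest; the channels deliberately do not compete,
since a pixel can plausibly support several hypotheses before NMS) plus a
half-resolution deep-supervision head weighted 0.4 during training, and a
3-class softmax for R-Net at region scale (¼ linear resolution, mirroring
10× region annotation of 40× cell annotation). Head biases start at zero;
a low-prior bias initialization was evaluated and rejected — under the
focal-style weight the initial gradients on cell pixels become so large at
usable learning rates that training settles into a constant-output
compromise.

The exact encoder/decoder internals of the published networks are not
specified; this architecture is a documented, replaceable contract — any
fully convolutional segmenter with the same head semantics can be plugged
in.

## Training

Network inputs are stain-space concentrations: each RGB tile is converted
to Ruifrok–Johnston hematoxylin / DAB / residual channels before
whitening. Stain deconvolution is standard IHC preprocessing, and at this
problem scale it is decisive — it hands the network the chromogen
structure (blue nucleus, brown membrane ring or cytoplasm) that raw-RGB
training would first have to rediscover.

Momentum SGD (momentum 0.9, batch 4). The full-scale recipe — initial
learning rate 0.001, 200 epochs, augmentation by rotation, shear, shift,
zoom, whitening and flips on 512-px tiles — is available via
`pipelineConfig(fullScale = TRUE)`. The default configuration is
desk-scale: 20 training tiles of 64 px (same cell density as the evaluation
tiles), 300 epochs at learning rate 0.05 halved every 120 epochs, flips and
exact quarter-turn rotations as augmentation, and training-set whitening
(per-channel mean/SD standardization, stored in the checkpoint and applied
at inference). The higher learning rate is a consequence of scale: with a
~10⁴-parameter network, 64-px tiles and ~10³ SGD updates, the full-scale
rate of 0.001 leaves the network far from convergence; 0.05 with decay is
stable for this problem size, together with global gradient-norm clipping
(at 5) and a 5-epoch linear warmup — without them the large focal-style
gradients of the first epochs intermittently blew the compact networks
into dead-ReLU constant states. When a validation set is present the
checkpoint with the best validation loss is returned; training is
bit-deterministic in the seed.

## From maps to scores

`extractDetections()` turns probability maps into points: per channel,
local maxima above threshold 0.5 (plateaus are collapsed to their centroid
via connected components, so a binary disk yields exactly one candidate),
greedy non-maximum suppression (higher peak wins, ties row-major), then
cross-channel suppression keeping the highest-scoring class. The
suppression distance defaults to the disk radius (9 px); the pipeline uses
11 px, just under the smallest center separation the generator produces
(adjacent pairs at 11.2 px) — any two peaks closer than that cannot be two
cells. The ensemble step multiplies the TC(+) and TC(−)
channels by the bilinearly upsampled tumor probability (sum of the two
tumor-region softmax channels) before peak extraction; immune and
fibrocyte channels pass through unchanged. Masking probabilities rather
than encoder features keeps the two networks independently testable and
has the same suppressive effect; whether the original system masked
features or probabilities is not recoverable from its description.

TPS is computed from the detected counts; slides aggregate by summing
counts across tiles and recomputing the ratio (never averaging per-tile
TPS). Expression categories use the half-open clinical bins: negative
(< 1), low (1–25), moderate (25–50), high (≥ 50); boundary values belong
to the upper bin. Immune-cell positivity is not algorithmically specified
in the clinical definition, so the package uses a documented stand-in: an
IC (lymphocyte or histocyte detection whose center lies on a tumor-region
pixel) is positive when its mean DAB concentration — Ruifrok–Johnston
color deconvolution with the standard hematoxylin/DAB vectors — over a
9-px disk reaches 0.15. Both threshold and radius are configurable.

## The synthetic data generator

No public slides exist for this task, so the generator is a first-class
module with exact ground truth. It emulates, at the 40× cell scale:
elliptical tumor nests covering a configurable area fraction (default 0.5)
calibrated iteratively to the requested coverage, with a subtle
hematoxylin background tint inside nests (confluent tumor cytoplasm is
visibly denser than stroma at 10×, which is what makes low-magnification
region segmentation learnable); hematoxylin-blue nuclei as anti-aliased
ellipses with class-specific size and chromatin density (tumor 5–9 px,
lymphocytes 3–4.5 px and hyperchromatic, histocytes 9–12 px irregular
with pale vesicular nuclei, fibrocytes elongated 8–12 × 2–3.5 px); a 2-px
DAB membrane ring on TC(+); diffuse DAB cytoplasm on PD-L1-positive immune
cells; stromal histocytes PD-L1-positive with probability 0.5
(macrophage-like confounders that make the masking ablation meaningful);
Gaussian noise in optical-density space over a linear mix of reference
stain vectors, so color deconvolution downstream is exercised honestly.
Class counts are exact: `round(n · TPS/100)` cells are TC(+), and the
positive cells form a contiguous territory around a random focus, from
which the TC(+)/TC(−) region labels are derived by nearest-cell
classification — every TC(+) cell therefore sits on a TC(+)-region pixel
by construction. A fraction (0.15) of tumor cells is generated as adjacent
pairs at 0.8 × nuclear diameter to exercise the close-cell behaviour;
other pairs respect a minimum separation (14 px at defaults). Impossible
packing requests raise an error rather than truncating.

What the generator does **not** emulate: texture inside nuclei, stain
gradients across a slide, out-of-focus regions, tissue folds, necrosis,
cytology artifacts, or pyramidal whole-slide formats. Passing end-to-end
tests therefore demonstrates that the pipeline machinery — loss, networks,
masking, scoring, statistics — is internally correct and recovers planted
signal under controlled conditions; it does not certify clinical
performance on real slides.

## Evaluation battery

* **Object-level F1**: optimal one-to-one matching (maximum cardinality,
  then minimum total distance) within a match radius, realized as a
  maximum-weight bipartite matching with weight `M − distance`; the test
  oracle enumerates all assignments exhaustively at small n. The match
  radius defaults to the target disk radius.
* **Count errors**: MAE, RMSE, MAPE (zero-truth patches excluded from MAPE
  only).
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measure — the appropriate form for "image analysis vs pathologist" —
  with the standard F-based confidence interval (Satterthwaite degrees of
  freedom). The published analysis says only "ICC"; the absolute-agreement
  single-measure form is fixed here and documented.
* **Fleiss' kappa** after dichotomization at 1/5/10/25/50&nbsp;%; a score
  exactly at a cutoff is positive, consistent with the closed lower bins.
  Fleiss' multi-rater formula is used with two raters (as the source
  analysis did), not Cohen's.
* **Associations**: Mann–Whitney U (normal approximation with tie
  correction, no continuity correction) comparing IPS across TPS groups,
  chi-square without continuity correction on the 2×2 table at the
  simultaneous 1&nbsp;% cutoffs, and Pearson/Spearman correlations.

Every statistic is checked against an independent brute-force or
closed-form oracle on random small instances.

## Worked example

```{r example}
library(PDL1score)

tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                               nTumorCells = 20, nImmuneCells = 10,
                               nFibrocytes = 5, plannedTPS = 40, seed = 7))
truthScore(tile)

cfg <- pipelineConfig(seed = 1, outDir = tempfile())
res <- runPipeline(cfg)   # simulate -> train -> score -> evaluate
res$report
```

## Numerical choices and degenerate inputs

* Predictions are clamped to `[1e-7, 1 − 1e-7]` inside the loss.
* Zero tumor cells: TPS is flagged not-amenable, never a division by zero;
  zero ICs flag IPS undefined; zero variance flags correlations/ICC
  undefined; one-category-only raters flag kappa undefined. Flags, not
  exceptions, so batch evaluation proceeds.
* Peak ties break in row-major order; equal-score plateaus collapse to the
  centroid-nearest maximum pixel.
* Tile seeds derive from the master seed and stay below 2³¹.
* Edge tiles are reflect-padded (mirror-periodic when the pad exceeds the
  source extent) and detections inside padding are dropped before
  stitching; duplicate detections in overlap zones resolve to the copy
  nearer its own tile center.

## Problem sizes

The default end-to-end configuration trains on twenty 64-px tiles and
scores fifteen two-tile 128-px slides (three per planned TPS level 0, 5,
25, 50, 90); the test suite and the acceptance script both use these sizes.
They were chosen as the smallest sizes at which every expression category
is represented by whole slides and planned TPS levels are exactly
realizable (tumor-cell counts divisible by 20).

## Known limitations

* The compact network is a stand-in for the published (unspecified)
  architectures; absolute detection accuracy is not comparable to a
  GPU-trained system, and the package's claims are about mechanism, not
  clinical performance.
* IC positivity by stain intensity is a documented surrogate for an
  unspecified procedure.
* One-vs-rest channels were chosen over softmax competition between cell
  classes; the original choice is not recoverable from the text.
* The generator's realized tumor-area fraction tracks the request only to
  within a few percent (elliptical nests, clipping).
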