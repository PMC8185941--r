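#' SlideScore: clinical PD-L1 quantities for a tile or slide
#'
#' Holds the tumor-cell and immune-cell counts together with the derived
#' tumor proportion score (TPS), immune cell proportion score (IPS) and the
#' expression category. TPS is the percentage of viable tumor cells with
#' membranous PD-L1 staining; IPS the percentage of intratumoral immune
#' cells (lymphocytes, histocytes) with membranous or cytoplasmic staining.
#'
#' @slot nTCPos,nTCNeg integer counts of PD-L1 positive / negative tumor cells.
#' @slot nIC,nICPos integer counts of intratumoral immune cells and of those
#'   scored PD-L1 positive.
#' @slot tps numeric TPS percent in `[0, 100]`, `NA` when not amenable.
#' @slot ips numeric IPS percent in `[0, 100]`, `NA` when no immune cells.
#' @slot category one of `"NEGATIVE"`, `"LOW"`, `"MODERATE"`, `"HIGH"`
#'   (or `NA` when not amenable).
#' @slot amenable logical; `FALSE` when the denominator of TPS is zero,
#'   mirroring cases not amenable to image-analysis scoring.
#'
#' @seealso [computeTPS()], [aggregateSlide()]
#' @export
setClass("SlideScore", representation(
  nTCPos = "integer", nTCNeg = "integer",
  nIC = "integer", nICPos = "integer",
  tps = "numeric", ips = "numeric",
  category = "character", amenable = "logical"
))

setValidity("SlideScore", function(object) {
  msg <- NULL
  cnt <- c(object@nTCPos, object@nTCNeg, object@nIC, object@nICPos)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be non-negative")
  den <- object@nTCPos + object@nTCNeg
  if (den > 0L) {
    if (!object@amenable) msg <- c(msg, "amenable must be TRUE when tumor cells exist")
    expected <- 100 * object@nTCPos / den
    if (!isTRUE(all.equal(object@tps, expected)))
      msg <- c(msg, "tps inconsistent with counts")
    if (!identical(object@category, unname(tpsCategoryOf(object@tps))))
      msg <- c(msg, "category inconsistent with tps")
  } else if (object@amenable) {
    msg <- c(msg, "amenable must be FALSE with zero tumor cells")
  }
  if (object@nIC > 0L && !is.na(object@ips)) {
    if (!isTRUE(all.equal(object@ips, 100 * object@nICPos / object@nIC)))
      msg <- c(msg, "ips inconsistent with counts")
  }
  if (is.null(msg)) TRUE else msg
})

#' RegionMask: low-magnification tumor-region labels
#'
#' A dense integer label image at region scale (by default 1/4 of the
#' cell-scale linear resolution, mirroring 10x annotation of 40x tiles).
#' Labels are `0` background, `1` TC(+) region, `2` TC(-) region,
#' `3` normal (stromal) region.
#'
#' @slot labels integer matrix of region labels.
#' @slot scaleFactor linear ratio of cell-scale to region-scale resolution.
#' @export
setClass("RegionMask", representation(
  labels = "matrix", scaleFactor = "numeric"
))

setValidity("RegionMask", function(object) {
  msg <- NULL
  if (!all(object@labels %in% REGION_LABELS))
    msg <- c(msg, "labels must be in {0, 1, 2, 3}")
  if (length(object@scaleFactor) != 1L || object@scaleFactor < 1)
    msg <- c(msg, "scaleFactor must be a single value >= 1")
  if (is.null(msg)) TRUE else msg
})

#' SynthSpec: parameters of one synthetic IHC tile
#'
#' Describes the study conditions a simulated tile realizes: geometry,
#' planned TPS/IPS, cell population sizes, tumor area fraction, stain noise
#' and the seed. Counts of PD-L1-positive tumor cells are exact:
#' `round(nTumorCells * plannedTPS / 100)` cells are generated TC(+).
#'
#' @slot tileWidth,tileHeight tile size in pixels (cell scale).
#' @slot plannedTPS,plannedIPS planned scores, percent in `[0, 100]`.
#' @slot nTumorCells,nImmuneCells,nFibrocytes cell population sizes.
#' @slot tumorAreaFraction fraction of the tile covered by tumor nests.
#' @slot stainNoiseSD Gaussian noise SD added in optical-density space.
#' @slot seed integer RNG seed; the generator is bit-deterministic in it.
#' @slot icTumorFraction fraction of immune cells placed inside tumor
#'   regions (these are the ICs counted for IPS).
#' @slot adjacentFraction fraction of tumor cells generated as deliberately
#'   adjacent pairs (center distance 0.8 x nuclear diameter).
#' @slot minSeparation minimum center-to-center distance (pixels) for all
#'   other cell pairs.
#' @slot stromalHistPosProb probability that a stromal histocyte is rendered
#'   PD-L1 positive (macrophage-like confounders for the masking ablation).
#' @export
setClass("SynthSpec", representation(
  tileWidth = "integer", tileHeight = "integer",
  plannedTPS = "numeric", plannedIPS = "numeric",
  nTumorCells = "integer", nImmuneCells = "integer", nFibrocytes = "integer",
  tumorAreaFraction = "numeric", stainNoiseSD = "numeric", seed = "integer",
  icTumorFraction = "numeric", adjacentFraction = "numeric",
  minSeparation = "numeric", stromalHistPosProb = "numeric"
))

setValidity("SynthSpec", function(object) {
  msg <- NULL
  if (object@tileWidth < 32L || object@tileHeight < 32L)
    msg <- c(msg, "tile must be at least 32 x 32 pixels")
  for (s in c("plannedTPS", "plannedIPS")) {
    v <- slot(object, s)
    if (v < 0 || v > 100) msg <- c(msg, paste(s, "must be in [0, 100]"))
  }
  if (object@nTumorCells < 0L || object@nImmuneCells < 0L ||
      object@nFibrocytes < 0L)
    msg <- c(msg, "cell counts must be non-negative")
  if (object@plannedTPS > 0 && object@nTumorCells < 1L)
    msg <- c(msg, "nTumorCells must be >= 1 when plannedTPS > 0")
  if (object@tumorAreaFraction < 0 || object@tumorAreaFraction > 1)
    msg <- c(msg, "tumorAreaFraction must be in [0, 1]")
  if (object@stainNoiseSD < 0) msg <- c(msg, "stainNoiseSD must be >= 0")
  for (s in c("icTumorFraction", "adjacentFraction", "stromalHistPosProb")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0, 1]"))
  }
  if (object@minSeparation <= 0) msg <- c(msg, "minSeparation must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' SynthTile: a simulated IHC tile with exact ground truth
#'
#' @slot image numeric array `(height, width, 3)` with values in `[0, 1]`,
#'   RGB, bright field (white background, hematoxylin-blue nuclei,
#'   DAB-brown PD-L1 staining).
#' @slot annotations `data.frame` with columns `x`, `y` (0-based pixel
#'   coordinates, x = column) and `cls` (one of the five cell classes).
#' @slot regionMask a [RegionMask-class] at region scale.
#' @slot truth a [SlideScore-class] recomputed exactly from the annotations.
#' @slot spec the generating [SynthSpec-class].
#' @export
setClass("SynthTile", representation(
  image = "array", annotations = "data.frame",
  regionMask = "RegionMask", truth = "SlideScore", spec = "SynthSpec"
))

setValidity("SynthTile", function(object) {
  msg <- NULL
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be (H, W, 3)")
  a <- object@annotations
  if (nrow(a)) {
    if (!all(c("x", "y", "cls") %in% names(a)))
      msg <- c(msg, "annotations need columns x, y, cls")
    else {
      if (any(a$x < 0 | a$x >= d[2] | a$y < 0 | a$y >= d[1]))
        msg <- c(msg, "annotation outside tile")
      if (!all(a$cls %in% CELL_CLASSES))
        msg <- c(msg, "unknown cell class in annotations")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' IHCNet: a compact fully convolutional network handle
#'
#' Wraps the weights and configuration of either the cellular localization
#' network (five sigmoid heads, one per cell class, plus a half-resolution
#' deep-supervision head used during training) or the tumor-region
#' segmentation network (three-class softmax head).
#'
#' @slot kind `"cnet"` or `"rnet"`.
#' @slot weights named list of weight matrices / bias vectors.
#' @slot config list: `nClasses`, `baseWidth`, `depth`, input channel
#'   normalization statistics, and the config hash.
#' @slot trained logical.
#' @slot history `data.frame` of per-epoch training (and validation) loss.
#' @export
setClass("IHCNet", representation(
  kind = "character", weights = "list", config = "list",
  trained = "logical", history = "data.frame"
))

setValidity("IHCNet", function(object) {
  if (!object@kind %in% c("cnet", "rnet")) return("kind must be cnet or rnet")
  TRUE
})

#' ConcordanceReport: reliability statistics for two score vectors
#'
#' @slot icc intraclass correlation ICC(2,1), two-way random effects,
#'   absolute agreement, single measure.
#' @slot iccCI numeric length-2 95 percent confidence interval.
#' @slot pearson,spearman correlation coefficients.
#' @slot kappa named numeric: Fleiss' kappa after dichotomization at each
#'   cutoff (percent).
#' @slot n number of paired cases.
#' @export
setClass("ConcordanceReport", representation(
  icc = "numeric", iccCI = "numeric",
  pearson = "numeric", spearman = "numeric",
  kappa = "numeric", n = "integer"
))

setValidity("ConcordanceReport", function(object) {
  msg <- NULL
  ok <- function(v) is.na(v) | (v >= -1 & v <= 1)
  if (!ok(object@icc) || !ok(object@pearson) || !ok(object@spearman))
    msg <- c(msg, "correlation-type statistics must be in [-1, 1] or NA")
  if (length(object@iccCI) != 2L)
    msg <- c(msg, "iccCI must have length 2")
  if (!is.na(object@icc) && !any(is.na(object@iccCI)) &&
      (object@iccCI[1] > object@icc + 1e-8 || object@iccCI[2] < object@icc - 1e-8))
    msg <- c(msg, "iccCI must bracket icc")
  if (is.null(msg)) TRUE else msg
})
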