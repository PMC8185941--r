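# Clinical scoring: TPS / IPS from detections, expression categories,
# stain deconvolution for immune-cell positivity, slide-level aggregation.

# Internal categorizer tolerant of NA (used by the SlideScore validity).
tpsCategoryOf <- function(tps) {
  if (is.na(tps)) return(NA_character_)
  if (tps < 1) "NEGATIVE" else if (tps < 25) "LOW"
  else if (tps < 50) "MODERATE" else "HIGH"
}

newSlideScore <- function(nTCPos, nTCNeg, nIC = 0L, nICPos = 0L) {
  den <- nTCPos + nTCNeg
  amenable <- den > 0L
  tpsv <- if (amenable) 100 * nTCPos / den else NA_real_
  ipsv <- if (nIC > 0L) 100 * nICPos / nIC else NA_real_
  new("SlideScore",
      nTCPos = as.integer(nTCPos), nTCNeg = as.integer(nTCNeg),
      nIC = as.integer(nIC), nICPos = as.integer(nICPos),
      tps = tpsv, ips = ipsv,
      category = tpsCategoryOf(tpsv), amenable = amenable)
}

#' Compute the tumor proportion score from detections
#'
#' TPS is the percentage of tumor cells with membranous PD-L1 staining among
#' all viable tumor cells: `100 * nTCPos / (nTCPos + nTCNeg)`. Non-tumor
#' detections (lymphocytes, histocytes, fibrocytes) are ignored. With zero
#' tumor cells the case is flagged not amenable instead of dividing by zero.
#'
#' @param detections `data.frame` with at least a `cls` column; typically
#'   the output of [extractDetections()] or ground-truth annotations.
#' @return a [SlideScore-class] (immune-cell slots zero; see
#'   [icPositivity()] and [computeIPS()] for IPS).
#' @examples
#' det <- data.frame(x = 0, y = 0,
#'                   cls = rep(c("TC_POS", "TC_NEG"), c(30, 70)))
#' tps(computeTPS(det))  # 30
#' @export
computeTPS <- function(detections) {
  cls <- detections$cls
  newSlideScore(sum(cls == "TC_POS"), sum(cls == "TC_NEG"))
}

#' Assign the PD-L1 expression category of a TPS value
#'
#' Half-open clinical bins: negative (TPS < 1), low (1 <= TPS < 25),
#' moderate (25 <= TPS < 50), high (TPS >= 50). Boundaries belong to the
#' upper bin.
#'
#' @param tps TPS percent in `[0, 100]` (vectorized).
#' @return character vector of categories.
#' @export
categorizeTPS <- function(tps) {
  if (any(is.na(tps)) || any(tps < 0 | tps > 100))
    stop("tps must be within [0, 100]")
  vapply(tps, tpsCategoryOf, character(1))
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert: `OD = -log10(I / I0)` per channel with `I0 = 1` (images are
#' stored in `[0, 1]`). Intensities are clamped below at 1/255 so fully
#' saturated pixels stay finite.
#'
#' @param image numeric array `(H, W, 3)` in `[0, 1]`.
#' @return array of the same shape holding optical densities.
#' @export
rgbToOD <- function(image) {
  -log10(pmax(image, 1 / 255))
}

#' Ruifrok-Johnston color deconvolution
#'
#' Projects per-pixel optical density onto reference stain vectors for
#' hematoxylin and DAB (plus an orthogonal residual), returning per-stain
#' concentration maps. This is the standard unmixing used to quantify DAB
#' staining intensity in IHC.
#'
#' @param image numeric array `(H, W, 3)` in `[0, 1]`.
#' @return named list of matrices `hematoxylin`, `dab`, `residual`.
#' @export
stainConcentrations <- function(image) {
  od <- rgbToOD(image)
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)  # pixels x RGB
  conc <- odm %*% solve(stainMatrix())
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab = matrix(conc[, 2], d[1], d[2]),
       residual = matrix(conc[, 3], d[1], d[2]))
}

# Mean of `values` (a matrix) over a disk of given radius centred at
# 0-based (x, y); the disk is clipped to the matrix extent.
diskMean <- function(values, x, y, radius) {
  H <- nrow(values); W <- ncol(values)
  r <- ceiling(radius)
  rows <- max(1L, y + 1L - r):min(H, y + 1L + r)
  cols <- max(1L, x + 1L - r):min(W, x + 1L + r)
  dy <- rows - (y + 1L); dx <- cols - (x + 1L)
  inside <- outer(dy^2, dx^2, "+") <= radius^2
  mean(values[rows, cols, drop = FALSE][inside])
}

#' Score immune-cell PD-L1 positivity by DAB optical density
#'
#' Immune cells for IPS are the lymphocyte and histocyte detections whose
#' center lies on a tumor-region pixel of the region mask. Each such IC is
#' scored PD-L1 positive when the mean DAB concentration (Ruifrok-Johnston
#' deconvolution) over a disk around its center reaches `odThreshold`;
#' membranous or cytoplasmic staining both raise this signal.
#'
#' @param image RGB tile, array `(H, W, 3)` in `[0, 1]`.
#' @param detections detection/annotation `data.frame` (`x`, `y`, `cls`).
#' @param regionMask a [RegionMask-class] (region scale; looked up by
#'   integer division of cell-scale coordinates).
#' @param odThreshold mean-DAB threshold, default 0.15.
#' @param diskRadius radius (pixels, cell scale) of the averaging disk.
#' @return `detections` restricted to intratumoral ICs, with a logical
#'   column `positive` appended.
#' @export
icPositivity <- function(image, detections, regionMask,
                         odThreshold = 0.15, diskRadius = 9) {
  ic <- detections[detections$cls %in% c("LYMPHOCYTE", "HISTOCYTE"), ,
                   drop = FALSE]
  if (nrow(ic) == 0L) {
    ic$positive <- logical(0)
    return(ic)
  }
  lab <- maskLabels(regionMask)
  sf <- scaleFactor(regionMask)
  rx <- pmin(floor(ic$x / sf), ncol(lab) - 1L)
  ry <- pmin(floor(ic$y / sf), nrow(lab) - 1L)
  inTumor <- lab[cbind(ry + 1L, rx + 1L)] %in%
    REGION_LABELS[c("TC_POS_REGION", "TC_NEG_REGION")]
  ic <- ic[inTumor, , drop = FALSE]
  if (nrow(ic) == 0L) {
    ic$positive <- logical(0)
    return(ic)
  }
  dab <- stainConcentrations(image)$dab
  ic$positive <- vapply(seq_len(nrow(ic)), function(i) {
    diskMean(dab, ic$x[i], ic$y[i], diskRadius) >= odThreshold
  }, logical(1))
  ic
}

#' Compute the immune cell proportion score
#'
#' IPS is the percentage of intratumoral immune cells scored PD-L1
#' positive: `100 * nICPos / nIC`, undefined (`NA`) when there are no ICs.
#'
#' @param icFlags logical vector of per-IC positivity (from
#'   [icPositivity()]'s `positive` column).
#' @return list with `nIC`, `nICPos`, `ips` (`NA` when `nIC == 0`) and
#'   `defined`.
#' @export
computeIPS <- function(icFlags) {
  n <- length(icFlags)
  npos <- sum(icFlags)
  list(nIC = n, nICPos = npos,
       ips = if (n > 0L) 100 * npos / n else NA_real_,
       defined = n > 0L)
}

#' Aggregate per-tile counts into a slide-level score
#'
#' Counts are summed across tiles and the ratios recomputed from the summed
#' counts; TPS is a count ratio, never the mean of per-tile TPS values.
#'
#' @param scores list of [SlideScore-class] objects (one per tile).
#' @return a single [SlideScore-class] for the slide.
#' @examples
#' a <- PDL1score:::newSlideScore(10, 90)
#' b <- PDL1score:::newSlideScore(30, 10)
#' tps(aggregateSlide(list(a, b)))  # 40 / 140 * 100 = 28.57
#' @export
aggregateSlide <- function(scores) {
  stopifnot(length(scores) >= 1L)
  cnt <- Reduce(`+`, lapply(scores, cellCounts))
  newSlideScore(cnt[["nTCPos"]], cnt[["nTCNeg"]], cnt[["nIC"]], cnt[["nICPos"]])
}

#' Score annotations or detections against a region mask
#'
#' Convenience wrapper producing a complete [SlideScore-class] for one tile:
#' tumor counts from the detections, IC positivity from the image by
#' [icPositivity()].
#'
#' @inheritParams icPositivity
#' @return a [SlideScore-class].
#' @export
scoreTile <- function(image, detections, regionMask,
                      odThreshold = 0.15, diskRadius = 9) {
  cls <- detections$cls
  ic <- icPositivity(image, detections, regionMask,
                     odThreshold = odThreshold, diskRadius = diskRadius)
  newSlideScore(sum(cls == "TC_POS"), sum(cls == "TC_NEG"),
                nrow(ic), sum(ic$positive))
}
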