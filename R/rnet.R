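# The multistage ensemble step: the low-magnification tumor probability
# map multiplicatively suppresses the localization network's tumor-cell
# responses outside tumor regions, so stromal DAB-positive mimics (e.g.
# macrophage-like histocytes) cannot be counted as tumor cells.

#' Cell-scale tumor probability from a region probability map
#'
#' Sums the TC(+)-region and TC(-)-region channels into a tumor
#' probability and upsamples it bilinearly (half-pixel aligned) by
#' `scaleFactor` to cell-scale resolution; values remain in `[0, 1]`.
#'
#' @param regionProb array `(h, w, 3)` of softmax region probabilities
#'   (channels TC_POS_REGION, TC_NEG_REGION, NORMAL_REGION).
#' @param scaleFactor integer linear upsampling factor, `>= 1`.
#' @return matrix `(h * scaleFactor, w * scaleFactor)` in `[0, 1]`.
#' @export
tumorProbability <- function(regionProb, scaleFactor = 4L) {
  stopifnot(scaleFactor >= 1)
  tp <- regionProb[, , 1] + regionProb[, , 2]
  tp <- pmin(pmax(tp, 0), 1)
  if (scaleFactor == 1L) return(tp)
  pmin(pmax(cpp_upsample_bilinear(tp, as.integer(scaleFactor)), 0), 1)
}

#' Mask cell probability maps with the tumor probability
#'
#' Multiplies the TC_POS and TC_NEG channels pixel-wise by the cell-scale
#' tumor probability; immune and fibrocyte channels pass through
#' unmodified. Masking never increases any probability, so tumor-cell
#' detections outside predicted tumor regions are suppressed below the
#' detection threshold.
#'
#' @param cellProb array `(H, W, 5)` of cell-class probabilities.
#' @param tumorProb matrix `(H, W)` in `[0, 1]` from [tumorProbability()].
#' @return masked probability array, same shape as `cellProb`.
#' @export
maskCellMaps <- function(cellProb, tumorProb) {
  if (!identical(dim(cellProb)[1:2], dim(tumorProb)[1:2]))
    stop("cellProb and tumorProb spatial sizes differ")
  out <- cellProb
  for (ch in c("TC_POS", "TC_NEG")) {
    k <- match(ch, dimnames(cellProb)[[3]])
    if (is.na(k)) k <- match(ch, CELL_CLASSES)
    out[, , k] <- cellProb[, , k] * tumorProb
  }
  out
}

#' Predicted region mask from region probabilities
#'
#' Argmax labelling of the region probability map, returned as a
#' [RegionMask-class] for downstream immune-cell gating.
#'
#' @inheritParams tumorProbability
#' @param scaleFactor cell-scale / region-scale ratio recorded in the mask.
#' @return a [RegionMask-class].
#' @export
regionProbToMask <- function(regionProb, scaleFactor = 4L) {
  lab <- apply(regionProb, c(1, 2), which.max)
  new("RegionMask", labels = matrix(as.integer(lab), nrow(lab), ncol(lab)),
      scaleFactor = scaleFactor)
}
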