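# Point-supervised training targets and the weighted pixel-wise
# cross-entropy loss used by the cellular localization network.
#
# Each point annotation is dilated into a small binary disk so the dense
# prediction has spatial support to learn from; the loss then re-weights
# every pixel by phi = lambda * |p - t|^gamma, which amplifies hard pixels
# (typically the boundaries between close/adhesive cells) and down-weights
# easy background, in the spirit of focal loss.

#' Loss configuration for the weighted pixel-wise cross-entropy
#'
#' @param lambda weight scale, `> 0` (default 3).
#' @param gamma focusing exponent, `>= 0` (default 3). `lambda = 1,
#'   gamma = 0` recovers plain binary cross-entropy.
#' @return a validated list of class `LossConfig`.
#' @export
lossConfig <- function(lambda = 3, gamma = 3) {
  stopifnot(lambda > 0, gamma >= 0)
  structure(list(lambda = lambda, gamma = gamma), class = "LossConfig")
}

#' Build binary target maps from point annotations
#'
#' Channel `c` receives a disk of ones of the given radius (`dx^2 + dy^2 <=
#' radius^2`, clipped to the tile) centred on every class-`c` annotation;
#' overlapping disks union. Output dimensions: `(H, W, 5)` in the fixed
#' class order TC_POS, TC_NEG, LYMPHOCYTE, HISTOCYTE, FIBROCYTE.
#'
#' @param annotations `data.frame` with `x`, `y` (0-based), `cls`.
#' @param shape `c(H, W)` of the tile.
#' @param diskRadius disk radius in pixels, `>= 1` (default 9: the nominal
#'   nuclear radius at 40x). Either a single radius for all classes or a
#'   named per-class vector (e.g. a smaller disk for lymphocytes, whose
#'   nuclei are half the diameter of tumor nuclei).
#' @return numeric array `(H, W, 5)` with values in `{0, 1}`.
#' @export
makeTargetMaps <- function(annotations, shape, diskRadius = 9) {
  stopifnot(all(diskRadius >= 1))
  radii <- if (length(diskRadius) == 1L && is.null(names(diskRadius))) {
    setNames(rep(diskRadius, length(CELL_CLASSES)), CELL_CLASSES)
  } else {
    r <- setNames(rep(max(diskRadius), length(CELL_CLASSES)), CELL_CLASSES)
    r[names(diskRadius)] <- diskRadius
    r
  }
  H <- shape[1]; W <- shape[2]
  if (nrow(annotations) &&
      any(annotations$x < 0 | annotations$x >= W |
          annotations$y < 0 | annotations$y >= H))
    stop("annotation outside the target shape")
  maps <- array(0, c(H, W, length(CELL_CLASSES)),
                dimnames = list(NULL, NULL, CELL_CLASSES))
  offsFor <- lapply(radii, function(rr) {
    r <- floor(rr)
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    offs[offs$dx^2 + offs$dy^2 <= rr^2, ]
  })
  for (i in seq_len(nrow(annotations))) {
    ch <- match(annotations$cls[i], CELL_CLASSES)
    offs <- offsFor[[annotations$cls[i]]]
    yy <- annotations$y[i] + offs$dy
    xx <- annotations$x[i] + offs$dx
    ok <- yy >= 0 & yy < H & xx >= 0 & xx < W
    maps[cbind(yy[ok] + 1L, xx[ok] + 1L, ch)] <- 1
  }
  maps
}

#' Per-pixel weight matrix of the weighted cross-entropy
#'
#' `phi = lambda * |pred - target|^gamma`, elementwise; values lie in
#' `[0, lambda]`.
#'
#' @param pred,target numeric arrays of identical shape; predictions in
#'   `[0, 1]`, targets binary.
#' @param cfg a [lossConfig()].
#' @return array of weights, same shape as `pred`.
#' @export
weightMatrix <- function(pred, target, cfg = lossConfig()) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  cfg$lambda * abs(pred - target)^cfg$gamma
}

#' Weighted pixel-wise cross-entropy loss
#'
#' `loss = -mean( phi * (t * log p + (1 - t) * log(1 - p)) )` over all
#' pixels and channels (and images of a batch), with predictions clamped to
#' `[eps, 1 - eps]`, `eps = 1e-7`. With `lambda = 1, gamma = 0` this is
#' exactly mean binary cross-entropy; with `gamma > 0` hard pixels (large
#' `|p - t|`) are up-weighted by up to `lambda`.
#'
#' @inheritParams weightMatrix
#' @return non-negative scalar.
#' @examples
#' # single pixel, t = 1, p = 0.5, lambda = gamma = 3:
#' weightedPixelwiseCE(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1)))
#' # 3 * 0.125 * log(2) = 0.259930
#' @export
weightedPixelwiseCE <- function(pred, target, cfg = lossConfig()) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  if (any(!is.finite(pred)) || any(!is.finite(target)))
    stop("non-finite values in pred or target")
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  phi <- cfg$lambda * abs(p - target)^cfg$gamma
  -mean(phi * (target * log(p) + (1 - target) * log(1 - p)))
}

# Gradient of weightedPixelwiseCE w.r.t. the (clamped) prediction,
# differentiating through the weight phi as well (as focal-style losses
# do). Returns an array of the same shape as pred.
weightedCEGrad <- function(pred, target, cfg) {
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  d <- p - target
  phi <- cfg$lambda * abs(d)^cfg$gamma
  ce <- -(target * log(p) + (1 - target) * log(1 - p))
  dce <- -(target / p - (1 - target) / (1 - p))
  dphi <- if (cfg$gamma == 0) 0
          else cfg$lambda * cfg$gamma * abs(d)^(cfg$gamma - 1) * sign(d)
  g <- (phi * dce + dphi * ce) / length(p)
  g[pred < eps | pred > 1 - eps] <- 0  # clamped region
  g
}
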