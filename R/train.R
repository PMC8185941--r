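# Training loops: momentum SGD (full-scale recipe: batch 4, initial learning
# rate 0.001, momentum 0.9) with optional online augmentation and
# training-set whitening. Desk-scale budgets (small tiles, tens of epochs)
# are the defaults; the full-scale recipe is a configuration choice.

#' Augmentation configuration
#'
#' Online augmentations applied independently per tile per epoch: random
#' horizontal/vertical flips (p = 0.5 each), rotation (uniform in
#' `[-rotate, rotate]` degrees), shear (degrees), shift (fraction of the
#' tile) and zoom (`1 +- zoom`), all applied jointly to the image and its
#' target maps with nearest-neighbour resampling. `augmentConfig()` (all
#' geometric magnitudes zero, flips on) is the default training setting;
#' `augmentConfig(rotate = 180, shear = 10, shift = 0.1, zoom = 0.1)` is
#' the full recipe.
#'
#' @param flip enable random flips.
#' @param rot90 enable random quarter-turn rotations (square tiles; exact,
#'   no resampling).
#' @param rotate,shear maximal rotation / shear in degrees.
#' @param shift maximal shift as a fraction of the tile side.
#' @param zoom maximal relative zoom.
#' @return a list of class `AugmentConfig`.
#' @export
augmentConfig <- function(flip = TRUE, rot90 = TRUE, rotate = 0, shear = 0,
                          shift = 0, zoom = 0) {
  structure(list(flip = flip, rot90 = rot90, rotate = rotate, shear = shear,
                 shift = shift, zoom = zoom), class = "AugmentConfig")
}

rotate90 <- function(arr, k) {
  k <- k %% 4L
  while (k > 0L) {
    arr <- aperm(arr, c(2, 1, 3))[rev(seq_len(dim(arr)[2])), , , drop = FALSE]
    k <- k - 1L
  }
  arr
}

# Apply one random augmentation draw to an (H, W, C) array pair.
# Fill value: `fill` for the image (white background), 0 for maps.
augmentPair <- function(image, maps, cfg) {
  if (isTRUE(cfg$rot90) && nrow(image) == ncol(image)) {
    k <- sample(0:3, 1L)
    if (k > 0L) {
      image <- rotate90(image, k)
      maps <- rotate90(maps, k)
    }
  }
  if (cfg$flip) {
    if (runif(1) < 0.5) {
      image <- image[, rev(seq_len(ncol(image))), , drop = FALSE]
      maps <- maps[, rev(seq_len(ncol(maps))), , drop = FALSE]
    }
    if (runif(1) < 0.5) {
      image <- image[rev(seq_len(nrow(image))), , , drop = FALSE]
      maps <- maps[rev(seq_len(nrow(maps))), , , drop = FALSE]
    }
  }
  if (cfg$rotate > 0 || cfg$shear > 0 || cfg$shift > 0 || cfg$zoom > 0) {
    th <- runif(1, -cfg$rotate, cfg$rotate) * pi / 180
    sh <- tan(runif(1, -cfg$shear, cfg$shear) * pi / 180)
    zx <- 1 + runif(1, -cfg$zoom, cfg$zoom)
    zy <- 1 + runif(1, -cfg$zoom, cfg$zoom)
    dx <- runif(1, -cfg$shift, cfg$shift) * ncol(image)
    dy <- runif(1, -cfg$shift, cfg$shift) * nrow(image)
    A <- matrix(c(cos(th) * zx, sin(th) * zx,
                  -sin(th) * zy + sh, cos(th) * zy), 2, 2)
    image <- affineNN(image, A, c(dx, dy), fill = max(image))
    maps <- affineNN(maps, A, c(dx, dy), fill = 0)
  }
  list(image = image, maps = maps)
}

# Inverse-mapped nearest-neighbour affine warp about the tile center.
affineNN <- function(arr, A, shift, fill = 0) {
  H <- nrow(arr); W <- ncol(arr)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  Ai <- solve(A)
  gx <- rep(seq_len(W) - cx - shift[1], each = H)
  gy <- rep(seq_len(H) - cy - shift[2], W)
  sx <- round(Ai[1, 1] * gx + Ai[1, 2] * gy + cx)
  sy <- round(Ai[2, 1] * gx + Ai[2, 2] * gy + cy)
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  out <- array(fill, dim(arr))
  idxOut <- which(ok)
  idxSrc <- sy[ok] + (sx[ok] - 1) * H
  for (ch in seq_len(dim(arr)[3])) {
    plane <- arr[, , ch]
    o <- matrix(fill, H, W)
    o[idxOut] <- plane[idxSrc]
    out[, , ch] <- o
  }
  out
}

# Whitening statistics, computed in stain space (the network input).
trainingStats <- function(tiles) {
  st <- lapply(tiles, toStainSpace)
  m <- rowMeans(vapply(st, function(t) apply(t, 3, mean), numeric(3)))
  s <- rowMeans(vapply(st, function(t) apply(t, 3, sd), numeric(3)))
  list(mean = m, sd = pmax(s, 1e-3))
}

# Shared SGD loop. lossFn(model, x, target, train) must return
# list(loss, cache, dOutZ, dAuxZ) with gradients w.r.t. the head logits.
runTraining <- function(model, tiles, targets, valTiles, valTargets,
                        epochs, batchSize, lr, momentum, augment, seed,
                        lossFn, lrDecayFactor = 1, lrDecayEvery = Inf,
                        clipNorm = 5, warmupEpochs = 5L) {
  if (length(tiles) == 0L) stop("empty training set")
  stopifnot(length(tiles) == length(targets))
  withSeed(seed, {
    stats <- trainingStats(tiles)
    model@config$norm <- stats
    xs <- lapply(tiles, function(t) normalizeInput(model, t))
    vxs <- lapply(valTiles, function(t) normalizeInput(model, t))
    weights <- model@weights
    velocity <- lapply(weights, function(w) w * 0)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       validation = numeric(0))
    best <- list(loss = Inf, weights = weights)
    n <- length(xs)
    for (ep in seq_len(epochs)) {
      lrEp <- lr * lrDecayFactor^floor((ep - 1) / lrDecayEvery)
      if (warmupEpochs > 0L) lrEp <- lrEp * min(1, ep / warmupEpochs)
      ord <- sample.int(n)
      epLoss <- 0
      bstarts <- seq(1L, n, by = batchSize)
      for (bs in bstarts) {
        idx <- ord[bs:min(bs + batchSize - 1L, n)]
        grads <- NULL
        for (i in idx) {
          x <- xs[[i]]; tg <- targets[[i]]
          if (!is.null(augment)) {
            ag <- augmentPair(x, tg, augment)
            x <- ag$image; tg <- ag$maps
          }
          model@weights <- weights
          res <- lossFn(model, x, tg, train = TRUE)
          if (!is.finite(res$loss))
            stop(paste0("training diverged (non-finite loss); config: ",
                        "lr=", lr, " momentum=", momentum,
                        " batch=", batchSize, " epoch=", ep))
          epLoss <- epLoss + res$loss / n
          g <- nnBackward(model, res$cache, res$dOutZ, res$dAuxZ)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g[names(grads)])
        }
        grads <- lapply(grads, function(g) g / length(idx))
        if (is.finite(clipNorm)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
          if (gn > clipNorm)
            grads <- lapply(grads, function(g) g * (clipNorm / gn))
        }
        st <- sgdStep(weights, grads, velocity, lrEp, momentum)
        weights <- st$weights; velocity <- st$velocity
      }
      vLoss <- NA_real_
      if (length(vxs)) {
        model@weights <- weights
        vLoss <- mean(vapply(seq_along(vxs), function(i)
          lossFn(model, vxs[[i]], valTargets[[i]], train = FALSE)$loss,
          numeric(1)))
        if (vLoss < best$loss) best <- list(loss = vLoss, weights = weights)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train = epLoss,
                                     validation = vLoss))
    }
    model@weights <- if (length(vxs)) best$weights else weights
    model@trained <- TRUE
    model@history <- hist
    model
  })
}

#' Train the cellular localization network
#'
#' Momentum SGD on the weighted pixel-wise cross-entropy
#' ([weightedPixelwiseCE()]) over the five sigmoid heads, with the
#' half-resolution deep-supervision head added at weight `auxWeight`.
#' Input channels are whitened by training-set mean/SD. Deterministic for
#' a fixed seed; when a validation set is given the checkpoint with the
#' best validation loss is returned.
#'
#' @param tiles list of RGB arrays `(H, W, 3)` in `[0, 1]`; sides should be
#'   divisible by `2^depth`.
#' @param targets list of target-map arrays from [makeTargetMaps()].
#' @param valTiles,valTargets optional validation set (may be empty: then
#'   the final-epoch weights are returned).
#' @param epochs,batchSize,lr,momentum optimizer settings; the full-scale
#'   recipe is batch 4, lr 0.001, momentum 0.9, 200 epochs.
#' @param lossCfg a [lossConfig()]; `lossConfig(1, 0)` trains with plain
#'   binary cross-entropy.
#' @param augment an [augmentConfig()] or `NULL` to disable augmentation.
#' @param auxWeight weight of the deep-supervision loss (0.4; applied
#'   during training only).
#' @param lrDecayFactor,lrDecayEvery step learning-rate schedule: the rate
#'   is multiplied by `lrDecayFactor` every `lrDecayEvery` epochs (default:
#'   constant rate).
#' @param clipNorm global gradient-norm clip (stabilizes the large focal
#'   gradients of the first epochs); `Inf` disables.
#' @param warmupEpochs linear learning-rate warmup length in epochs.
#' @param seed seed controlling initialization, shuffling, augmentation.
#' @param model optionally a pre-built [buildCnet()] handle to continue.
#' @param baseWidth,depth architecture, forwarded to [buildCnet()].
#' @return a trained [IHCNet-class] with the loss history in `@history`.
#' @export
trainCnet <- function(tiles, targets, valTiles = list(), valTargets = list(),
                      epochs = 30L, batchSize = 4L, lr = 0.001,
                      momentum = 0.9, lossCfg = lossConfig(),
                      augment = augmentConfig(), auxWeight = 0.4,
                      seed = 1L, model = NULL, baseWidth = 8L, depth = 2L,
                      lrDecayFactor = 1, lrDecayEvery = Inf,
                      clipNorm = 5, warmupEpochs = 5L) {
  if (is.null(model)) model <- buildCnet(baseWidth = baseWidth,
                                         depth = depth, seed = seed)
  lossFn <- function(model, x, tg, train) {
    fw <- nnForward(model, x, train = train)
    p <- fw$cache$out
    loss <- weightedPixelwiseCE(p, tg, lossCfg)
    dOutZ <- NULL; dAuxZ <- NULL
    if (train) {
      dOutZ <- weightedCEGrad(p, tg, lossCfg) * p * (1 - p)
      if (!is.null(fw$cache$aux)) {
        tgHalf <- cpp_avgpool2(tg)
        pa <- fw$cache$aux$p
        loss <- loss + auxWeight * weightedPixelwiseCE(pa, tgHalf, lossCfg)
        dAuxZ <- auxWeight * weightedCEGrad(pa, tgHalf, lossCfg) * pa * (1 - pa)
      }
    }
    list(loss = loss, cache = fw$cache, dOutZ = dOutZ, dAuxZ = dAuxZ)
  }
  runTraining(model, tiles, targets, valTiles, valTargets, epochs,
              batchSize, lr, momentum, augment, seed, lossFn,
              lrDecayFactor, lrDecayEvery, clipNorm, warmupEpochs)
}

# One-hot region target from a label matrix; background (0, acellular) is
# folded into NORMAL_REGION since both carry zero tumor probability.
regionOneHot <- function(labels) {
  if (!all(labels %in% 0:3)) stop("region labels must be in {0, 1, 2, 3}")
  H <- nrow(labels); W <- ncol(labels)
  t <- array(0, c(H, W, 3))
  cls <- ifelse(labels == 0L, 3L, labels)
  for (k in 1:3) t[, , k] <- (cls == k) * 1
  t
}

#' Train the tumor-region segmentation network
#'
#' Pixel-wise 3-class cross-entropy on the softmax head; otherwise the same
#' optimizer, whitening, augmentation and checkpoint-selection behaviour as
#' [trainCnet()]. Inputs are region-scale RGB tiles (see
#' [downsampleImage()]); targets are region label matrices with values in
#' `{0, 1, 2, 3}` (background is folded into the normal class).
#'
#' @param tiles list of region-scale RGB arrays.
#' @param masks list of integer label matrices.
#' @param valTiles,valMasks optional validation set.
#' @inheritParams trainCnet
#' @return a trained [IHCNet-class].
#' @export
trainRnet <- function(tiles, masks, valTiles = list(), valMasks = list(),
                      epochs = 30L, batchSize = 4L, lr = 0.001,
                      momentum = 0.9, augment = augmentConfig(),
                      seed = 1L, model = NULL, baseWidth = 8L, depth = 2L,
                      lrDecayFactor = 1, lrDecayEvery = Inf,
                      clipNorm = 5, warmupEpochs = 5L) {
  if (is.null(model)) model <- buildRnet(baseWidth = baseWidth,
                                         depth = depth, seed = seed)
  targets <- lapply(masks, regionOneHot)
  valTargets <- lapply(valMasks, regionOneHot)
  lossFn <- function(model, x, tg, train) {
    fw <- nnForward(model, x, train = train)
    p <- pmax(fw$cache$out, 1e-9)
    nPix <- dim(p)[1] * dim(p)[2]
    loss <- -sum(tg * log(p)) / nPix
    dOutZ <- if (train) (fw$cache$out - tg) / nPix else NULL
    list(loss = loss, cache = fw$cache, dOutZ = dOutZ, dAuxZ = NULL)
  }
  runTraining(model, tiles, targets, valTiles, valTargets, epochs,
              batchSize, lr, momentum, augment, seed, lossFn,
              lrDecayFactor, lrDecayEvery, clipNorm, warmupEpochs)
}

#' Downsample an RGB image by an integer power-of-two factor
#'
#' Repeated 2x2 average pooling; used to derive region-scale (10x) tiles
#' from cell-scale (40x) tiles with the default scale factor 4.
#'
#' @param image numeric array `(H, W, C)`.
#' @param factor power of two, `>= 1`.
#' @return downsampled array.
#' @export
downsampleImage <- function(image, factor = 4L) {
  stopifnot(factor >= 1, bitwAnd(factor, factor - 1L) == 0L)
  while (factor > 1L) {
    image <- cpp_avgpool2(image)
    factor <- factor %/% 2L
  }
  image
}
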