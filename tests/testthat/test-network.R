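# Network contracts: shapes, ranges, backprop correctness, training
# determinism and seeded smoke runs.

test_that("cnet outputs full-resolution sigmoid maps for any input size", {
  net <- buildCnet(baseWidth = 4, depth = 2, seed = 1)
  p <- predictProbabilityMaps(net, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(p), c(64, 64, 5))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(dimnames(p)[[3]],
               c("TC_POS", "TC_NEG", "LYMPHOCYTE", "HISTOCYTE", "FIBROCYTE"))
  # non-divisible input is reflect-padded internally and cropped back
  odd <- predictProbabilityMaps(net, array(runif(50 * 70 * 3), c(50, 70, 3)))
  expect_equal(dim(odd), c(50, 70, 5))
})

test_that("doubling base width grows the parameter count, net stays valid", {
  n1 <- buildCnet(baseWidth = 4, depth = 2, seed = 1)
  n2 <- buildCnet(baseWidth = 8, depth = 2, seed = 1)
  count <- function(n) sum(vapply(n@weights, length, 1L))
  expect_gt(count(n2), count(n1))
  p <- predictProbabilityMaps(n2, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_true(all(is.finite(p)))
})

test_that("untrained cnet yields a finite loss against any target", {
  net <- buildCnet(baseWidth = 4, depth = 2, seed = 5)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tg <- makeTargetMaps(data.frame(x = 10L, y = 12L, cls = "TC_NEG"),
                       c(32, 32), 5)
  p <- predictProbabilityMaps(net, x)
  expect_true(is.finite(weightedPixelwiseCE(p, tg)))
})

test_that("rnet outputs a valid probability simplex at every pixel", {
  net <- buildRnet(baseWidth = 4, depth = 2, seed = 1)
  p <- predictProbabilityMaps(net, array(runif(128 * 128 * 3),
                                         c(128, 128, 3)))
  expect_equal(dim(p), c(128, 128, 3))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  expect_true(all(p >= 0))
})

test_that("hand-derived backprop matches finite differences", {
  set.seed(3)
  net <- buildCnet(baseWidth = 2, depth = 2, seed = 3)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  tg <- array(rbinom(8 * 8 * 5, 1, 0.2), c(8, 8, 5))
  cfg <- lossConfig(3, 3)
  lossOf <- function(w) {
    net@weights <- w
    fw <- PDL1score:::nnForward(net, x, train = TRUE)
    weightedPixelwiseCE(fw$cache$out, tg, cfg) +
      0.4 * weightedPixelwiseCE(fw$cache$aux$p,
                                PDL1score:::cpp_avgpool2(tg), cfg)
  }
  fw <- PDL1score:::nnForward(net, x, train = TRUE)
  p <- fw$cache$out
  dOutZ <- PDL1score:::weightedCEGrad(p, tg, cfg) * p * (1 - p)
  pa <- fw$cache$aux$p
  dAuxZ <- 0.4 * PDL1score:::weightedCEGrad(pa, PDL1score:::cpp_avgpool2(tg),
                                            cfg) * pa * (1 - pa)
  g <- PDL1score:::nnBackward(net, fw$cache, dOutZ, dAuxZ)
  eps <- 1e-5
  for (nm in c("enc1_w", "trans1_w", "skip2_w", "bott_w", "dec1_w",
               "head_w", "aux_b")) {
    for (i in sample(length(net@weights[[nm]]), 3)) {
      wp <- net@weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- net@weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossOf(wp) - lossOf(wm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   info = paste("weight", nm, "index", i))
    }
  }
})

test_that("seeded cnet smoke training reduces the loss deterministically", {
  set.seed(123)
  tiles <- lapply(1:8, function(i)
    simulateTile(synthSpec(tileWidth = 64, tileHeight = 64,
                           plannedTPS = 50, nTumorCells = 6,
                           nImmuneCells = 2, nFibrocytes = 1,
                           minSeparation = 10, seed = 300 + i)))
  imgs <- lapply(tiles, function(t) t@image)
  tgs <- lapply(tiles, function(t)
    makeTargetMaps(annotations(t), c(64, 64), 6))
  cn <- trainCnet(imgs, tgs, epochs = 15, lr = 0.05, seed = 0,
                  baseWidth = 4)
  expect_lt(tail(cn@history$train, 1), cn@history$train[1])
  # running minimum of the training loss is monotone non-increasing
  expect_true(all(diff(cummin(cn@history$train)) <= 0))
  cn2 <- trainCnet(imgs, tgs, epochs = 15, lr = 0.05, seed = 0,
                   baseWidth = 4)
  expect_identical(cn@history, cn2@history)
  expect_identical(cn@weights, cn2@weights)
  expect_error(trainCnet(list(), list()), "empty")
})

test_that("seeded rnet smoke training beats chance pixel accuracy", {
  tiles <- lapply(1:8, function(i)
    simulateTile(synthSpec(tileWidth = 64, tileHeight = 64,
                           plannedTPS = 50, nTumorCells = 6,
                           nImmuneCells = 2, nFibrocytes = 1,
                           minSeparation = 10, seed = 400 + i)))
  rimgs <- lapply(tiles, function(t) downsampleImage(t@image, 4))
  rmasks <- lapply(tiles, function(t) maskLabels(regionMask(t)))
  rn <- trainRnet(rimgs, rmasks, epochs = 40, lr = 0.05, seed = 0,
                  baseWidth = 4)
  expect_lt(tail(rn@history$train, 1), rn@history$train[1])
  acc <- mean(vapply(1:8, function(i) {
    p <- predictProbabilityMaps(rn, rimgs[[i]])
    predLab <- apply(p, c(1, 2), which.max)
    truthLab <- ifelse(rmasks[[i]] == 0L, 3L, rmasks[[i]])
    mean(predLab == truthLab)
  }, numeric(1)))
  expect_gt(acc, 1 / 3)
  rn2 <- trainRnet(rimgs, rmasks, epochs = 40, lr = 0.05, seed = 0,
                   baseWidth = 4)
  expect_identical(rn@history, rn2@history)
  expect_error(trainRnet(rimgs, lapply(rmasks, function(m) m + 7L)),
               "labels")
})
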