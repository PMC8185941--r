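# Synthetic tile generator: exactness, determinism, geometry, signal.

smallSpec <- function(seed, tps = 40, ...) {
  synthSpec(tileWidth = 128, tileHeight = 128, plannedTPS = tps,
            plannedIPS = 50, nTumorCells = 20, nImmuneCells = 10,
            nFibrocytes = 5, seed = seed, ...)
}

test_that("generated class counts realize the planned TPS exactly", {
  tile <- simulateTile(synthSpec(tileWidth = 256, tileHeight = 256,
                                 nTumorCells = 100, plannedTPS = 40,
                                 nImmuneCells = 10, nFibrocytes = 5,
                                 seed = 7))
  ann <- annotations(tile)
  expect_equal(sum(ann$cls == "TC_POS"), 40L)
  expect_equal(sum(ann$cls == "TC_NEG"), 60L)
  expect_equal(tps(truthScore(tile)), 40)
})

test_that("the generator is bit-deterministic in its seed", {
  a <- simulateTile(smallSpec(7))
  b <- simulateTile(smallSpec(7))
  expect_identical(a@image, b@image)
  expect_identical(annotations(a), annotations(b))
  expect_identical(maskLabels(regionMask(a)), maskLabels(regionMask(b)))
  c <- simulateTile(smallSpec(8))
  expect_false(identical(a@image, c@image))
})

test_that("truth score is recomputable exactly from the annotations", {
  for (seed in 1:5) {
    tile <- simulateTile(smallSpec(seed, tps = sample(c(0, 5, 25, 50, 90), 1)))
    ann <- annotations(tile)
    s <- truthScore(tile)
    expect_equal(tps(computeTPS(ann)), tps(s))
    expect_equal(unname(cellCounts(s)[["nIC"]]), sum(ann$intratumoral))
  }
})

test_that("cells respect geometry: inside tile, separated, adjacency pairs", {
  spec <- smallSpec(11)
  tile <- simulateTile(spec)
  ann <- annotations(tile)
  expect_true(all(ann$x >= 0 & ann$x < 128 & ann$y >= 0 & ann$y < 128))
  d <- as.matrix(dist(ann[, c("x", "y")]))
  diag(d) <- Inf
  minPair <- apply(d, 1, min)
  # most pairs respect minSeparation; the deliberately adjacent pairs sit
  # near 0.8 x nuclear diameter (11.2 px)
  expect_true(any(minPair >= spec@minSeparation))
  close <- minPair[minPair < spec@minSeparation]
  if (length(close)) expect_true(all(close > 8))
})

test_that("TC(+) cells lie in TC(+) regions and ICs in tumor regions", {
  for (seed in c(3, 13)) {
    tile <- simulateTile(smallSpec(seed))
    ann <- annotations(tile)
    lab <- maskLabels(regionMask(tile))
    regOf <- function(x, y) lab[cbind(floor(y / 4) + 1L, floor(x / 4) + 1L)]
    pos <- ann[ann$cls == "TC_POS", ]
    expect_true(all(regOf(pos$x, pos$y) == 1L))
    ics <- ann[ann$intratumoral, ]
    expect_true(all(regOf(ics$x, ics$y) %in% c(1L, 2L)))
  }
})

test_that("tumor area fraction tracks the request over seeded tiles", {
  fr <- vapply(1:20, function(seed) {
    lab <- maskLabels(regionMask(simulateTile(smallSpec(seed))))
    mean(lab %in% c(1L, 2L))
  }, numeric(1))
  expect_true(all(fr >= 0.4 & fr <= 0.6))
})

test_that("membranous DAB signal separates TC(+) from TC(-) by construction", {
  for (seed in c(2, 22)) {
    tile <- simulateTile(smallSpec(seed, tps = 50))
    dab <- stainConcentrations(tile@image)$dab
    ann <- annotations(tile)
    mdab <- function(df) mean(vapply(seq_len(nrow(df)), function(i)
      PDL1score:::diskMean(dab, df$x[i], df$y[i], 9), numeric(1)))
    expect_gt(mdab(ann[ann$cls == "TC_POS", ]),
              mdab(ann[ann$cls == "TC_NEG", ]))
  }
})

test_that("impossible packing raises an error instead of truncating", {
  expect_error(simulateTile(synthSpec(tileWidth = 64, tileHeight = 64,
                                      nTumorCells = 300, plannedTPS = 50,
                                      nImmuneCells = 0, nFibrocytes = 0,
                                      seed = 1)),
               "packing")
  expect_error(simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                                      nTumorCells = 10, plannedTPS = 50,
                                      tumorAreaFraction = 0,
                                      nImmuneCells = 0, nFibrocytes = 0,
                                      seed = 1)),
               "packing")
})

test_that("slide truth sums tile counts rather than averaging TPS", {
  sl <- simulateSlide(list(smallSpec(1, tps = 10), smallSpec(2, tps = 90)))
  expect_equal(tps(sl$score), 50)          # (2 + 18) / 40
  oneTile <- simulateSlide(list(smallSpec(3)))
  expect_equal(cellCounts(oneTile$score),
               cellCounts(truthScore(oneTile$tiles[[1]])))
  # empty-tumor tile + 50% tile: slide TPS equals the 50% tile's ratio
  empty <- synthSpec(tileWidth = 128, tileHeight = 128, plannedTPS = 0,
                     nTumorCells = 0, nImmuneCells = 6, nFibrocytes = 3,
                     seed = 4)
  mix <- simulateSlide(list(empty, smallSpec(5, tps = 50)))
  expect_equal(tps(mix$score), 50)
})

test_that("fixture writer materializes a readable standard set", {
  dir <- withr::local_tempdir()
  prefixes <- writeFixtures(dir)
  expect_length(prefixes, 3L)
  ann <- readAnnotations(paste0(prefixes[1], "_cells.csv"))
  img <- readImagePNG(paste0(prefixes[1], ".png"))
  mask <- readRegionMask(paste0(prefixes[1], "_regions.png"))
  truth <- jsonlite::read_json(paste0(prefixes[1], "_truth.json"))
  expect_gt(nrow(ann), 0)
  expect_equal(dim(img), c(128, 128, 3))
  expect_true(all(maskLabels(mask) %in% 0:3))
  expect_equal(truth$counts$nTCPos + truth$counts$nTCNeg, 20)
  # the PNG-serialized image reproduces the in-memory tile bit-exactly
  tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                                 nTumorCells = 20, nImmuneCells = 10,
                                 nFibrocytes = 5, plannedTPS = 25, seed = 1))
  expect_equal(img, tile@image, tolerance = 1e-9)
})
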