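# TPS / IPS computation, categories and slide aggregation.

det <- function(...) {
  cls <- c(...)
  data.frame(x = seq_along(cls), y = seq_along(cls), cls = cls)
}

test_that("TPS is the tumor-cell count ratio, ignoring immune cells", {
  d <- det(rep("TC_POS", 30), rep("TC_NEG", 70),
           rep("LYMPHOCYTE", 12), rep("FIBROCYTE", 4))
  s <- computeTPS(d)
  expect_equal(tps(s), 30)
  expect_equal(category(s), "MODERATE")
  expect_equal(tps(computeTPS(det(rep("TC_NEG", 50)))), 0)

  none <- computeTPS(det(rep("HISTOCYTE", 5)))
  expect_false(none@amenable)
  expect_true(is.na(tps(none)))
})

test_that("TPS is invariant to non-tumor detections and monotone in TC(+)", {
  base <- det(rep("TC_POS", 10), rep("TC_NEG", 30))
  extra <- rbind(base, det(rep("LYMPHOCYTE", 25)))
  expect_equal(tps(computeTPS(base)), tps(computeTPS(extra)))
  prev <- -1
  for (npos in 0:8) {
    s <- computeTPS(det(rep("TC_POS", npos), rep("TC_NEG", 8 - npos)))
    expect_gt(tps(s), prev)
    prev <- tps(s)
  }
})

test_that("expression categories use half-open clinical bins", {
  expect_equal(categorizeTPS(0), "NEGATIVE")
  expect_equal(categorizeTPS(0.5), "NEGATIVE")
  expect_equal(categorizeTPS(1), "LOW")       # boundary to the upper bin
  expect_equal(categorizeTPS(24.999), "LOW")
  expect_equal(categorizeTPS(25), "MODERATE")
  expect_equal(categorizeTPS(49.999), "MODERATE")
  expect_equal(categorizeTPS(50), "HIGH")
  expect_equal(categorizeTPS(100), "HIGH")
  expect_error(categorizeTPS(101), "within")
  expect_error(categorizeTPS(-1), "within")
})

test_that("slide aggregation sums counts, never averages per-tile TPS", {
  a <- PDL1score:::newSlideScore(10, 90)
  b <- PDL1score:::newSlideScore(30, 10)
  s <- aggregateSlide(list(a, b))
  expect_equal(tps(s), 100 * 40 / 140, tolerance = 1e-12)
  expect_equal(round(tps(s), 2), 28.57)
  expect_false(isTRUE(all.equal(tps(s), mean(c(10, 75)))))

  expect_equal(tps(aggregateSlide(list(a))), tps(a))  # identity on one tile

  # a tile with no tumor cells contributes its IC counts only
  empty <- PDL1score:::newSlideScore(0, 0, nIC = 4, nICPos = 2)
  s2 <- aggregateSlide(list(a, empty))
  expect_equal(tps(s2), 10)
  expect_equal(unname(cellCounts(s2)[c("nIC", "nICPos")]), c(4, 2))

  # (10,90) + (90,10) gives 50 from summed counts
  s3 <- aggregateSlide(list(PDL1score:::newSlideScore(10, 90),
                            PDL1score:::newSlideScore(90, 10)))
  expect_equal(tps(s3), 50)
})

test_that("IPS is the positive fraction of ICs, undefined without ICs", {
  expect_equal(computeIPS(rep(c(TRUE, FALSE), c(5, 15)))$ips, 25)
  expect_equal(computeIPS(rep(TRUE, 7))$ips, 100)
  none <- computeIPS(logical(0))
  expect_true(is.na(none$ips))
  expect_false(none$defined)
})

test_that("stain deconvolution recovers planted DAB and drives IC calls", {
  tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                                 nTumorCells = 12, nImmuneCells = 10,
                                 nFibrocytes = 3, plannedTPS = 50,
                                 plannedIPS = 50, seed = 42))
  ann <- annotations(tile)
  ic <- icPositivity(tile@image, ann, regionMask(tile))
  # gating: exactly the intratumoral lymphocytes/histocytes are ICs
  expect_equal(nrow(ic), sum(ann$intratumoral))
  # generator <-> deconvolution consistency: planted positivity recovered
  truthFlags <- ann$positive[ann$intratumoral &
                               ann$cls %in% c("LYMPHOCYTE", "HISTOCYTE")]
  expect_equal(sum(ic$positive), sum(truthFlags))
  s <- scoreTile(tile@image, ann, regionMask(tile))
  expect_equal(ips(s), ips(truthScore(tile)))
})

test_that("scoring ground-truth annotations returns planned TPS exactly", {
  for (planned in c(0, 25, 90)) {
    tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
                                   nTumorCells = 20, nImmuneCells = 6,
                                   nFibrocytes = 3, plannedTPS = planned,
                                   seed = 100 + planned))
    expect_equal(tps(computeTPS(annotations(tile))), planned)
    expect_equal(tps(truthScore(tile)), planned)
  }
})
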