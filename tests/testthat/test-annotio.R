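# Readers/writers, tiling arithmetic and detection stitching.

test_that("annotation CSV and JSON round-trip losslessly", {
  ann <- data.frame(x = c(12L, 0L, 99L), y = c(34L, 0L, 5L),
                    cls = c("TC_POS", "LYMPHOCYTE", "FIBROCYTE"))
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeAnnotations(ann, path)
    back <- readAnnotations(path)
    expect_equal(back, ann, ignore_attr = TRUE)
  }
})

test_that("annotation reader enforces the class vocabulary and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,class", "12,34,TC_POS", "1,2,TCPLUS"), path)
  expect_error(readAnnotations(path), "TCPLUS")
  expect_error(readAnnotations(path), "row 2")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,class", empty)
  expect_equal(nrow(readAnnotations(empty)), 0L)

  ok <- readAnnotations({
    p <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("x,y,class", "12,34,TC_POS"), p); p
  })
  expect_equal(ok$x, 12L)
  expect_equal(ok$y, 34L)
  expect_equal(ok$cls, "TC_POS")
})

test_that("images and region masks round-trip through PNG", {
  img <- array(round(runif(32 * 32 * 3) * 255) / 255, c(32, 32, 3))
  p <- withr::local_tempfile(fileext = ".png")
  writeImagePNG(img, p)
  expect_equal(readImagePNG(p), img, tolerance = 1e-9)

  lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  mask <- new("RegionMask", labels = lab, scaleFactor = 4)
  mp <- withr::local_tempfile(fileext = ".png")
  writeRegionMask(mask, mp)
  back <- readRegionMask(mp)
  expect_identical(maskLabels(back), lab)
  expect_equal(scaleFactor(back), 4)
})

test_that("score tables are validated on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = c("a", "b"), rater_a = c(10, 50),
                       rater_b = c(15, 55), subtype = c("SCC", "AD")),
            p, row.names = FALSE)
  tab <- readScoreTable(p)
  expect_equal(nrow(tab), 2L)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = "a", rater_a = 150, rater_b = 10),
            bad, row.names = FALSE)
  expect_error(readScoreTable(bad), "outside")
})

test_that("tiling covers the image with the expected grid and padding", {
  img <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  tiles <- tileImage(img, 512, 0)
  expect_length(tiles, 4L)
  offs <- t(vapply(tiles, function(t) t$offset, c(x = 0, y = 0)))
  expect_setequal(paste(offs[, "x"], offs[, "y"]),
                  c("0 0", "512 0", "0 512", "512 512"))
  expect_true(all(vapply(tiles, function(t) all(t$pad == 0), TRUE)))

  img600 <- array(runif(600 * 600 * 3), c(600, 600, 3))
  t600 <- tileImage(img600, 512, 0)
  expect_length(t600, 4L)
  pads <- t(vapply(t600, function(t) t$pad, c(x = 0, y = 0)))
  expect_equal(max(pads), 424)             # 2 * 512 - 600
  expect_equal(dim(t600[[4]]$tile), c(512, 512, 3))

  tov <- tileImage(img, 512, 64)           # stride 448 -> 3 x 3 grid
  expect_length(tov, 9L)
  expect_equal(sort(unique(vapply(tov, function(t) t$offset[["x"]], 0))),
               c(0, 448, 896))

  expect_warning(tileImage(array(runif(300), c(10, 10, 3)), 64, 0),
                 "single")
})

test_that("reflection padding mirrors edge content", {
  img <- array(seq_len(8 * 8 * 1) / 64, c(8, 8, 1))
  t <- tileImage(img, 6, 0)
  edge <- t[[4]]$tile                      # bottom-right tile, pad 4
  expect_equal(edge[1:2, 1:2, 1], img[7:8, 7:8, 1])
  expect_equal(edge[, 3, 1], edge[, 2, 1]) # mirrored around the last column
  expect_equal(edge[, 4, 1], edge[, 1, 1])
})

test_that("detections map to parent coordinates and pads are dropped", {
  d <- data.frame(x = 10, y = 10, cls = "TC_POS", score = 0.9)
  out <- detectionsToParent(d, c(x = 512, y = 0))
  expect_equal(out$x, 522)
  expect_equal(out$y, 10)
  expect_equal(nrow(detectionsToParent(d[0, ], c(x = 0, y = 0))), 0L)
  # a detection inside the reflected pad is an artifact and is dropped
  padded <- data.frame(x = 510, y = 5, cls = "TC_POS", score = 0.8)
  out2 <- detectionsToParent(padded, c(x = 0, y = 0),
                             pad = c(x = 100, y = 0), tileSize = 512)
  expect_equal(nrow(out2), 0L)
})

test_that("stitching keeps one copy per physical cell in overlap zones", {
  img <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  tiles <- tileImage(img, 512, 64)
  # one physical cell at parent (470, 100): tile (0,0) sees it at (470,100),
  # tile offset (448,0) sees it at (22,100)
  detList <- rep(list(data.frame(x = integer(0), y = integer(0),
                                 cls = character(0), score = numeric(0))),
                 length(tiles))
  i1 <- which(vapply(tiles, function(t)
    t$offset[["x"]] == 0 && t$offset[["y"]] == 0, TRUE))
  i2 <- which(vapply(tiles, function(t)
    t$offset[["x"]] == 448 && t$offset[["y"]] == 0, TRUE))
  detList[[i1]] <- data.frame(x = 470, y = 100, cls = "TC_POS", score = 0.8)
  detList[[i2]] <- data.frame(x = 22, y = 101, cls = "TC_POS", score = 0.9)
  merged <- stitchDetections(detList, tiles, 512, radius = 9)
  expect_equal(nrow(merged), 1L)
  # the copy closer to its own tile center wins: (470,100) is 265 px from
  # tile 1's center, (22,101) is 280 px from tile 2's center
  expect_equal(merged$y, 100)
  # disjoint tiles: stitching is the identity on coordinates
  tiles0 <- tileImage(img, 512, 0)
  det0 <- lapply(tiles0, function(t)
    data.frame(x = 100, y = 200, cls = "TC_NEG", score = 0.7))
  m0 <- stitchDetections(det0, tiles0, 512, radius = 9)
  expect_equal(nrow(m0), 4L)
  expect_setequal(m0$x, c(100, 612))
})

test_that("the 60/20/20 split is stratified and seed deterministic", {
  strata <- rep(c(0, 5, 25, 50, 90), each = 10)
  sp <- splitDataset(strata, seed = 3)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:50)
  expect_length(sp$train, 30L)
  expect_length(sp$validation, 10L)
  expect_length(sp$test, 10L)
  for (s in unique(strata))                # stratification: 6/2/2 per level
    expect_equal(sum(strata[sp$train] == s), 6L)
  expect_identical(sp, splitDataset(strata, seed = 3))
  expect_false(identical(sp, splitDataset(strata, seed = 4)))
})
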