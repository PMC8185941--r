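# End-to-end orchestration: simulate synthetic slides, train the two
# networks, score slides with the multistage ensemble, and evaluate
# concordance of recovered vs planned TPS.

#' Score a slide with the trained network ensemble
#'
#' For each tile: run the cellular localization network at cell scale; run
#' the region segmenter on the 4x-downsampled tile; if `useMask`, multiply
#' the tumor-cell probability channels by the upsampled tumor probability
#' ([maskCellMaps()]); extract detections; gate and score immune cells on
#' the predicted region mask; finally aggregate counts over tiles
#' ([aggregateSlide()]).
#'
#' @param images list of cell-scale RGB arrays `(H, W, 3)` in `[0, 1]`.
#' @param cnet,rnet trained [IHCNet-class] handles.
#' @param useMask logical: apply the R-Net tumor-probability masking (the
#'   ensemble step); `FALSE` gives the C-Net-only ablation.
#' @param threshold,minDistance peak extraction settings
#'   ([extractDetections()]); the default suppression distance (11 px)
#'   sits just below the smallest true center separation the generator
#'   produces (adjacent pairs at 11.2 px).
#' @param odThreshold,diskRadius immune-cell positivity settings
#'   ([icPositivity()]).
#' @param scaleFactor cell-scale / region-scale ratio (default 4).
#' @return list: `score` (slide [SlideScore-class]), `tileScores`,
#'   `detections` (per-tile `data.frame`s).
#' @export
scoreSlide <- function(images, cnet, rnet, useMask = TRUE, threshold = 0.5,
                       minDistance = 11, odThreshold = 0.15, diskRadius = 9,
                       scaleFactor = 4L) {
  tileScores <- list()
  detections <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    cellProb <- predictProbabilityMaps(cnet, img)
    regionProb <- predictProbabilityMaps(rnet,
                                         downsampleImage(img, scaleFactor))
    if (useMask) {
      tp <- tumorProbability(regionProb, scaleFactor)
      cellProb <- maskCellMaps(cellProb, tp)
    }
    det <- extractDetections(cellProb, threshold, minDistance)
    mask <- regionProbToMask(regionProb, scaleFactor)
    tileScores[[i]] <- scoreTile(img, det, mask,
                                 odThreshold = odThreshold,
                                 diskRadius = diskRadius)
    detections[[i]] <- det
  }
  list(score = aggregateSlide(tileScores), tileScores = tileScores,
       detections = detections)
}

#' Default pipeline configuration
#'
#' Desk-scale settings: 128 x 128 tiles with 20 tumor cells each (counts
#' divisible by 20 keep the planned TPS levels exactly realizable), TPS
#' levels spanning the clinical categories, compact networks and short
#' training budgets. `fullScale = TRUE` switches to the full-scale recipe
#' (512 px tiles, batch 4, lr 0.001, 200 epochs).
#'
#' @param seed master seed; all per-tile seeds derive from it.
#' @param outDir results directory.
#' @param fullScale use the full-scale training settings.
#' @return a config list (also serializable to YAML).
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("pdl1run"),
                           fullScale = FALSE) {
  cfg <- list(
    seed = as.integer(seed), outDir = outDir,
    tileSize = 128L, tilesPerSlide = 2L,
    tpsLevels = c(0, 5, 25, 50, 90), slidesPerLevel = 3L,
    nTumorCells = 20L, nImmuneCells = 10L, nFibrocytes = 5L,
    tumorAreaFraction = 0.5, stainNoiseSD = 0.02, plannedIPS = 50,
    minSeparation = 14,
    # training fixture: small tiles keep the per-update cost low so the
    # compact networks can afford enough SGD updates on one CPU
    trainTileSize = 64L, trainTumorCells = 6L, trainImmuneCells = 4L,
    trainFibrocytes = 2L, trainMinSeparation = 10,
    nTrainTiles = 25L, epochs = 300L, batchSize = 4L, lr = 0.05,
    lrDecayFactor = 0.5, lrDecayEvery = 120L,
    momentum = 0.9, lambda = 3, gamma = 3, baseWidth = 8L, depth = 2L,
    detectionThreshold = 0.5, minDistance = 11, odThreshold = 0.15,
    diskRadius = 9, lymphDiskRadius = 9, matchRadius = 9, useMask = TRUE
  )
  if (fullScale) {
    cfg$tileSize <- 512L
    cfg$trainTileSize <- 512L
    cfg$trainTumorCells <- 100L
    cfg$trainImmuneCells <- 25L
    cfg$trainFibrocytes <- 20L
    cfg$trainMinSeparation <- 14
    cfg$epochs <- 200L
    cfg$lr <- 0.001
    cfg$lrDecayFactor <- 1
    cfg$nTrainTiles <- 60L
  }
  cfg$hash <- configHash(cfg[setdiff(names(cfg), c("outDir", "hash"))])
  cfg
}

# Derived per-tile seed, kept below 2^31.
tileSeed <- function(seed, slide, tile) {
  (as.integer(seed) * 97L + slide * 13L + tile) %% 2000000000L
}

specForConfig <- function(cfg, plannedTPS, seed, train = FALSE) {
  if (train) {
    synthSpec(tileWidth = cfg$trainTileSize, tileHeight = cfg$trainTileSize,
              plannedTPS = plannedTPS, plannedIPS = cfg$plannedIPS,
              nTumorCells = cfg$trainTumorCells,
              nImmuneCells = cfg$trainImmuneCells,
              nFibrocytes = cfg$trainFibrocytes,
              tumorAreaFraction = cfg$tumorAreaFraction,
              stainNoiseSD = cfg$stainNoiseSD,
              minSeparation = cfg$trainMinSeparation, seed = seed)
  } else {
    synthSpec(tileWidth = cfg$tileSize, tileHeight = cfg$tileSize,
              plannedTPS = plannedTPS, plannedIPS = cfg$plannedIPS,
              nTumorCells = cfg$nTumorCells, nImmuneCells = cfg$nImmuneCells,
              nFibrocytes = cfg$nFibrocytes,
              tumorAreaFraction = cfg$tumorAreaFraction,
              stainNoiseSD = cfg$stainNoiseSD,
              minSeparation = cfg$minSeparation, seed = seed)
  }
}

#' Simulate the study's synthetic slide set
#'
#' `slidesPerLevel` slides at each planned TPS level, `tilesPerSlide` tiles
#' each, with seeds derived deterministically from the master seed.
#'
#' @param cfg a [pipelineConfig()].
#' @return list of slides; each slide is the [simulateSlide()] result plus
#'   `plannedTPS`.
#' @export
simulateStudySlides <- function(cfg) {
  slides <- list()
  s <- 0L
  for (lev in cfg$tpsLevels) {
    for (r in seq_len(cfg$slidesPerLevel)) {
      s <- s + 1L
      specs <- lapply(seq_len(cfg$tilesPerSlide), function(t)
        specForConfig(cfg, lev, tileSeed(cfg$seed, s, t)))
      sl <- simulateSlide(specs)
      sl$plannedTPS <- lev
      slides[[s]] <- sl
    }
  }
  slides
}

#' Train both networks on simulated tiles
#'
#' Simulates `nTrainTiles` training tiles (TPS levels cycled so every
#' expression category is represented), splits them 60/20/20
#' ([splitDataset()]) and trains the localization network on cell-scale
#' tiles/target maps and the region segmenter on downsampled tiles/region
#' labels.
#'
#' @param cfg a [pipelineConfig()].
#' @param lossCfg loss used for the localization network (default the
#'   weighted loss with the configured lambda/gamma).
#' @return list `cnet`, `rnet`, `split`, `tiles`.
#' @export
trainPipelineNetworks <- function(cfg, lossCfg = NULL) {
  if (is.null(lossCfg)) lossCfg <- lossConfig(cfg$lambda, cfg$gamma)
  levs <- rep(cfg$tpsLevels, length.out = cfg$nTrainTiles)
  tiles <- lapply(seq_len(cfg$nTrainTiles), function(i)
    simulateTile(specForConfig(cfg, levs[i],
                               tileSeed(cfg$seed + 7L, 1000L + i, 1L),
                               train = TRUE)))
  split <- splitDataset(levs, seed = cfg$seed)
  trIdx <- split$train
  imgs <- lapply(tiles, function(t) t@image)
  radii <- c(TC_POS = cfg$diskRadius, TC_NEG = cfg$diskRadius,
             LYMPHOCYTE = cfg$lymphDiskRadius, HISTOCYTE = cfg$diskRadius,
             FIBROCYTE = cfg$diskRadius)
  tmaps <- lapply(tiles, function(t)
    makeTargetMaps(annotations(t), dim(t@image)[1:2], radii))
  # region-scale inputs for the segmenter
  cnet <- trainCnet(imgs[trIdx], tmaps[trIdx],
                    imgs[split$validation], tmaps[split$validation],
                    epochs = cfg$epochs, batchSize = cfg$batchSize,
                    lr = cfg$lr, momentum = cfg$momentum, lossCfg = lossCfg,
                    seed = cfg$seed, baseWidth = cfg$baseWidth,
                    depth = cfg$depth, lrDecayFactor = cfg$lrDecayFactor,
                    lrDecayEvery = cfg$lrDecayEvery)
  # the region segmenter trains on full-size tiles at region scale, where
  # nest geometry is actually resolved (training thumbnails are too small)
  rlevs <- rep(cfg$tpsLevels, length.out = 15L)
  rtiles <- lapply(seq_along(rlevs), function(i)
    simulateTile(specForConfig(cfg, rlevs[i],
                               tileSeed(cfg$seed + 13L, 2000L + i, 1L))))
  rsplit <- splitDataset(rlevs, seed = cfg$seed + 1L)
  rimgs <- lapply(rtiles, function(t) downsampleImage(t@image, 4L))
  rmasks <- lapply(rtiles, function(t) maskLabels(regionMask(t)))
  rTr <- c(rsplit$train, rsplit$test)
  rnet <- trainRnet(rimgs[rTr], rmasks[rTr],
                    rimgs[rsplit$validation], rmasks[rsplit$validation],
                    epochs = cfg$epochs, batchSize = cfg$batchSize,
                    lr = cfg$lr, momentum = cfg$momentum,
                    seed = cfg$seed, baseWidth = cfg$baseWidth,
                    depth = cfg$depth, lrDecayFactor = cfg$lrDecayFactor,
                    lrDecayEvery = cfg$lrDecayEvery)
  list(cnet = cnet, rnet = rnet, split = split, tiles = tiles)
}

#' Run the full pipeline
#'
#' simulate -> train -> score -> evaluate, writing the configuration
#' (YAML), per-slide score table (CSV), loss histories (CSV) and the
#' concordance report (JSON) into `cfg$outDir`.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with the trained networks, slide table and
#'   [ConcordanceReport-class].
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[setdiff(names(cfg), "outDir")],
                   file.path(cfg$outDir, "config.yaml"))
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = file.path(cfg$outDir, "run.log"), append = TRUE)
  }
  logf("seed=%d config=%s", cfg$seed, cfg$hash)
  t0 <- proc.time()[3]
  nets <- trainPipelineNetworks(cfg)
  logf("training done (%.1f s)", proc.time()[3] - t0)
  write.csv(nets$cnet@history, file.path(cfg$outDir, "cnet_loss.csv"),
            row.names = FALSE)
  write.csv(nets$rnet@history, file.path(cfg$outDir, "rnet_loss.csv"),
            row.names = FALSE)
  slides <- simulateStudySlides(cfg)
  rows <- lapply(seq_along(slides), function(i) {
    sl <- slides[[i]]
    res <- scoreSlide(lapply(sl$tiles, function(t) t@image),
                      nets$cnet, nets$rnet, useMask = cfg$useMask,
                      threshold = cfg$detectionThreshold,
                      minDistance = cfg$minDistance,
                      odThreshold = cfg$odThreshold,
                      diskRadius = cfg$diskRadius)
    s <- res$score
    data.frame(case_id = sprintf("slide%03d", i),
               planned_tps = sl$plannedTPS,
               truth_tps = tps(sl$score),
               pred_tps = if (s@amenable) tps(s) else NA_real_,
               pred_ips = ips(s),
               nTCPos = s@nTCPos, nTCNeg = s@nTCNeg,
               category = if (s@amenable) category(s) else NA_character_,
               amenable = s@amenable)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(cfg$outDir, "scores.csv"), row.names = FALSE)
  ok <- !is.na(tab$pred_tps)
  report <- NULL
  payload <- list(n = sum(ok), icc = NA, icc_ci = c(NA, NA), pearson = NA,
                  spearman = NA, kappa = list())
  if (sum(ok) >= 5) {    # reliability statistics need enough amenable slides
    report <- concordanceReport(tab$planned_tps[ok], tab$pred_tps[ok])
    payload <- list(n = report@n, icc = report@icc, icc_ci = report@iccCI,
                    pearson = report@pearson, spearman = report@spearman,
                    kappa = as.list(report@kappa))
  }
  jsonlite::write_json(payload, file.path(cfg$outDir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  logf("scored %d slides (%.1f s total)", nrow(tab), proc.time()[3] - t0)
  invisible(list(cnet = nets$cnet, rnet = nets$rnet, slides = tab,
                 report = report, outDir = cfg$outDir))
}

#' Write a detection overlay image
#'
#' Marks detections on the tile with per-class colored squares (TC(+) red,
#' TC(-) green, lymphocyte blue, histocyte purple, fibrocyte orange).
#'
#' @param image RGB array.
#' @param detections detection `data.frame`.
#' @param path output PNG path.
#' @export
writeOverlayPNG <- function(image, detections, path) {
  cols <- c(TC_POS = "#FF0000", TC_NEG = "#00C000", LYMPHOCYTE = "#0000FF",
            HISTOCYTE = "#A000C0", FIBROCYTE = "#FF8000")
  H <- nrow(image); W <- ncol(image)
  for (i in seq_len(nrow(detections))) {
    rgb <- col2rgb(cols[[detections$cls[i]]]) / 255
    ys <- pmax(1L, pmin(H, detections$y[i] + 1L + (-1:1)))
    xs <- pmax(1L, pmin(W, detections$x[i] + 1L + (-1:1)))
    for (ch in 1:3) image[ys, xs, ch] <- rgb[ch]
  }
  writeImagePNG(image, path)
}
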