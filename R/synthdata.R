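# Synthetic bright-field IHC tile generator with exact ground truth.
#
# Tiles emulate PD-L1 IHC at the 40x cell scale: hematoxylin-blue nuclei,
# DAB-brown membranous staining on PD-L1-positive tumor cells, diffuse
# brown cytoplasm on PD-L1-positive immune cells, tumor cells packed in
# nest-shaped regions and fibrocytes in stroma. Colors are composed by
# linear mixing of reference stain vectors in optical-density space, so
# color deconvolution downstream recovers the planted DAB signal.

#' Construct a synthetic-tile specification
#'
#' Defaults describe a realistic 512 x 512 tile at 40x: 100 tumor cells in
#' nests covering half the tile, 25 immune cells (60 percent intratumoral),
#' 20 stromal fibrocytes, planned TPS 30 and IPS 20, mild stain noise.
#' `round(nTumorCells * plannedTPS / 100)` tumor cells are generated TC(+)
#' -- the realized count is exact, not sampled.
#'
#' @param tileWidth,tileHeight tile size in pixels; must be divisible by 4
#'   (the region-mask scale factor).
#' @param plannedTPS,plannedIPS planned scores in percent.
#' @param nTumorCells,nImmuneCells,nFibrocytes population sizes.
#' @param tumorAreaFraction fraction of the tile covered by tumor nests.
#' @param stainNoiseSD Gaussian noise SD in optical-density space.
#' @param seed integer seed; generation is bit-deterministic in it.
#' @param icTumorFraction fraction of immune cells placed in tumor regions.
#' @param adjacentFraction fraction of tumor cells generated as adjacent
#'   pairs at 0.8 x nuclear diameter (close/adhesive cells).
#' @param minSeparation minimum center distance (px) for all other pairs.
#' @param stromalHistPosProb probability a stromal histocyte is PD-L1+.
#' @return a [SynthSpec-class].
#' @export
synthSpec <- function(tileWidth = 512L, tileHeight = 512L,
                      plannedTPS = 30, plannedIPS = 20,
                      nTumorCells = 100L, nImmuneCells = 25L,
                      nFibrocytes = 20L, tumorAreaFraction = 0.5,
                      stainNoiseSD = 0.02, seed = 1L,
                      icTumorFraction = 0.6, adjacentFraction = 0.15,
                      minSeparation = 14, stromalHistPosProb = 0.5) {
  new("SynthSpec",
      tileWidth = as.integer(tileWidth), tileHeight = as.integer(tileHeight),
      plannedTPS = plannedTPS, plannedIPS = plannedIPS,
      nTumorCells = as.integer(nTumorCells),
      nImmuneCells = as.integer(nImmuneCells),
      nFibrocytes = as.integer(nFibrocytes),
      tumorAreaFraction = tumorAreaFraction, stainNoiseSD = stainNoiseSD,
      seed = as.integer(seed), icTumorFraction = icTumorFraction,
      adjacentFraction = adjacentFraction, minSeparation = minSeparation,
      stromalHistPosProb = stromalHistPosProb)
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Elliptical-nest tumor mask at region scale. Returns an integer matrix
# (h x w) with REGION_LABELS codes; all tumor pixels are provisionally
# TC(-) region (the TC(+)/TC(-) split is derived later from the placed
# cells). Nest radii are calibrated iteratively so realized tumor coverage
# tracks the requested fraction.
makeRegionLabels <- function(h, w, tumorFrac) {
  lab <- matrix(REGION_LABELS[["NORMAL_REGION"]], h, w)
  if (tumorFrac > 0) {
    nNests <- if (tumorFrac < 0.3) 2L else 3L
    cx <- runif(nNests, 0.15 * w, 0.85 * w)
    cy <- runif(nNests, 0.15 * h, 0.85 * h)
    ang <- runif(nNests, 0, pi)
    ratio <- runif(nNests, 1.1, 1.7)
    # per-nest area so the union (before clipping/overlap) hits the target
    base <- sqrt(tumorFrac * h * w / (nNests * pi))
    a <- base * sqrt(ratio); b <- base / sqrt(ratio)
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, w), h, w)
    scale <- 1
    for (iter in 1:8) {
      tumor <- matrix(FALSE, h, w)
      for (k in seq_len(nNests)) {
        dx <- xs - cx[k]; dy <- ys - cy[k]
        u <- dx * cos(ang[k]) + dy * sin(ang[k])
        v <- -dx * sin(ang[k]) + dy * cos(ang[k])
        tumor <- tumor | (u / (scale * a[k]))^2 + (v / (scale * b[k]))^2 <= 1
      }
      f <- mean(tumor)
      if (abs(f - tumorFrac) < 0.01 || f <= 0) break
      scale <- scale * sqrt(tumorFrac / f) # clipping/overlap compensation
    }
    lab[tumor] <- REGION_LABELS[["TC_NEG_REGION"]]
  }
  # a couple of small acellular holes (background) in the stroma
  nHoles <- sample(0:2, 1L)
  if (nHoles > 0) {
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, w), h, w)
    for (k in seq_len(nHoles)) {
      hx <- runif(1, 0.1 * w, 0.9 * w); hy <- runif(1, 0.1 * h, 0.9 * h)
      hr <- runif(1, 0.02, 0.05) * min(h, w)
      hole <- (xs - hx)^2 + (ys - hy)^2 <= hr^2 &
        lab == REGION_LABELS[["NORMAL_REGION"]]
      lab[hole] <- REGION_LABELS[["BACKGROUND"]]
    }
  }
  lab
}

# Rejection-sample n cell centers on `allowed` (logical, cell scale),
# respecting minSep against all previously placed centers. Errors on
# impossible packing rather than silently truncating.
placeCenters <- function(n, allowed, minSep, placed, margin = 6) {
  if (n == 0L) return(placed)
  H <- nrow(allowed); W <- ncol(allowed)
  ok <- allowed
  if (margin > 0) {
    ok[c(seq_len(min(margin, H)), seq_len(min(margin, H)) + H - min(margin, H)), ] <- FALSE
    ok[, c(seq_len(min(margin, W)), seq_len(min(margin, W)) + W - min(margin, W))] <- FALSE
  }
  cand <- which(ok)
  if (length(cand) == 0L)
    stop("impossible packing: no admissible pixels for requested cells")
  attempts <- 0L; maxAttempts <- 400L * n + 2000L
  placedN <- 0L
  while (placedN < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(
        "impossible packing: placed %d of %d cells after %d attempts",
        placedN, n, attempts))
    pix <- cand[sample.int(length(cand), 1L)]
    y <- (pix - 1L) %% H; x <- (pix - 1L) %/% H
    if (nrow(placed) == 0L ||
        all((placed$x - x)^2 + (placed$y - y)^2 >= minSep^2)) {
      placed <- rbind(placed, data.frame(x = x, y = y))
      placedN <- placedN + 1L
    }
  }
  placed
}

# Place nPairs additional partners adjacent (at `dist` px) to randomly
# chosen existing anchors, restricted to `allowed`.
placeAdjacent <- function(nPairs, allowed, dist, anchors, placed) {
  if (nPairs == 0L || nrow(anchors) == 0L) {
    return(placed[0, , drop = FALSE])
  }
  H <- nrow(allowed); W <- ncol(allowed)
  out <- placed[0, , drop = FALSE]
  sel <- sample.int(nrow(anchors), min(nPairs, nrow(anchors)))
  for (i in sel) {
    for (try in 1:60) {
      th <- runif(1, 0, 2 * pi)
      x <- round(anchors$x[i] + dist * cos(th))
      y <- round(anchors$y[i] + dist * sin(th))
      if (x < 0 || y < 0 || x >= W || y >= H) next
      if (!allowed[y + 1L, x + 1L]) next
      others <- rbind(placed[, c("x", "y")], out)
      others <- others[!(others$x == anchors$x[i] & others$y == anchors$y[i]), ,
                       drop = FALSE]
      if (nrow(others) == 0L ||
          all((others$x - x)^2 + (others$y - y)^2 >= (0.8 * dist)^2)) {
        out <- rbind(out, data.frame(x = x, y = y))
        break
      }
    }
  }
  out
}

# Add an anti-aliased elliptical contribution to stain concentration maps.
# `mode`: "nucleus" (hematoxylin core), "membrane" (2 px DAB ring just
# outside the nucleus), "cytoplasm" (diffuse DAB halo).
paintCell <- function(hConc, dConc, x, y, a, b, theta, mode, density = 0.85) {
  H <- nrow(hConc); W <- ncol(hConc)
  ext <- ceiling(max(a, b)) + 4L
  rows <- max(1L, y + 1L - ext):min(H, y + 1L + ext)
  cols <- max(1L, x + 1L - ext):min(W, x + 1L + ext)
  dy <- rows - (y + 1L); dx <- cols - (x + 1L)
  u <- outer(dy * sin(theta), dx * cos(theta), "+")
  v <- outer(dy * cos(theta), -dx * sin(theta), "+")
  rho <- sqrt((u / a)^2 + (v / b)^2)
  rEff <- (a + b) / 2
  if (mode == "nucleus") {
    cov <- pmin(1, pmax(0, (1 - rho) * rEff + 0.5))
    hConc[rows, cols] <- hConc[rows, cols] + density * cov
  } else if (mode == "membrane") {
    radial <- (rho - 1) * rEff  # approx px outside the nuclear boundary
    cov <- pmin(1, pmax(0, 1.5 - abs(radial - 1)))
    dConc[rows, cols] <- dConc[rows, cols] + 0.95 * cov
  } else { # cytoplasm
    cov <- pmin(1, pmax(0, (1.8 - rho) * rEff / 2))
    dConc[rows, cols] <- dConc[rows, cols] + 0.55 * cov
  }
  list(h = hConc, d = dConc)
}

# Per-class nuclear geometry and chromatin density: lymphocytes are small,
# round and hyperchromatic (dark); histocyte nuclei are large, irregular
# and pale/vesicular; fibrocyte nuclei elongated; tumor nuclei in between.
cellGeometry <- function(cls) {
  switch(cls,
    TC_POS = , TC_NEG = {
      r <- runif(1, 5, 9); ar <- runif(1, 0.85, 1.15)
      c(a = r * ar, b = r / ar, theta = runif(1, 0, pi), density = 0.85)
    },
    LYMPHOCYTE = {
      r <- runif(1, 3, 4.5)
      c(a = r, b = r, theta = 0, density = 1.3)
    },
    HISTOCYTE = {
      r <- runif(1, 9, 12); ar <- sqrt(runif(1, 1.1, 1.6))
      c(a = r * ar, b = r / ar, theta = runif(1, 0, pi), density = 0.55)
    },
    FIBROCYTE = c(a = runif(1, 8, 12), b = runif(1, 2, 3.5),
                  theta = runif(1, 0, pi), density = 0.95)
  )
}

#' Simulate one synthetic IHC tile
#'
#' Generates the region mask (tumor nests split into TC(+)/TC(-) territory,
#' stroma, occasional acellular background), places cells by rejection
#' sampling with a minimum separation (plus a fraction of deliberately
#' adjacent pairs), renders them in optical-density space with reference
#' hematoxylin/DAB stain vectors and Gaussian noise, and returns the tile
#' with exact ground-truth annotations and score.
#'
#' The generated class counts are exact: `round(nTumorCells *
#' plannedTPS/100)` TC(+), the rest TC(-); intratumoral immune cells are
#' PD-L1 positive in the exact planned proportion. Requesting more cells
#' than the admissible area can hold raises an error (never silent
#' truncation).
#'
#' @param spec a [SynthSpec-class].
#' @return a [SynthTile-class].
#' @examples
#' tile <- simulateTile(synthSpec(tileWidth = 128, tileHeight = 128,
#'                                nTumorCells = 20, nImmuneCells = 8,
#'                                nFibrocytes = 4, plannedTPS = 40,
#'                                seed = 7))
#' truthScore(tile)
#' @export
simulateTile <- function(spec) {
  validObject(spec)
  W <- spec@tileWidth; H <- spec@tileHeight
  if (W %% 4L != 0L || H %% 4L != 0L)
    stop("tile dimensions must be divisible by the region scale factor (4)")
  withSeed(spec@seed, {
    nPos <- as.integer(round(spec@nTumorCells * spec@plannedTPS / 100))
    nNeg <- spec@nTumorCells - nPos

    lab <- makeRegionLabels(H %/% 4L, W %/% 4L, spec@tumorAreaFraction)
    labCell <- upsampleLabels(lab, 4L)

    inTumor <- labCell == REGION_LABELS[["TC_NEG_REGION"]]
    inStroma <- labCell == REGION_LABELS[["NORMAL_REGION"]]

    if (spec@nTumorCells > 0L && !any(inTumor))
      stop("impossible packing: tumor cells requested but tumorAreaFraction is 0")

    sep <- spec@minSeparation
    adjDist <- 0.8 * 14  # 0.8 x nuclear diameter (mean radius 7 px)
    nAdjPairs <- min(spec@nTumorCells %/% 2L,
                     floor(spec@adjacentFraction * spec@nTumorCells / 2))

    placed <- data.frame(x = integer(0), y = integer(0))
    ann <- data.frame(x = integer(0), y = integer(0), cls = character(0),
                      positive = logical(0), intratumoral = logical(0))

    # all tumor cells in the tumor mask, adjacency pairs included; the
    # nPos cells nearest a randomly chosen focus become TC(+) -- a
    # contiguous positive territory with an exact count
    if (spec@nTumorCells > 0L) {
      base <- placeCenters(spec@nTumorCells - nAdjPairs, inTumor, sep, placed)
      adj <- placeAdjacent(nAdjPairs, inTumor, adjDist, base, base)
      pts <- rbind(base, adj)
      if (nrow(pts) < spec@nTumorCells)
        stop("impossible packing: could not place adjacent tumor-cell pairs")
      isPos <- rep(FALSE, nrow(pts))
      if (nPos > 0L) {
        focus <- sample.int(nrow(pts), 1L)
        d2 <- (pts$x - pts$x[focus])^2 + (pts$y - pts$y[focus])^2
        isPos[order(d2)[seq_len(nPos)]] <- TRUE
      }
      placed <- rbind(placed, pts[, c("x", "y")])
      ann <- rbind(ann, data.frame(
        x = pts$x, y = pts$y, cls = ifelse(isPos, "TC_POS", "TC_NEG"),
        positive = isPos, intratumoral = FALSE))
      # split the tumor territory by the class of the nearest tumor cell
      tumorPix <- which(matrix(lab == REGION_LABELS[["TC_NEG_REGION"]],
                               nrow(lab), ncol(lab)), arr.ind = TRUE)
      if (nrow(tumorPix) && nPos > 0L) {
        pcx <- (tumorPix[, 2] - 0.5) * 4; pcy <- (tumorPix[, 1] - 0.5) * 4
        nearestPos <- vapply(seq_len(nrow(tumorPix)), function(i) {
          d2c <- (pts$x - pcx[i])^2 + (pts$y - pcy[i])^2
          isPos[which.min(d2c)]
        }, logical(1))
        lab[tumorPix[nearestPos, , drop = FALSE]] <-
          REGION_LABELS[["TC_POS_REGION"]]
      }
    }
    mask <- new("RegionMask", labels = lab, scaleFactor = 4)

    # immune cells: intratumoral (counted as ICs) vs stromal
    nICin <- as.integer(round(spec@nImmuneCells * spec@icTumorFraction))
    nICout <- spec@nImmuneCells - nICin
    nICinPos <- as.integer(round(nICin * spec@plannedIPS / 100))
    addIC <- function(n, allowed, posFlags) {
      if (n == 0L) return(data.frame())
      before <- nrow(placed)
      pts <- placeCenters(n, allowed, sep, placed)
      pts <- pts[seq.int(before + 1L, nrow(pts)), , drop = FALSE]
      placed <<- rbind(placed, pts)
      lymph <- runif(n) < 0.7
      data.frame(x = pts$x, y = pts$y,
                 cls = ifelse(lymph, "LYMPHOCYTE", "HISTOCYTE"),
                 positive = posFlags, stringsAsFactors = FALSE)
    }
    if (nICin > 0L && !any(inTumor))
      stop("impossible packing: intratumoral immune cells need tumor area")
    icIn <- addIC(nICin, inTumor,
                  sample(rep(c(TRUE, FALSE), c(nICinPos, nICin - nICinPos))))
    icOutAllowed <- if (any(inStroma)) inStroma else !inTumor
    icOut <- addIC(nICout, icOutAllowed, logical(nICout))
    if (nrow(icOut)) {
      hist <- icOut$cls == "HISTOCYTE"
      icOut$positive[hist] <- runif(sum(hist)) < spec@stromalHistPosProb
    }
    if (nrow(icIn))
      ann <- rbind(ann, data.frame(x = icIn$x, y = icIn$y, cls = icIn$cls,
                                   positive = icIn$positive,
                                   intratumoral = TRUE))
    if (nrow(icOut))
      ann <- rbind(ann, data.frame(x = icOut$x, y = icOut$y, cls = icOut$cls,
                                   positive = icOut$positive,
                                   intratumoral = FALSE))

    if (spec@nFibrocytes > 0L) {
      fibAllowed <- if (any(inStroma)) inStroma else !inTumor
      before <- nrow(placed)
      pts <- placeCenters(spec@nFibrocytes, fibAllowed, sep, placed)
      pts <- pts[seq.int(before + 1L, nrow(pts)), , drop = FALSE]
      placed <- rbind(placed, pts)
      ann <- rbind(ann, data.frame(x = pts$x, y = pts$y, cls = "FIBROCYTE",
                                   positive = FALSE, intratumoral = FALSE))
    }

    # render in optical-density space; tumor nests carry a subtle extra
    # hematoxylin tint (confluent tumor cytoplasm), visibly denser than
    # stroma at low magnification as in real H-DAB sections
    labCellFinal <- upsampleLabels(lab, 4L)
    hConc <- matrix(0.06, H, W)
    hConc[labCellFinal %in% REGION_LABELS[c("TC_POS_REGION",
                                            "TC_NEG_REGION")]] <- 0.18
    hConc[labCellFinal == REGION_LABELS[["BACKGROUND"]]] <- 0.004
    dConc <- matrix(0, H, W)
    if (nrow(ann)) {
      for (i in seq_len(nrow(ann))) {
        g <- cellGeometry(ann$cls[i])
        res <- paintCell(hConc, dConc, ann$x[i], ann$y[i],
                         g[["a"]], g[["b"]], g[["theta"]], "nucleus",
                         density = g[["density"]])
        hConc <- res$h; dConc <- res$d
        if (ann$cls[i] == "TC_POS") {
          res <- paintCell(hConc, dConc, ann$x[i], ann$y[i],
                           g[["a"]], g[["b"]], g[["theta"]], "membrane")
          hConc <- res$h; dConc <- res$d
        } else if (ann$positive[i]) {
          res <- paintCell(hConc, dConc, ann$x[i], ann$y[i],
                           g[["a"]], g[["b"]], g[["theta"]], "cytoplasm")
          hConc <- res$h; dConc <- res$d
        }
      }
    }
    hConc <- pmin(hConc, 1.3); dConc <- pmin(dConc, 1.3)
    sm <- stainMatrix()
    od <- array(0, c(H, W, 3))
    for (ch in 1:3)
      od[, , ch] <- hConc * sm[1, ch] + dConc * sm[2, ch]
    if (spec@stainNoiseSD > 0)
      od <- od + array(rnorm(length(od), sd = spec@stainNoiseSD), dim(od))
    img <- 10^(-pmax(od, 0))
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255  # 8-bit quantization

    nIC <- sum(ann$intratumoral)
    nICPos <- sum(ann$intratumoral & ann$positive)
    truth <- newSlideScore(nPos, nNeg, nIC, nICPos)
    new("SynthTile", image = img,
        annotations = ann[, c("x", "y", "cls", "positive", "intratumoral")],
        regionMask = mask, truth = truth, spec = spec)
  })
}

# Nearest-neighbour upsampling of a label matrix by an integer factor.
upsampleLabels <- function(lab, factor) {
  lab[rep(seq_len(nrow(lab)), each = factor),
      rep(seq_len(ncol(lab)), each = factor)]
}

#' Simulate a multi-tile synthetic slide
#'
#' Runs [simulateTile()] for each spec and aggregates the ground truth at
#' slide level by summing counts ([aggregateSlide()]); the slide TPS is the
#' ratio of summed counts, not the mean of per-tile TPS values.
#'
#' @param specList non-empty list of [SynthSpec-class] objects.
#' @return list with `tiles` (list of [SynthTile-class]) and `score`
#'   (slide-level [SlideScore-class]).
#' @export
simulateSlide <- function(specList) {
  stopifnot(length(specList) >= 1L)
  tiles <- lapply(specList, simulateTile)
  list(tiles = tiles, score = aggregateSlide(lapply(tiles, truthScore)))
}

#' Materialize a standard synthetic fixture set on disk
#'
#' Writes, for each seed, one tile as PNG plus annotations (CSV and JSON),
#' region mask (single-channel PNG) and ground-truth score (JSON).
#'
#' @param dir output directory (created if needed).
#' @param specs list of [SynthSpec-class]; default builds three small tiles.
#' @return invisibly, the vector of tile prefixes written.
#' @export
writeFixtures <- function(dir, specs = NULL) {
  if (is.null(specs))
    specs <- lapply(1:3, function(s)
      synthSpec(tileWidth = 128, tileHeight = 128, nTumorCells = 20,
                nImmuneCells = 10, nFibrocytes = 5, plannedTPS = 25,
                seed = s))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefixes <- character(0)
  for (i in seq_along(specs)) {
    tile <- simulateTile(specs[[i]])
    pre <- file.path(dir, sprintf("tile%03d", i))
    writeImagePNG(tile@image, paste0(pre, ".png"))
    writeAnnotations(annotations(tile), paste0(pre, "_cells.csv"))
    writeAnnotations(annotations(tile), paste0(pre, "_cells.json"))
    writeRegionMask(regionMask(tile), paste0(pre, "_regions.png"))
    s <- truthScore(tile)
    jsonlite::write_json(
      list(counts = as.list(cellCounts(s)), tps = s@tps, ips = s@ips,
           category = s@category, amenable = s@amenable),
      paste0(pre, "_truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
    prefixes <- c(prefixes, pre)
  }
  invisible(prefixes)
}
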