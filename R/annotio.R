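# Readers/writers and tiling. Coordinate convention used throughout the
# package: 0-based, x = pixel column, y = pixel row, pixel-center,
# half-open tile ranges.

#' Read and write RGB images
#'
#' PNG via the png package; TIFF via the tiff package when the file
#' extension is `.tif`/`.tiff`. Images are numeric arrays `(H, W, 3)` in
#' `[0, 1]`; writing quantizes to 8-bit.
#'
#' @param path file path; format chosen by extension.
#' @param image numeric array `(H, W, 3)` in `[0, 1]`.
#' @return `readImagePNG` returns the image array.
#' @export
readImagePNG <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    requireNamespace("tiff")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname readImagePNG
#' @export
writeImagePNG <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    requireNamespace("tiff")
    tiff::writeTIFF(image, path, bits.per.sample = 8L)
  } else {
    png::writePNG(image, path)
  }
  invisible(path)
}

#' Read point annotations
#'
#' CSV schema: header `x,y,class`, one row per cell, 0-based pixel
#' coordinates; JSON: an array of `{x, y, class}` objects. An unknown class
#' string raises an error naming the offending row.
#'
#' @param path `.csv` or `.json` file.
#' @return `data.frame` with columns `x`, `y` (integer) and `cls`.
#' @export
readAnnotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- if (length(raw) == 0L)
      data.frame(x = integer(0), y = integer(0), class = character(0))
    else as.data.frame(raw)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L)
    return(data.frame(x = integer(0), y = integer(0), cls = character(0)))
  names(df)[names(df) == "class"] <- "cls"
  bad <- which(!df$cls %in% CELL_CLASSES)
  if (length(bad))
    stop(sprintf("unknown cell class '%s' at row %d of %s",
                 df$cls[bad[1]], bad[1], path))
  data.frame(x = as.integer(df$x), y = as.integer(df$y), cls = df$cls)
}

#' @rdname readAnnotations
#' @param annotations `data.frame` with columns `x`, `y`, `cls`.
#' @export
writeAnnotations <- function(annotations, path) {
  out <- data.frame(x = annotations$x, y = annotations$y,
                    class = annotations$cls)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  } else {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write region label masks
#'
#' Stored as single-channel 8-bit PNG label images whose pixel values are
#' the raw label codes (0 background, 1 TC(+) region, 2 TC(-) region,
#' 3 normal region).
#'
#' @param path PNG file path.
#' @param scaleFactor linear cell-scale / region-scale ratio of the mask.
#' @return `readRegionMask` returns a [RegionMask-class].
#' @export
readRegionMask <- function(path, scaleFactor = 4) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  new("RegionMask", labels = lab, scaleFactor = scaleFactor)
}

#' @rdname readRegionMask
#' @param mask a [RegionMask-class].
#' @export
writeRegionMask <- function(mask, path) {
  png::writePNG(maskLabels(mask) / 255, path)
  invisible(path)
}

#' Read a two-rater TPS score table
#'
#' CSV schema: `case_id, rater_a, rater_b[, subtype]`. Scores must lie in
#' `[0, 100]` with no missing values in retained rows; `subtype`, when
#' present, is one of SCC, AD, ADSQ.
#'
#' @param path CSV file.
#' @return `data.frame` with columns `case_id`, `rater_a`, `rater_b` and
#'   optionally `subtype`.
#' @export
readScoreTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "rater_a", "rater_b")
  if (!all(need %in% names(df)))
    stop("score table must have columns case_id, rater_a, rater_b")
  for (col in c("rater_a", "rater_b")) {
    v <- df[[col]]
    if (any(is.na(v))) stop(sprintf("missing %s values in %s", col, path))
    if (any(v < 0 | v > 100))
      stop(sprintf("%s scores outside [0, 100] in %s", col, path))
  }
  if ("subtype" %in% names(df) &&
      !all(is.na(df$subtype) | df$subtype %in% c("SCC", "AD", "ADSQ")))
    stop("subtype must be SCC, AD or ADSQ")
  df
}

# Mirror-periodic index extension: 1..n, n..1, 1..n, ... beyond n.
mirrorIndex <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  m <- (k - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Reflect-pad an image array (H, W, C) on the bottom/right; pads larger
# than the source extent continue the mirror periodically.
reflectPad <- function(image, padBottom, padRight) {
  d <- dim(image)
  if (padBottom > 0) {
    idx <- mirrorIndex(seq.int(d[1] + 1L, d[1] + padBottom), d[1])
    image <- array(image[c(seq_len(d[1]), idx), , , drop = FALSE],
                   c(d[1] + padBottom, d[2], d[3]))
  }
  d <- dim(image)
  if (padRight > 0) {
    idx <- mirrorIndex(seq.int(d[2] + 1L, d[2] + padRight), d[2])
    image <- array(image[, c(seq_len(d[2]), idx), , drop = FALSE],
                   c(d[1], d[2] + padRight, d[3]))
  }
  image
}

#' Split an image into (optionally overlapping) tiles
#'
#' Tiles are laid on a regular grid with stride `tileSize - overlap`; the
#' grid uses as many tiles per axis as needed to cover the image
#' (ceiling division). Edge tiles are padded to full size by reflection
#' and the pad extent recorded. Offsets are top-left corners in parent
#' coordinates (0-based, half-open ranges).
#'
#' @param image numeric array `(H, W, C)`.
#' @param tileSize tile side length in pixels.
#' @param overlap overlap between neighbouring tiles, `0 <= overlap <
#'   tileSize`.
#' @return list of lists with elements `tile` (array), `offset`
#'   (`c(x, y)`), `pad` (`c(x, y)` reflection-pad extents).
#' @export
tileImage <- function(image, tileSize, overlap = 0L) {
  stopifnot(tileSize > overlap, overlap >= 0L)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (tileSize >= H && tileSize >= W)
    warning("tileSize covers the whole image; returning a single padded tile")
  stride <- tileSize - overlap
  starts <- function(D) {
    if (D <= tileSize) return(0L)
    as.integer(stride) * (0:ceiling((D - tileSize) / stride))
  }
  out <- list()
  for (oy in starts(H)) {
    for (ox in starts(W)) {
      ys <- (oy + 1L):min(H, oy + tileSize)
      xs <- (ox + 1L):min(W, ox + tileSize)
      sub <- image[ys, xs, , drop = FALSE]
      pad <- c(x = tileSize - length(xs), y = tileSize - length(ys))
      if (any(pad > 0)) sub <- reflectPad(sub, pad[["y"]], pad[["x"]])
      out[[length(out) + 1L]] <-
        list(tile = sub, offset = c(x = ox, y = oy), pad = pad)
    }
  }
  out
}

#' Map tile detections back to parent-image coordinates
#'
#' Drops detections that fall into the reflection-padded margin of an edge
#' tile, then translates coordinates by the tile offset.
#'
#' @param detections `data.frame` (`x`, `y`, `cls`, optionally `score`) in
#'   tile coordinates.
#' @param offset `c(x, y)` top-left corner of the tile in the parent.
#' @param pad `c(x, y)` pad extents recorded by [tileImage()].
#' @param tileSize tile side length.
#' @return detections in parent coordinates.
#' @export
detectionsToParent <- function(detections, offset, pad = c(x = 0L, y = 0L),
                               tileSize = NULL) {
  if (nrow(detections) == 0L) return(detections)
  if (!is.null(tileSize) && any(pad > 0)) {
    keep <- detections$x < tileSize - pad[["x"]] &
      detections$y < tileSize - pad[["y"]]
    detections <- detections[keep, , drop = FALSE]
  }
  detections$x <- detections$x + offset[["x"]]
  detections$y <- detections$y + offset[["y"]]
  detections
}

#' Merge detections from overlapping tiles
#'
#' Applies [detectionsToParent()] per tile and removes duplicates arising
#' in overlap zones: among same-class detections within `radius` of each
#' other, the copy whose distance to its own tile center is smaller wins.
#'
#' @param detectionList list of per-tile detection `data.frame`s.
#' @param tiles the tile list returned by [tileImage()].
#' @param tileSize tile side length used for tiling.
#' @param radius de-duplication radius in pixels (default: the peak
#'   minimum distance used at detection time).
#' @return merged detections in parent coordinates.
#' @export
stitchDetections <- function(detectionList, tiles, tileSize, radius = 9) {
  stopifnot(length(detectionList) == length(tiles))
  all <- list()
  for (i in seq_along(tiles)) {
    det <- detectionList[[i]]
    if (nrow(det) == 0L) next
    det$.cdist <- sqrt((det$x - tileSize / 2)^2 + (det$y - tileSize / 2)^2)
    det <- detectionsToParent(det, tiles[[i]]$offset, tiles[[i]]$pad, tileSize)
    if (nrow(det) == 0L) next
    all[[length(all) + 1L]] <- det
  }
  if (length(all) == 0L)
    return(data.frame(x = integer(0), y = integer(0), cls = character(0),
                      score = numeric(0)))
  det <- do.call(rbind, all)
  det <- det[order(det$.cdist), , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      j <- (i + 1L):nrow(det)
      close <- keep[j] & det$cls[j] == det$cls[i] &
        (det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2 < radius^2
      keep[j[close]] <- FALSE
    }
  }
  det <- det[keep, , drop = FALSE]
  det$.cdist <- NULL
  rownames(det) <- NULL
  det
}

#' Stratified 60/20/20 dataset split
#'
#' Splits tile indices into training, validation and test sets (default
#' 60/20/20), stratified by a grouping factor (typically the planned TPS
#' bin), deterministically for a fixed seed.
#'
#' @param strata vector (one entry per tile) defining the strata.
#' @param fractions numeric length-3 summing to 1.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(strata, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  withSeed(seed, {
    train <- integer(0); val <- integer(0); test <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      nTrain <- round(fractions[1] * n)
      nVal <- round(fractions[2] * n)
      train <- c(train, idx[seq_len(nTrain)])
      val <- c(val, idx[seq_len(nVal) + nTrain])
      if (nTrain + nVal < n)
        test <- c(test, idx[(nTrain + nVal + 1L):n])
    }
    list(train = sort(train), validation = sort(val), test = sort(test))
  })
}
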