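# Peak extraction: probability maps -> point detections via per-channel
# local maxima and greedy non-maximum suppression.

localMaxima <- function(plane) {
  H <- nrow(plane); W <- ncol(plane)
  p <- matrix(-Inf, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- plane
  ok <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & plane >= p[2:(H + 1) + dy, 2:(W + 1) + dx]
  }
  ok
}

# Label 8-connected components of a logical mask; returns an integer
# matrix (0 = background). Used to collapse local-maximum plateaus (e.g.
# binary target disks) into a single candidate peak.
labelComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextLab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      cy <- (cur - 1L) %% H + 1L
      cx <- (cur - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- cy + dy; nx <- cx + dx
        if (ny < 1L || ny > H || nx < 1L || nx > W) next
        ni <- ny + (nx - 1L) * H
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- nextLab
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# One representative candidate per plateau component: among its
# maximum-score pixels, the one closest to the component centroid
# (ties row-major).
plateauPeaks <- function(plane, mask) {
  lab <- labelComponents(mask)
  out <- NULL
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k, arr.ind = TRUE)
    sc <- plane[pix]
    top <- pix[sc >= max(sc) - 1e-12, , drop = FALSE]
    cyx <- colMeans(pix)
    d2 <- (top[, 1] - cyx[1])^2 + (top[, 2] - cyx[2])^2
    ord <- order(d2, top[, 1], top[, 2])
    best <- top[ord[1], ]
    out <- rbind(out, data.frame(x = best[[2]] - 1L, y = best[[1]] - 1L,
                                 score = max(sc)))
  }
  out
}

# Greedy NMS on a candidate data.frame ordered by (score desc, y, x):
# a candidate is kept when no already-kept candidate lies within minDist.
greedyNMS <- function(df, minDist) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(-df$score, df$y, df$x), , drop = FALSE]
  keep <- logical(nrow(df))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (length(kx) == 0L ||
        all((kx - df$x[i])^2 + (ky - df$y[i])^2 >= minDist^2)) {
      keep[i] <- TRUE
      kx <- c(kx, df$x[i]); ky <- c(ky, df$y[i])
    }
  }
  df[keep, , drop = FALSE]
}

#' Extract point detections from probability maps
#'
#' Per channel, local maxima (8-neighbourhood, ties included) with score at
#' least `threshold` are suppressed greedily so retained peaks are at least
#' `minDistance` apart -- the higher peak wins, ties broken in row-major
#' order. Across channels, when detections of different classes fall within
#' `minDistance` of each other only the highest-scoring one is kept.
#'
#' @param prob numeric array `(H, W, C)` in `[0, 1]` with channel names
#'   (e.g. from [predictProbabilityMaps()]).
#' @param threshold minimal peak score (default 0.5).
#' @param minDistance minimal peak separation in pixels (default 9, the
#'   target disk radius).
#' @return `data.frame` with columns `x`, `y` (0-based), `cls`, `score`.
#' @export
extractDetections <- function(prob, threshold = 0.5, minDistance = 9) {
  classes <- dimnames(prob)[[3]]
  if (is.null(classes)) classes <- CELL_CLASSES[seq_len(dim(prob)[3])]
  perClass <- list()
  for (ch in seq_len(dim(prob)[3])) {
    plane <- prob[, , ch]
    mask <- localMaxima(plane) & plane >= threshold
    if (!any(mask)) next
    df <- plateauPeaks(plane, mask)
    df$cls <- classes[ch]
    perClass[[length(perClass) + 1L]] <- greedyNMS(df, minDistance)
  }
  empty <- data.frame(x = integer(0), y = integer(0), cls = character(0),
                      score = numeric(0))
  if (length(perClass) == 0L) return(empty)
  merged <- greedyNMS(do.call(rbind, perClass), minDistance)
  merged <- merged[, c("x", "y", "cls", "score")]
  rownames(merged) <- NULL
  merged
}
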