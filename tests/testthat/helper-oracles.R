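# Independent oracles: deliberately naive scalar-loop / enumeration
# implementations used only to check the package's vectorized versions.

# Weighted pixel-wise cross-entropy by an explicit per-element loop.
oracleWeightedCE <- function(pred, target, lambda, gamma) {
  eps <- 1e-7
  total <- 0
  n <- 0L
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    t <- target[i]
    phi <- lambda * abs(p - t)^gamma
    total <- total + phi * (t * log(p) + (1 - t) * log(1 - p))
    n <- n + 1L
  }
  -total / n
}

# Optimal matching by exhaustive enumeration over all one-to-one
# assignments (feasible for <= 8 points per side): maximum cardinality,
# then minimum total distance.
oracleMatch <- function(px, py, tx, ty, radius) {
  nP <- length(px); nT <- length(tx)
  if (nP == 0L || nT == 0L) return(list(tp = 0L, dist = 0))
  d <- outer(seq_len(nP), seq_len(nT), function(i, j)
    sqrt((px[i] - tx[j])^2 + (py[i] - ty[j])^2))
  best <- list(tp = 0L, dist = Inf)
  assignRec <- function(i, used, tp, dist) {
    if (i > nP) {
      if (tp > best$tp || (tp == best$tp && dist < best$dist))
        best <<- list(tp = tp, dist = dist)
      return(invisible())
    }
    assignRec(i + 1L, used, tp, dist)  # prediction i unmatched
    for (j in seq_len(nT)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        assignRec(i + 1L, used, tp + 1L, dist + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  assignRec(1L, logical(nT), 0L, 0)
  if (is.infinite(best$dist)) best$dist <- 0
  best
}

# ICC(2,1) from aov() mean squares (two-way layout, subjects random).
oracleICC21 <- function(a, b) {
  n <- length(a)
  df <- data.frame(score = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]]$`Mean Sq`
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Fleiss' kappa from the explicit n x 2 category-count table.
oracleFleiss <- function(posA, posB) {
  n <- length(posA)
  k <- 2
  tab <- cbind(pos = as.integer(posA) + as.integer(posB))
  tab <- cbind(tab, neg = k - tab[, "pos"])
  Pi <- (rowSums(tab^2) - k) / (k * (k - 1))
  pj <- colSums(tab) / (n * k)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-12) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

# Spearman as Pearson on average ranks.
oracleSpearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Pearson chi-square on a 2x2 table by sum((O - E)^2 / E).
oracleChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Small helper: deterministic random detection/annotation frames.
randomPoints <- function(n, cls, size = 100) {
  if (n == 0L)
    return(data.frame(x = integer(0), y = integer(0), cls = character(0)))
  data.frame(x = sample.int(size, n, replace = TRUE) - 1L,
             y = sample.int(size, n, replace = TRUE) - 1L,
             cls = cls)
}
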