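# Evaluation battery: object-level detection metrics, count-error metrics,
# reliability statistics (ICC(2,1), Fleiss' kappa at clinical cutoffs),
# correlations and association tests.

# Maximum-cardinality, minimum-total-distance one-to-one matching between
# two point sets, restricted to pairs within `radius`. Realized as a
# maximum-weight bipartite matching with weight M - distance and M large
# enough that every additional match dominates any distance saving.
matchPoints <- function(px, py, tx, ty, radius) {
  nP <- length(px); nT <- length(tx)
  if (nP == 0L || nT == 0L) return(integer(0))
  edges <- integer(0); w <- numeric(0)
  M <- (nP + nT + 1) * radius + 1
  for (i in seq_len(nP)) {
    d <- sqrt((tx - px[i])^2 + (ty - py[i])^2)
    j <- which(d <= radius)
    if (length(j)) {
      edges <- c(edges, rbind(i, nP + j))
      w <- c(w, M - d[j])
    }
  }
  if (length(edges) == 0L) return(integer(0))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nP), rep(TRUE, nT)),
                                    edges, directed = FALSE)
  igraph::E(g)$weight <- w
  m <- igraph::max_bipartite_match(g)$matching
  match <- m[seq_len(nP)]
  match[!is.na(match)] <- match[!is.na(match)] - nP
  match
}

#' Object-level detection metrics
#'
#' Matches predictions to ground-truth points per class by an optimal
#' one-to-one assignment (maximum cardinality; among maximum matchings,
#' minimum total distance) restricted to pairs within `matchRadius`.
#' Matched predictions are true positives, unmatched predictions false
#' positives, unmatched truths false negatives.
#'
#' @param pred detection `data.frame` (`x`, `y`, `cls`).
#' @param truth annotation `data.frame` (`x`, `y`, `cls`).
#' @param matchRadius maximal matching distance in pixels (default 9, the
#'   target disk radius).
#' @param classes classes to evaluate (default: all present).
#' @return list with `perClass` (`data.frame`: class, tp, fp, fn,
#'   precision, recall, f1) and `macro` (averaged precision/recall/f1 over
#'   evaluated classes).
#' @export
objectF1 <- function(pred, truth, matchRadius = 9, classes = NULL) {
  stopifnot(matchRadius > 0)
  if (is.null(classes))
    classes <- intersect(CELL_CLASSES, unique(c(pred$cls, truth$cls)))
  rows <- lapply(classes, function(cl) {
    p <- pred[pred$cls == cl, , drop = FALSE]
    t <- truth[truth$cls == cl, , drop = FALSE]
    m <- matchPoints(p$x, p$y, t$x, t$y, matchRadius)
    tp <- sum(!is.na(m))
    fp <- nrow(p) - tp
    fn <- nrow(t) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(cls = cl, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1)
  })
  perClass <- do.call(rbind, rows)
  list(perClass = perClass,
       macro = c(precision = mean(perClass$precision),
                 recall = mean(perClass$recall),
                 f1 = mean(perClass$f1)))
}

#' Count-error metrics over paired patch counts
#'
#' MAE = mean absolute error, RMSE = root mean squared error, MAPE = mean
#' absolute percent error computed over patches with nonzero truth (zero
#' truth patches are excluded from MAPE only; MAPE is flagged undefined
#' when no patch has positive truth).
#'
#' @param pred,truth equal-length numeric vectors of per-patch counts.
#' @return list `mae`, `rmse`, `mape` (`NA` when undefined), `mapeDefined`.
#' @export
countErrors <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  d <- pred - truth
  pos <- truth > 0
  list(mae = mean(abs(d)),
       rmse = sqrt(mean(d^2)),
       mape = if (any(pos)) 100 * mean(abs(d[pos]) / truth[pos]) else NA_real_,
       mapeDefined = any(pos))
}

#' Intraclass correlation ICC(2,1) with 95 percent confidence interval
#'
#' Two-way random effects, absolute agreement, single measure, computed
#' from the mean squares of the two-way (subject x rater) layout; the
#' confidence interval follows the standard F-based construction with
#' Satterthwaite degrees of freedom.
#'
#' @param a,b paired score vectors, `n >= 5`.
#' @param conf confidence level (default 0.95).
#' @return list `icc`, `ci` (length 2), `n`, `defined` (`FALSE` when both
#'   raters have zero variance).
#' @export
iccTwoWay <- function(a, b, conf = 0.95) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 5)
  X <- cbind(a, b)
  k <- 2L
  grand <- mean(X)
  rm <- rowMeans(X); cm <- colMeans(X)
  MSR <- k * sum((rm - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  SSE <- sum((X - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (den <= 0 || (MSR == 0 && MSC == 0 && MSE == 0))
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                defined = FALSE))
  icc <- (MSR - MSE) / den
  if (abs(icc - 1) < 1e-12)
    return(list(icc = icc, ci = c(1, 1), n = n, defined = TRUE))
  alpha <- 1 - conf
  aQ <- k * icc / (n * (1 - icc))
  bQ <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (aQ * MSC + bQ * MSE)^2 /
    ((aQ * MSC)^2 / (k - 1) + (bQ * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci = c(lower, upper), n = n, defined = TRUE)
}

# Fleiss' kappa for 2 raters x n subjects x 2 categories, from the
# category-count table n_ij in {0, 1, 2}.
fleissKappa2 <- function(posA, posB) {
  n <- length(posA)
  nPos <- posA + posB           # per-subject positive count in {0, 1, 2}
  nNeg <- 2L - nPos
  k <- 2
  Pi <- (nPos^2 + nNeg^2 - k) / (k * (k - 1))
  pPos <- sum(nPos) / (n * k)
  pNeg <- 1 - pPos
  Pbar <- mean(Pi)
  Pe <- pPos^2 + pNeg^2
  if (1 - Pe < 1e-12) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

#' Fleiss' kappa after dichotomization at clinical cutoffs
#'
#' Each rater's score is dichotomized as `score >= cutoff` (a score exactly
#' at the cutoff counts positive, consistent with the closed lower bounds
#' of the expression categories); Fleiss' kappa is then computed for the
#' two raters over the two categories. When both raters place all subjects
#' in one category the kappa is undefined (`NA`).
#'
#' @param a,b paired score vectors in `[0, 100]`.
#' @param cutoffs percent cutoffs (default 1, 5, 10, 25, 50).
#' @return named numeric vector of kappas.
#' @export
kappaAtCutoffs <- function(a, b, cutoffs = c(1, 5, 10, 25, 50)) {
  stopifnot(all(a >= 0 & a <= 100), all(b >= 0 & b <= 100))
  vapply(cutoffs, function(ct) fleissKappa2(a >= ct, b >= ct),
         numeric(1)) |> stats::setNames(as.character(cutoffs))
}

#' Pearson and Spearman correlation
#'
#' Standard definitions; Spearman uses average ranks for ties. Zero
#' variance in either vector yields `NA` with `defined = FALSE`.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list `pearson`, `spearman`, `n`, `defined`.
#' @export
correlations <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (var(x) == 0 || var(y) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n = n,
                defined = FALSE))
  list(pearson = cor(x, y), spearman = cor(x, y, method = "spearman"),
       n = n, defined = TRUE)
}

#' Association between TPS and IPS
#'
#' For each TPS cutoff, a Mann-Whitney U test (normal approximation with
#' tie correction, no continuity correction) compares IPS between the
#' TPS-high and TPS-low groups; a chi-square test (no continuity
#' correction) is run on the 2x2 table at the simultaneous cutoffs
#' (`tps >= 1`, `ips >= ipsCutoff`); Pearson and Spearman correlations are
#' reported alongside. Tests with an empty group are flagged undefined.
#'
#' @param tpsv,ipsv paired score vectors in percent.
#' @param tpsCutoffs TPS cutoffs for the U tests.
#' @param ipsCutoff IPS cutoff for the chi-square table (default 1).
#' @return list with `mannWhitney` (data.frame: cutoff, U, p, defined),
#'   `chisq` (list: statistic, p, defined), `correlation`.
#' @export
ipsTpsAssociation <- function(tpsv, ipsv, tpsCutoffs = c(1, 25, 50),
                              ipsCutoff = 1) {
  stopifnot(length(tpsv) == length(ipsv))
  mw <- do.call(rbind, lapply(tpsCutoffs, function(ct) {
    hi <- tpsv >= ct
    if (!any(hi) || all(hi))
      return(data.frame(cutoff = ct, U = NA_real_, p = NA_real_,
                        defined = FALSE))
    wt <- suppressWarnings(
      wilcox.test(ipsv[hi], ipsv[!hi], exact = FALSE, correct = FALSE))
    data.frame(cutoff = ct, U = unname(wt$statistic), p = wt$p.value,
               defined = TRUE)
  }))
  tpsPos <- factor(tpsv >= 1, levels = c(FALSE, TRUE))
  ipsPos <- factor(ipsv >= ipsCutoff, levels = c(FALSE, TRUE))
  tab <- table(tpsPos, ipsPos)
  chis <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    list(statistic = NA_real_, p = NA_real_, defined = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value, defined = TRUE)
  }
  list(mannWhitney = mw, chisq = chis,
       correlation = correlations(tpsv, ipsv))
}

#' Full concordance report for two TPS score vectors
#'
#' Bundles ICC(2,1) with its confidence interval, Pearson and Spearman
#' correlations and Fleiss' kappa at the clinical cutoffs into a
#' [ConcordanceReport-class].
#'
#' @inheritParams iccTwoWay
#' @param cutoffs kappa cutoffs in percent.
#' @return a [ConcordanceReport-class].
#' @export
concordanceReport <- function(a, b, cutoffs = c(1, 5, 10, 25, 50)) {
  ic <- iccTwoWay(a, b)
  cr <- correlations(a, b)
  new("ConcordanceReport", icc = ic$icc, iccCI = ic$ci,
      pearson = cr$pearson, spearman = cr$spearman,
      kappa = kappaAtCutoffs(a, b, cutoffs), n = length(a))
}
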