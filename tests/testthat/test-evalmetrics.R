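# Detection, count-error, reliability and association statistics against
# brute-force / closed-form oracles.

test_that("objectF1 handles the canonical hand cases", {
  a <- data.frame(x = c(3, 10), y = c(4, 12), cls = "TC_POS")
  res <- objectF1(a, a, matchRadius = 5)
  expect_equal(res$perClass$f1, 1)
  expect_equal(res$perClass$tp, 2)

  far <- objectF1(data.frame(x = 0, y = 0, cls = "TC_POS"),
                  data.frame(x = 100, y = 100, cls = "TC_POS"),
                  matchRadius = 10)
  expect_equal(far$perClass$f1, 0)

  r <- objectF1(data.frame(x = c(0, 3), y = c(0, 0), cls = "TC_POS"),
                data.frame(x = 0, y = 0, cls = "TC_POS"), matchRadius = 5)
  expect_equal(r$perClass$tp, 1)
  expect_equal(r$perClass$fp, 1)
  expect_equal(r$perClass$fn, 0)
  expect_equal(r$perClass$precision, 0.5)
  expect_equal(r$perClass$recall, 1)
  expect_equal(r$perClass$f1, 2 / 3)
})

test_that("objectF1 equals exhaustive optimal matching on random instances", {
  set.seed(7)
  for (trial in 1:100) {
    nP <- sample(0:8, 1)
    nT <- sample(0:8, 1)
    pred <- randomPoints(nP, "TC_POS", size = 30)
    truth <- randomPoints(nT, "TC_POS", size = 30)
    radius <- sample(c(3, 6, 12), 1)
    res <- objectF1(pred, truth, matchRadius = radius,
                    classes = "TC_POS")
    o <- oracleMatch(pred$x, pred$y, truth$x, truth$y, radius)
    expect_equal(res$perClass$tp, o$tp,
                 info = sprintf("trial %d", trial))
  }
})

test_that("objectF1 is translation invariant and swaps P/R under pred<->truth", {
  set.seed(8)
  pred <- randomPoints(6, "TC_NEG", 40)
  truth <- randomPoints(5, "TC_NEG", 40)
  r1 <- objectF1(pred, truth, 8)
  shifted <- function(df) transform(df, x = x + 17, y = y + 31)
  r2 <- objectF1(shifted(pred), shifted(truth), 8)
  expect_equal(r1$perClass$tp, r2$perClass$tp)
  r3 <- objectF1(truth, pred, 8)
  expect_equal(r1$perClass$precision, r3$perClass$recall)
  expect_equal(r1$perClass$recall, r3$perClass$precision)
  expect_equal(r1$perClass$f1, r3$perClass$f1)
})

test_that("count errors reproduce hand arithmetic and the zero-truth rule", {
  r <- countErrors(c(4, 6), c(5, 6))
  expect_equal(r$mae, 0.5)
  expect_equal(r$rmse, sqrt(0.5), tolerance = 1e-6)
  expect_equal(round(r$rmse, 5), 0.70711)
  expect_equal(r$mape, 10)

  z <- countErrors(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(z$mae, z$rmse, z$mape), c(0, 0, 0))

  withZero <- countErrors(c(2, 5), c(0, 4))
  expect_equal(withZero$mae, 1.5)          # zero-truth patch kept in MAE
  expect_equal(withZero$mape, 25)          # but excluded from MAPE
  expect_false(countErrors(c(1, 1), c(0, 0))$mapeDefined)
  expect_gte(countErrors(c(9, 1), c(2, 2))$rmse,
             countErrors(c(9, 1), c(2, 2))$mae)
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  set.seed(9)
  for (trial in 1:100) {
    n <- sample(5:12, 1)
    a <- round(runif(n, 0, 100), 1)
    b <- round(pmin(pmax(a + rnorm(n, 0, 15), 0), 100), 1)
    if (var(a) == 0 && var(b) == 0) next
    r <- iccTwoWay(a, b)
    expect_equal(r$icc, oracleICC21(a, b), tolerance = 1e-8)
    expect_true(r$ci[1] <= r$icc + 1e-8 && r$ci[2] >= r$icc - 1e-8)
  }
})

test_that("ICC is 1 for identical raters, < 1 under a constant shift", {
  a <- c(0, 20, 40, 60, 80)
  expect_equal(iccTwoWay(a, a)$icc, 1)
  shifted <- iccTwoWay(a, a + 10)
  expect_lt(shifted$icc, 1)               # absolute agreement penalizes shift
  expect_gt(shifted$icc, 0.5)
  expect_equal(shifted$icc, oracleICC21(a, a + 10), tolerance = 1e-8)
  expect_false(iccTwoWay(rep(5, 6), rep(5, 6))$defined)
})

test_that("ICC of independent uniform raters is near zero", {
  set.seed(10)
  a <- runif(200, 0, 100)
  b <- runif(200, 0, 100)
  expect_lt(abs(iccTwoWay(a, b)$icc), 0.15)
})

test_that("Fleiss' kappa matches the brute-force table formula", {
  set.seed(12)
  for (trial in 1:100) {
    n <- sample(5:12, 1)
    a <- runif(n, 0, 100)
    b <- runif(n, 0, 100)
    k <- kappaAtCutoffs(a, b, cutoffs = c(1, 5, 10, 25, 50))
    for (ct in c(1, 5, 10, 25, 50))
      expect_equal(unname(k[as.character(ct)]),
                   oracleFleiss(a >= ct, b >= ct))
  }
})

test_that("kappa hits 1 on perfect mixed agreement and < 0 on disagreement", {
  a <- c(0, 0, 60, 70, 80)
  expect_equal(unname(kappaAtCutoffs(a, a, 50)), 1)
  # raters always on opposite sides of the cutoff
  b <- c(60, 70, 0, 0, 0)
  expect_lt(unname(kappaAtCutoffs(a, b, 50)), 0)
  # all subjects in one category for both raters: undefined
  expect_true(is.na(kappaAtCutoffs(c(60, 70, 80), c(90, 95, 99), 50)))
  # boundary: a score exactly at the cutoff is positive
  expect_equal(unname(kappaAtCutoffs(c(25, 0), c(30, 0), 25)), 1)
})

test_that("correlations match standard and rank-based oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlations(x, 2 * x)$pearson, 1)
  expect_equal(correlations(x, 2 * x)$spearman, 1)
  sq <- correlations(x, x^2)
  expect_equal(sq$spearman, 1)
  expect_lt(sq$pearson, 1)
  set.seed(13)
  for (trial in 1:20) {
    a <- sample(0:50, 8, replace = TRUE)  # replace => ties exercised
    b <- sample(0:50, 8, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    r <- correlations(a, b)
    expect_equal(r$spearman, oracleSpearman(a, b), tolerance = 1e-12)
    expect_equal(r$pearson, cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  }
  expect_false(correlations(c(1, 1, 1), c(1, 2, 3))$defined)
})

test_that("TPS/IPS association tests behave as specified", {
  # identical IPS distributions in both TPS groups -> p near 1
  tpsv <- c(rep(0, 10), rep(60, 10))
  ipsv <- rep(c(10, 20), 10)
  r <- ipsTpsAssociation(tpsv, ipsv, tpsCutoffs = 50)
  expect_gt(r$mannWhitney$p[1], 0.9)

  # hand chi-square on the [[30,5],[5,30]] table (no continuity correction)
  tps2 <- c(rep(0, 30), rep(5, 5), rep(0, 5), rep(10, 30))
  ips2 <- c(rep(0, 30), rep(0, 5), rep(5, 5), rep(5, 30))
  r2 <- ipsTpsAssociation(tps2, ips2)
  expect_equal(r2$chisq$statistic, 35.7143, tolerance = 1e-4)
  expect_equal(r2$chisq$statistic,
               oracleChisq(matrix(c(30, 5, 5, 30), 2)), tolerance = 1e-8)

  # perfectly separated groups -> extreme U, tiny p
  sep <- ipsTpsAssociation(c(rep(0, 6), rep(80, 6)),
                           c(1:6, 94:99), tpsCutoffs = 50)
  expect_lt(sep$mannWhitney$p[1], 0.01)
  expect_true(sep$mannWhitney$U[1] %in% c(0, 36))

  # empty group flagged, not an error
  e <- ipsTpsAssociation(rep(80, 5), runif(5), tpsCutoffs = 50)
  expect_false(e$mannWhitney$defined[1])
})

test_that("concordance report bundles consistent statistics", {
  set.seed(14)
  a <- runif(20, 0, 100)
  b <- pmin(pmax(a + rnorm(20, 0, 5), 0), 100)
  rep <- concordanceReport(a, b)
  expect_s4_class(rep, "ConcordanceReport")
  expect_equal(icc(rep), iccTwoWay(a, b)$icc)
  expect_equal(kappas(rep), kappaAtCutoffs(a, b))
  expect_equal(rep@n, 20L)
  expect_output(show(rep), "ICC")
})
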