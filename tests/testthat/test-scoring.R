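test_that("per-gene standardisation matches hand arithmetic", {
  m <- matrix(c(0, 2), 1, 2, dimnames = list("g1", c("a", "b")))
  z <- zscoreTransform(m)
  expect_equal(unname(z["g1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  m2 <- rbind(m, g2 = c(3, 3))
  z2 <- zscoreTransform(m2)
  expect_equal(unname(z2["g2", ]), c(0, 0))
  expect_identical(attr(z2, "zeroVariance"), "g2")

  set.seed(9)
  m3 <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  z3 <- zscoreTransform(m3)
  expect_equal(unname(rowMeans(z3)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z3, 1, sd)), rep(1, 5), tolerance = 1e-12)

  expect_error(zscoreTransform(m[, 1, drop = FALSE]), "single")
})

test_that("combined Z-score reduces correctly in degenerate cases", {
  m <- matrix(c(0, 2, 0, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("U1", "D1"), c("a", "b")))
  sc <- combinedZScore(m, GeneSignature("s", up = "U1", down = "D1"))
  expect_equal(unname(scores(sc)), c(0, 0), tolerance = 1e-12)

  scUp <- suppressWarnings(
    combinedZScore(m, GeneSignature("s", up = "U1", down = "ABSENT")))
  expect_equal(unname(scores(scUp)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_identical(scUp@nDownUsed, 0L)

  expect_error(
    combinedZScore(m, GeneSignature("s", up = "X", down = "Y")),
    "no signature genes")
  const <- matrix(5, 2, 3, dimnames = list(c("U1", "D1"), c("a", "b", "c")))
  expect_error(
    combinedZScore(const, GeneSignature("s", up = "U1", down = "D1")),
    "zero variance")
})

test_that("combined Z-score equals the brute-force oracle", {
  m <- toyExpr(10, 6, seed = 101)
  sig <- GeneSignature("s", up = c("g01", "g02", "g03"),
                       down = c("g04", "g05"))
  sc <- combinedZScore(m, sig)
  expect_equal(unname(scores(sc)),
               unname(oracleCombinedZ(m, sig@up, sig@down)),
               tolerance = 1e-12)
  expect_identical(sc@nUpUsed, 3L)
  expect_identical(sc@nDownUsed, 2L)
})

test_that("combined Z-score is invariant under positive gene-wise affine maps", {
  m <- toyExpr(8, 7, seed = 5)
  sig <- GeneSignature("s", up = paste0("g0", 1:3), down = paste0("g0", 4:5))
  base <- scores(combinedZScore(m, sig))
  set.seed(6)
  a <- runif(nrow(m), 0.5, 4)
  b <- rnorm(nrow(m), 0, 10)
  sc2 <- scores(combinedZScore(m * a + b, sig))
  expect_equal(sc2, base, tolerance = 1e-10)
})

test_that("raising an up-gene in one sample raises its relative score", {
  m <- toyExpr(6, 5, seed = 12)
  sig <- GeneSignature("s", up = "g01", down = "g04")
  for (delta in c(0.5, 1, 3)) {
    m2 <- m
    m2["g01", 2] <- m2["g01", 2] + delta
    rel1 <- scores(combinedZScore(m, sig))
    rel2 <- scores(combinedZScore(m2, sig))
    ## rank of sample 2 among samples must not decrease
    expect_gte(rank(rel2)[2], rank(rel1)[2])
    expect_equal(unname(rel2), unname(oracleCombinedZ(m2, "g01", "g04")),
                 tolerance = 1e-12)
  }
})

test_that("mean-scaled score follows its closed form and invariances", {
  m <- rbind(U1 = c(2, 4), D1 = c(1, 4), H1 = c(1, 2))
  colnames(m) <- c("a", "b")
  sig <- GeneSignature("s", up = "U1", down = "D1")
  sc <- meanScaledScore(m, sig, housekeeping = "H1")
  expect_equal(unname(scores(sc)), c(1, 0))   # (2-1)/1 = 1; 4-4 = 0

  ## global multiplicative rescale on linear scale leaves G0m unchanged
  sc2 <- meanScaledScore(m * 3.7, sig, housekeeping = "H1")
  expect_equal(scores(sc2), scores(sc), tolerance = 1e-12)

  ## signature genes are excluded from the housekeeping mean
  sc3 <- meanScaledScore(m, sig, housekeeping = c("H1", "U1", "D1"))
  expect_equal(scores(sc3), scores(sc))

  mzero <- m; mzero["H1", 1] <- 0
  expect_error(meanScaledScore(mzero, sig, "H1"), "a")
})

test_that("rank score matches extreme cases and the sort oracle", {
  m <- matrix(c(10, 1, 5, 5, 5, 5), 3, 2,
              dimnames = list(c("U1", "D1", "N1"), c("a", "b")))
  sig <- GeneSignature("s", up = "U1", down = "D1")
  sc <- rankScore(m, sig)
  expect_equal(unname(scores(sc)), c(1, 0))  # extremes; then all tied

  m2 <- toyExpr(20, 5, seed = 33)
  sig2 <- GeneSignature("s", up = sprintf("g%02d", 1:4),
                        down = sprintf("g%02d", 15:20))
  expect_equal(unname(scores(rankScore(m2, sig2))),
               unname(oracleRankScore(m2, sig2@up, sig2@down)),
               tolerance = 1e-12)
})

test_that("purity adjustment filters and rescales on the linear scale", {
  m <- matrix(c(10, 10, 10), 1, 3,
              dimnames = list("g1", c("a", "b", "c")))
  purity <- c(a = 0.29, b = 0.5, c = 1)
  out <- purityAdjust(m, purity, minPurity = 0.30, logScale = FALSE)
  expect_identical(colnames(out), c("b", "c"))       # a dropped at 29%
  expect_equal(out["g1", "b"], 20)                   # 10 / 0.5
  expect_equal(out["g1", "c"], 10)                   # purity 1: unchanged

  ## log2-scale input is exponentiated, divided, re-logged
  mlog <- log2(m)
  outLog <- purityAdjust(mlog, purity, logScale = TRUE)
  expect_equal(unname(2^outLog["g1", ]), c(20, 10), tolerance = 1e-12)

  expect_error(purityAdjust(m, purity[-1]), "missing purity")

  em <- ExpressionMatrix(mlog)
  outEm <- purityAdjust(em, purity)
  expect_s4_class(outEm, "ExpressionMatrix")
  expect_true(isLogScale(outEm))
})

test_that("state calls use a strict threshold and proportions partition", {
  sc <- c(s1 = -1, s2 = 0, s3 = 2)
  labels <- callStates(sc, threshold = 0)
  expect_identical(labels$state, c("proliferating", "proliferating", "G0"))

  all_g0 <- callStates(c(a = 1, b = 2), threshold = 0)
  expect_identical(proportionArrested(all_g0)$fraction_G0, 1)

  grouped <- callStates(c(a = 1, b = -1, c = 1, d = 1),
                        group = c("t0", "t0", "t1", "t1"))
  tab <- proportionArrested(grouped)
  expect_identical(sum(tab$n), 4)
  expect_equal(tab$fraction_G0[tab$group == "t0"], 0.5)
  expect_equal(tab$fraction_G0[tab$group == "t1"], 1)
})

test_that("planted two-state fractions are recovered within binomial error", {
  sig <- readSignature(g0SignatureFile("generic"))
  fractions <- c(0.4, 0.9, 0.6)
  for (i in seq_along(fractions)) {
    sim <- simulateBulk(sig, nSamples = 500, fractionG0 = fractions[i],
                        effectSize = 3, seed = 100 + i)
    sc <- combinedZScore(sim$expr, sig)
    frac <- proportionArrested(callStates(sc))$fraction_G0
    expect_lt(abs(frac - fractions[i]),
              3 * sqrt(fractions[i] * (1 - fractions[i]) / 500) + 0.02)
  }
})

test_that("AUC follows the Mann-Whitney formulation with ties", {
  expect_equal(evaluateAUC(c(a = 1, b = 2, c = 10, d = 11),
                           c(a = "proliferating", b = "proliferating",
                             c = "G0", d = "G0")), 1)
  expect_equal(evaluateAUC(c(a = 1, b = 1, c = 1, d = 1),
                           c(a = "proliferating", b = "proliferating",
                             c = "G0", d = "G0")), 0.5)
  ## 6 samples, one inversion: 8 of 9 pairs concordant
  s <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5, s6 = 6)
  truth <- c(s1 = "proliferating", s2 = "proliferating", s3 = "G0",
             s4 = "proliferating", s5 = "G0", s6 = "G0")
  expect_equal(evaluateAUC(s, truth), 8 / 9)
  expect_error(evaluateAUC(s, setNames(rep("G0", 6), names(s))),
               "both classes")
})

test_that("rank AUC equals pair-counting and trapezoidal oracles", {
  set.seed(77)
  for (rep in 1:5) {
    s <- round(rnorm(30), 1)          # rounding forces ties
    names(s) <- sprintf("s%02d", 1:30)
    isPos <- rep(c(TRUE, FALSE), 15)
    truth <- setNames(ifelse(isPos, "G0", "proliferating"), names(s))
    auc <- evaluateAUC(s, truth)
    expect_equal(auc, oracleAUCPairs(s, isPos), tolerance = 1e-12)
    expect_equal(auc, oracleAUCTrapezoid(s, isPos), tolerance = 1e-12)
  }
})

test_that("k-means high/low recovers a planted split and ignores batch", {
  sig <- readSignature(g0SignatureFile("generic"))
  sim <- simulateBulk(sig, nSamples = 60, effectSize = 3, seed = 21)
  lv <- kmeansHighLow(sim$expr, sig, seed = 3)
  truth <- setNames(sim$truth$labels$state, sim$truth$labels$sample)
  expect_identical(unname(ifelse(lv$level == "high", "G0", "proliferating")),
                   unname(truth[lv$sample]))

  ## adding +5 to one batch of otherwise comparable samples must not
  ## drive the clustering
  m <- exprValues(sim$expr)
  batch <- rep(c("b1", "b2"), length.out = ncol(m))
  m2 <- m + ifelse(batch == "b2", 5, 0)[col(m)]
  lv2 <- kmeansHighLow(m2, sig, batch = batch, seed = 3)
  expect_identical(lv2$level, lv$level)

  ## orientation rule: the "high" cluster has the higher mean score
  sc <- scores(combinedZScore(sim$expr, sig))
  expect_gt(mean(sc[lv$sample[lv$level == "high"]]),
            mean(sc[lv$sample[lv$level == "low"]]))
})
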