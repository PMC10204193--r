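test_that("mutation rate follows log10(count / exome length)", {
  expect_equal(mutationRate(38), 0)
  expect_equal(mutationRate(380), 1)
  expect_equal(mutationRate(50), log10(50 / 38), tolerance = 1e-12)
  expect_equal(mutationRate(50), 0.1192, tolerance = 1e-3)
  expect_error(mutationRate(0), "pseudo-count")
  expect_equal(mutationRate(0, floor = 1), log10(1 / 38))
})

test_that("driver prioritisation matches the hand-computed odds ratio", {
  samples <- sprintf("s%03d", 1:100)
  events <- matrix(0L, 100, 2,
                   dimnames = list(samples, c("hit", "flat")))
  events[1:40, "hit"] <- 1L           # 40/50 mutated in high
  events[51:60, "hit"] <- 1L          # 10/50 mutated in low
  events[seq(1, 100, 4), "flat"] <- 1L  # same rate in both groups
  groups <- setNames(rep(c("high", "low"), each = 50), samples)
  res <- prioritiseDrivers(events, groups)
  hit <- res[res$feature == "hit", ]
  expect_equal(hit$odds_ratio, 16)    # (40*40)/(10*10)
  expect_identical(hit$direction, "enriched")
  expect_true(hit$flagged)
  flat <- res[res$feature == "flat", ]
  expect_gt(flat$p, 0.9)
  expect_false(flat$flagged)

  withConst <- cbind(events, stuck = 1L)
  expect_warning(prioritiseDrivers(withConst, groups), "constant")
})

test_that("BH correction keeps null false-flag rates controlled", {
  flagged <- vapply(1:10, function(s) {
    set.seed(200 + s)
    ev <- matrix(rbinom(80 * 30, 1, 0.3), 80, 30,
                 dimnames = list(sprintf("s%02d", 1:80),
                                 sprintf("f%02d", 1:30)))
    gr <- setNames(rep(c("high", "low"), each = 40), rownames(ev))
    mean(suppressWarnings(prioritiseDrivers(ev, gr))$flagged)
  }, numeric(1))
  expect_lte(mean(flagged), 0.05)
})

test_that("single-iteration consensus equals the single fit", {
  g <- simulateGenomic(nSamples = 200, seed = 31)
  ens <- ensembleElasticNet(g$X, g$y, nIter = 1, subsampleFrac = 1,
                            seed = 31)
  expect_identical(sort(consensusFeatures(ens)),
                   sort(ens@iterations[[1]]$features))
  expect_equal(meanCoefficients(ens)[consensusFeatures(ens)],
               ens@iterations[[1]]$coefficients[consensusFeatures(ens)])
})

test_that("consensus shrinks (weakly) as iterations accumulate", {
  g <- simulateGenomic(nSamples = 200, noiseSd = 2, seed = 32)
  ens5 <- ensembleElasticNet(g$X, g$y, nIter = 5, seed = 32)
  ens20 <- ensembleElasticNet(g$X, g$y, nIter = 20, seed = 32)
  ## same seed stream: the first 5 iterations coincide, so the larger
  ## ensemble's consensus is a subset
  expect_true(all(consensusFeatures(ens20) %in% consensusFeatures(ens5)))
})

test_that("the minimum-mutation filter drops the configured samples", {
  g <- simulateGenomic(nSamples = 300, fracLowMutation = 0.3, seed = 33)
  ens <- ensembleElasticNet(g$X, g$y, nMutations = g$nMutations,
                            nIter = 2, seed = 33)
  expect_identical(nrow(ens@design),
                   sum(g$nMutations >= 50))
  expect_false(any(rownames(ens@design) %in% g$truth$lowMutationSamples))
})

test_that("noise-free planted coefficients are recovered closely", {
  g <- simulateGenomic(nSamples = 400, noiseSd = 0, seed = 34)
  ens <- ensembleElasticNet(g$X, g$y, nIter = 5, lambdaRule = "min",
                            seed = 34)
  expect_setequal(consensusFeatures(ens), names(g$truth$coefficients))
  model <- consensusLinearModel(ens)
  ## elastic-net averaging keeps a little shrinkage even without noise
  expect_equal(model@coefficients[names(g$truth$coefficients)],
               g$truth$coefficients, tolerance = 0.05)
  ## prediction at the training means reproduces the response mean
  expect_equal(unname(predict(model, t(as.matrix(model@featureMeans)))),
               mean(ens@response), tolerance = 1e-10)
})

test_that("consensus model intercept follows its closed form", {
  ens <- new("EnsembleResult",
             iterations = list(list(features = "f",
                                    coefficients = c(f = 2))),
             consensusFeatures = "f", meanCoefficients = c(f = 2),
             nIter = 1L,
             design = matrix(c(-1, 1), 2, 1,
                             dimnames = list(c("a", "b"), "f")),
             response = c(a = 0, b = 2))
  model <- consensusLinearModel(ens)
  expect_equal(model@intercept, 1)   # mean(y) - 2 * mean(f) = 1 - 0
  empty <- new("EnsembleResult", iterations = list(),
               consensusFeatures = character(),
               meanCoefficients = numeric(), nIter = 0L,
               design = matrix(numeric(), 0, 0), response = numeric())
  expect_error(consensusLinearModel(empty), "empty")
})

test_that("linear Shapley values satisfy formula, additivity and the oracle", {
  model <- new("LinearConsensusModel", intercept = 0.5,
               coefficients = c(a = 2, b = -1, c = 0.3),
               featureMeans = c(a = 1, b = 0, c = -2))
  X <- rbind(s1 = c(a = 3, b = 1, c = -2),
             s2 = c(a = 1, b = 0, c = -2),
             s3 = c(a = -2, b = 4, c = 1))
  phi <- linearShap(model, X)
  expect_equal(phi["s1", "a"], 4)       # 2 * (3 - 1)
  expect_equal(unname(phi["s2", ]), c(0, 0, 0))  # at the feature means

  pred <- predict(model, X)
  predAtMeans <- predict(model, t(as.matrix(model@featureMeans)))
  expect_equal(rowSums(phi), pred - predAtMeans, tolerance = 1e-12)

  for (s in rownames(X)) {
    brute <- oracleShapPermutation(model@coefficients, model@featureMeans,
                                   X[s, ])
    expect_equal(unname(phi[s, ]), brute, tolerance = 1e-12)
  }

  expect_error(linearShap(model, X[, c("a", "b")]), "lacks")
})

test_that("ANOVA screening finds a perfectly separating feature", {
  set.seed(41)
  n <- 80
  labels <- setNames(rep(c("G0", "proliferating"), each = n / 2),
                     sprintf("s%03d", 1:n))
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(names(labels), sprintf("f%02d", 1:12)))
  X[, "f01"] <- ifelse(labels == "G0", 3, -3) + rnorm(n, sd = 0.2)
  fit <- anovaRfTissueModel(X, labels, topK = 3, nSplits = 3, seed = 41)
  expect_identical(fit$features[1], "f01")
  expect_gt(fit$meanAccuracy, 0.95)

  full <- anovaRfTissueModel(X, labels, topK = ncol(X), nSplits = 1,
                             seed = 41)
  expect_setequal(full$features, colnames(X))

  permuted <- setNames(sample(labels), names(labels))
  nullFit <- anovaRfTissueModel(X[, -1], permuted, topK = 5, nSplits = 4,
                                seed = 42)
  expect_lt(abs(nullFit$meanAccuracy - 0.5), 0.25)

  expect_error(anovaRfTissueModel(X, setNames(rep("G0", n), names(labels))),
               "two classes")
})
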