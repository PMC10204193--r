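#' Per-sample mutation rate
#'
#' Log10 of the mutation count divided by the exome capture length in
#' megabases (default 38 Mb).
#'
#' @param nMutations non-negative mutation count(s).
#' @param exomeMb exome capture length in Mb (default 38).
#' @param floor optional pseudo-count applied to zero counts; with the
#'   default `NULL`, a zero count is an error.
#' @return Numeric vector of log10 mutation rates.
#' @examples
#' mutationRate(38)   # 0
#' mutationRate(380)  # 1
#' @export
mutationRate <- function(nMutations, exomeMb = 38, floor = NULL) {
  if (any(nMutations < 0)) stopValidation("mutation counts must be >= 0")
  if (any(nMutations == 0)) {
    if (is.null(floor))
      stopValidation("mutation count of 0 has no defined log rate; set ",
                     "'floor' to use a pseudo-count")
    nMutations <- pmax(nMutations, floor)
  }
  log10(nMutations / exomeMb)
}

#' Prioritise driver events enriched or depleted in high-G0 samples
#'
#' Per binary feature, a 2x2 Fisher's exact test of event presence
#' against the high/low G0 grouping, with Benjamini-Hochberg correction.
#'
#' @param events samples x features 0/1 matrix (rownames = samples).
#' @param groups data.frame with `sample` and `level` columns
#'   (`"high"`/`"low"`, as from [kmeansHighLow()]) or a named character
#'   vector.
#' @param alphaFdr FDR threshold for flagging (default 0.05).
#' @return data.frame with one row per testable feature: `feature`,
#'   `odds_ratio` (conditional MLE from the exact test), `p`, `q`,
#'   `direction` (`"enriched"`/`"depleted"` in high-G0) and `flagged`.
#'   Features constant across all samples are skipped with a warning.
#' @export
prioritiseDrivers <- function(events, groups, alphaFdr = 0.05) {
  events <- as.matrix(events)
  if (!all(events %in% c(0, 1)))
    stopValidation("'events' must be a binary 0/1 matrix")
  if (is.data.frame(groups)) groups <- setNames(groups$level, groups$sample)
  groups <- groups[rownames(events)]
  if (anyNA(groups)) stopValidation("missing group label for some samples")
  high <- groups == "high"
  if (sum(high) == 0L || sum(!high) == 0L)
    stopValidation("both groups must be non-empty")
  constant <- apply(events, 2L, function(x) length(unique(x)) == 1L)
  if (any(constant))
    warning("skipping constant feature(s): ",
            paste(head(colnames(events)[constant], 5L), collapse = ", "),
            call. = FALSE)
  feats <- colnames(events)[!constant]
  res <- lapply(feats, function(f) {
    tab <- table(factor(events[, f], levels = c(1, 0)),
                 factor(ifelse(high, "high", "low"),
                        levels = c("high", "low")))
    ft <- fisher.test(tab)
    ## sample odds ratio (Haldane 0.5 correction on zero cells); the
    ## exact test's conditional MLE is kept for inference only
    ct <- as.numeric(tab)
    if (any(ct == 0)) ct <- ct + 0.5
    or <- (ct[1L] * ct[4L]) / (ct[2L] * ct[3L])
    rateHigh <- mean(events[high, f])
    rateLow <- mean(events[!high, f])
    data.frame(feature = f, odds_ratio = or,
               p = ft$p.value,
               direction = if (rateHigh >= rateLow) "enriched" else
                 "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out$flagged <- out$q < alphaFdr
  out[order(out$q, out$p), c("feature", "odds_ratio", "p", "q",
                             "direction", "flagged")]
}

## Standardise continuous columns of a design matrix; binary 0/1 columns
## are left untouched. Returns the matrix plus the applied centre/scale.
.prepareDesign <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopValidation("feature matrix needs colnames")
  isBinary <- apply(X, 2L, function(x) all(x %in% c(0, 1)))
  centre <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  names(centre) <- names(scale) <- colnames(X)
  for (j in which(!isBinary)) {
    centre[j] <- mean(X[, j])
    s <- sd(X[, j])
    scale[j] <- if (s > 0) s else 1
    X[, j] <- (X[, j] - centre[j]) / scale[j]
  }
  list(X = X, centre = centre, scale = scale, isBinary = isBinary)
}

#' Ensemble elastic-net selection of genomic features
#'
#' Fits an elastic net regression of the G0 score on genomic features
#' `nIter` times, each time on a random subsample (without replacement)
#' of `subsampleFrac` of the samples. Samples with fewer than
#' `minMutations` mutations are removed first. Features with a nonzero
#' coefficient (|coef| > `coefTol`) in every iteration form the consensus
#' set; their coefficients are averaged across iterations. The elastic-net
#' mixing parameter and penalty are chosen by cross-validation over
#' `alphaGrid` with an automatic lambda path: once on the full filtered
#' training data and reused across iterations (`tuning = "once"`, the
#' default, so that iteration-to-iteration variation reflects subsampling
#' only), or independently inside every iteration
#' (`tuning = "per_iteration"`).
#'
#' Continuous covariates are standardised (training mean/SD); binary 0/1
#' features are left as is. Categorical features should be supplied
#' one-hot encoded.
#'
#' @param X samples x features numeric matrix.
#' @param y named numeric response (G0 scores), aligned with `X` rows by
#'   name when named.
#' @param nMutations optional named mutation count per sample, used by the
#'   `minMutations` filter.
#' @param nIter ensemble iterations (default 1000).
#' @param subsampleFrac fraction of samples drawn per iteration
#'   (default 0.9).
#' @param minMutations minimum mutation count (default 50; ignored when
#'   `nMutations` is NULL).
#' @param alphaGrid elastic-net mixing grid (default 0.1 to 1 by 0.1).
#' @param nFolds cross-validation folds (default 10).
#' @param tuning `"once"` or `"per_iteration"`.
#' @param lambdaRule `"1se"` (default) takes the largest penalty within
#'   one standard error of the CV minimum, the conventional parsimony
#'   rule that keeps marginal noise features out of every iteration;
#'   `"min"` takes the CV-minimising penalty.
#' @param coefTol threshold below which a coefficient counts as zero
#'   (default 1e-8).
#' @param seed RNG seed.
#' @return An [EnsembleResult-class]; empty consensus (with a warning) is
#'   a valid outcome.
#' @export
ensembleElasticNet <- function(X, y, nMutations = NULL, nIter = 1000L,
                               subsampleFrac = 0.9, minMutations = 50L,
                               alphaGrid = seq(0.1, 1, by = 0.1),
                               nFolds = 10L,
                               tuning = c("once", "per_iteration"),
                               lambdaRule = c("1se", "min"),
                               coefTol = 1e-8, seed = 1L) {
  tuning <- match.arg(tuning)
  lambdaRule <- match.arg(lambdaRule)
  if (nIter < 1L) stopValidation("'nIter' must be >= 1")
  if (subsampleFrac <= 0 || subsampleFrac > 1)
    stopValidation("'subsampleFrac' must lie in (0, 1]")
  X <- as.matrix(X)
  if (!is.null(names(y))) y <- y[rownames(X)]
  if (length(y) != nrow(X) || anyNA(y))
    stopValidation("'y' must provide one value per sample of X")
  if (!is.null(nMutations)) {
    if (!is.null(names(nMutations))) nMutations <- nMutations[rownames(X)]
    keep <- !is.na(nMutations) & nMutations >= minMutations
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  prep <- .prepareDesign(X)
  Xs <- prep$X
  n <- nrow(Xs)
  m <- floor(subsampleFrac * n)
  if (m < nFolds) stopValidation("too few samples after filtering")

  .withSeed(.deriveSeed(seed, "ensemble"), {
    cvPick <- function(xx, yy) {
      best <- NULL
      for (a in alphaGrid) {
        cv <- glmnet::cv.glmnet(xx, yy, alpha = a, nfolds = nFolds,
                                standardize = FALSE)
        err <- min(cv$cvm)
        if (is.null(best) || err < best$err)
          best <- list(alpha = a,
                       lambda = if (lambdaRule == "1se") cv$lambda.1se
                                else cv$lambda.min,
                       err = err)
      }
      best
    }
    tuned <- if (tuning == "once") cvPick(Xs, y) else NULL
    iterations <- vector("list", nIter)
    for (i in seq_len(nIter)) {
      idx <- sample.int(n, m)
      tun <- if (is.null(tuned)) cvPick(Xs[idx, , drop = FALSE], y[idx])
             else tuned
      fit <- glmnet::glmnet(Xs[idx, , drop = FALSE], y[idx],
                            alpha = tun$alpha, standardize = FALSE)
      cf <- as.matrix(coef(fit, s = tun$lambda))[, 1L][-1L]  # drop intercept
      nz <- names(cf)[abs(cf) > coefTol]
      iterations[[i]] <- list(features = nz, coefficients = cf[nz])
    }
    consensus <- Reduce(intersect, lapply(iterations, `[[`, "features"))
    if (!length(consensus)) {
      warning("no feature was selected in every iteration; consensus is ",
              "empty", call. = FALSE)
      meanCoef <- numeric()
    } else {
      meanCoef <- vapply(consensus, function(f)
        mean(vapply(iterations, function(it) it$coefficients[[f]],
                    numeric(1L))), numeric(1L))
    }
    new("EnsembleResult", iterations = iterations,
        consensusFeatures = as.character(consensus),
        meanCoefficients = meanCoef, nIter = as.integer(nIter),
        design = Xs, response = y)
  })
}

#' Consensus linear model from an ensemble
#'
#' The model's coefficients are the ensemble's averaged elastic-net
#' coefficients on the consensus features; the intercept is chosen so the
#' model is exact at the training feature means
#' (`intercept = mean(y) - sum(coef * mean(x))`). Training feature means
#' are stored for Shapley attribution.
#'
#' @param ens an [EnsembleResult-class] with non-empty consensus.
#' @param X,y training design and response; default to the (prepared)
#'   matrices stored in `ens`.
#' @return A [LinearConsensusModel-class].
#' @export
consensusLinearModel <- function(ens, X = ens@design, y = ens@response) {
  feats <- consensusFeatures(ens)
  if (!length(feats)) stopValidation("consensus feature set is empty")
  cf <- meanCoefficients(ens)[feats]
  mu <- colMeans(as.matrix(X)[, feats, drop = FALSE])
  new("LinearConsensusModel",
      intercept = mean(y) - sum(cf * mu),
      coefficients = cf, featureMeans = mu)
}

#' Exact Shapley attributions for a linear model
#'
#' Under the independent-features convention the Shapley value of feature
#' k for sample j is `coef_k * (x_jk - mean_k)`, exact for linear models.
#' Attributions are additive: they sum to the sample's prediction minus
#' the prediction at the training feature means.
#'
#' @param model a [LinearConsensusModel-class].
#' @param X samples x features matrix covering the model features.
#' @return samples x features matrix of attributions.
#' @export
linearShap <- function(model, X) {
  feats <- names(model@coefficients)
  X <- as.matrix(X)
  miss <- setdiff(feats, colnames(X))
  if (length(miss))
    stopValidation("X lacks model feature(s): ",
                   paste(miss, collapse = ", "))
  dev <- sweep(X[, feats, drop = FALSE], 2L, model@featureMeans, "-")
  sweep(dev, 2L, model@coefficients, "*")
}

#' ANOVA feature screening plus random-forest classification
#'
#' Per feature, a one-way ANOVA F statistic against the binary G0 state
#' ranks the features; the `topK` features train a random-forest
#' classifier whose accuracy is averaged over `nSplits` random stratified
#' 80/20 train/test splits.
#'
#' @param X samples x features numeric matrix.
#' @param labels data.frame with `sample` and `state` columns, or a named
#'   character vector of two classes.
#' @param topK features kept (default 30; clipped to the total).
#' @param nSplits random splits (default 5).
#' @param trainFrac training fraction per split (default 0.8).
#' @param numTrees forest size (default 500).
#' @param seed RNG seed.
#' @return list with `features` (selected, by decreasing F), `fStat`
#'   (named statistics) and `meanAccuracy`.
#' @export
anovaRfTissueModel <- function(X, labels, topK = 30L, nSplits = 5L,
                               trainFrac = 0.8, numTrees = 500L,
                               seed = 1L) {
  X <- as.matrix(X)
  if (is.data.frame(labels)) labels <- setNames(labels$state, labels$sample)
  if (!is.null(names(labels))) labels <- labels[rownames(X)]
  g <- factor(labels)
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stopValidation("labels must contain two classes with >= 2 samples each")
  topK <- min(topK, ncol(X))
  fStat <- apply(X, 2L, function(x) {
    if (sd(x) == 0) return(0)
    unname(oneway.test(x ~ g, var.equal = TRUE)$statistic)
  })
  sel <- names(sort(fStat, decreasing = TRUE))[seq_len(topK)]
  Xd <- as.data.frame(X[, sel, drop = FALSE])
  acc <- .withSeed(.deriveSeed(seed, "anova_rf"), {
    vapply(seq_len(nSplits), function(s) {
      trainIdx <- unlist(lapply(levels(g), function(lv) {
        idx <- which(g == lv)
        sample(idx, floor(trainFrac * length(idx)))
      }), use.names = FALSE)
      testIdx <- setdiff(seq_len(nrow(Xd)), trainIdx)
      fit <- ranger::ranger(
        x = Xd[trainIdx, , drop = FALSE], y = g[trainIdx],
        num.trees = numTrees, num.threads = 1L,
        seed = .deriveSeed(seed, paste0("rf_split_", s)))
      pred <- predict(fit, data = Xd[testIdx, , drop = FALSE],
                      num.threads = 1L)$predictions
      mean(pred == g[testIdx])
    }, numeric(1L))
  })
  list(features = sel, fStat = fStat[sel], meanAccuracy = mean(acc),
       splitAccuracy = acc)
}
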