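#' Per-gene standardisation across samples
#'
#' Each gene row is centred and scaled to unit sample standard deviation
#' (n-1 denominator). Zero-variance genes are set to 0 and recorded in the
#' attribute `zeroVariance`.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix with at
#'   least 2 samples.
#' @return Object of the same kind with standardised rows; the matrix
#'   carries a `zeroVariance` attribute naming flagged genes (on the
#'   returned matrix, or in `metadata()` for an ExpressionMatrix).
#' @export
zscoreTransform <- function(expr) {
  m <- .exprs(expr)
  if (ncol(m) < 2L)
    stopValidation("cohort-level standardisation is undefined for a single ",
                   "sample; provide a multi-sample matrix")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  zero <- rownames(m)[s == 0]
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  if (is(expr, "ExpressionMatrix")) {
    out <- ExpressionMatrix(z, isLogScale(expr))
    S4Vectors::metadata(out)$zeroVariance <- zero
    out
  } else {
    attr(z, "zeroVariance") <- zero
    z
  }
}

## Sum of z over present, non-degenerate genes divided by sqrt of their
## count; the core of the combined Z-score. Returns list(score, nUsed,
## contributions).
.directionZ <- function(z, genes, zero) {
  present <- intersect(genes, rownames(z))
  informative <- setdiff(present, zero)
  if (!length(informative)) {
    sc <- rep(0, ncol(z))
    names(sc) <- colnames(z)
    return(list(score = sc, nUsed = length(present),
                contributions = z[character(), , drop = FALSE]))
  }
  sub <- z[informative, , drop = FALSE]
  list(score = colSums(sub) / sqrt(nrow(sub)),
       nUsed = length(present),
       contributions = sub)
}

#' Combined Z-score of G0 arrest
#'
#' Per-gene z-scores (across samples) are summed over the upregulated
#' signature genes and divided by the square root of the number of genes
#' used; likewise for the downregulated genes; the final score is the up
#' score minus the down score. Signature genes absent from the data
#' (dropout) are silently excluded; zero-variance genes contribute 0 and
#' are excluded from the square-root normaliser. Higher scores mean more
#' G0-arrested.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix
#'   (>= 2 samples).
#' @param sig a [GeneSignature-class].
#' @param contributions if `TRUE`, attach the per-gene z contribution
#'   matrix as attribute `contributions` (used by stress subtyping).
#' @return A [G0Scores-class].
#' @export
combinedZScore <- function(expr, sig, contributions = FALSE) {
  m <- .exprs(expr)
  z <- zscoreTransform(m)
  zero <- attr(z, "zeroVariance")
  presentUp <- intersect(sig@up, rownames(m))
  presentDown <- intersect(sig@down, rownames(m))
  if (length(presentUp) + length(presentDown) == 0L)
    stopValidation("no signature genes present in the expression data")
  if (length(sig@up) && !length(presentUp))
    warning("no upregulated signature genes present; score uses the ",
            "down direction only", call. = FALSE)
  if (length(sig@down) && !length(presentDown))
    warning("no downregulated signature genes present; score uses the ",
            "up direction only", call. = FALSE)
  up <- .directionZ(z, sig@up, zero)
  down <- .directionZ(z, sig@down, zero)
  if (nrow(up$contributions) + nrow(down$contributions) == 0L)
    stopValidation("all present signature genes have zero variance; ",
                   "the combined Z-score is undefined")
  out <- G0Scores(up$score - down$score, method = "zscore",
                  nUpUsed = up$nUsed, nDownUsed = down$nUsed)
  if (contributions)
    attr(out, "contributions") <- rbind(up$contributions,
                                        -down$contributions)
  out
}

#' Mean-scaled G0 arrest score
#'
#' Per sample, the mean expression of the upregulated signature genes
#' minus the mean of the downregulated genes, divided by the mean of a
#' housekeeping gene set: `G0m = (mean(G_U) - mean(G_D)) / mean(G_H)`.
#' Means are taken over the genes present in the data. Housekeeping genes
#' that overlap the signature are excluded from the housekeeping mean.
#'
#' @inheritParams combinedZScore
#' @param housekeeping character vector of housekeeping gene identifiers.
#' @return A [G0Scores-class] with method `"mean_scaled"`.
#' @export
meanScaledScore <- function(expr, sig, housekeeping) {
  m <- .exprs(expr)
  up <- intersect(sig@up, rownames(m))
  down <- intersect(sig@down, rownames(m))
  hk <- intersect(setdiff(housekeeping, signatureGenes(sig)), rownames(m))
  if (!length(up) || !length(down))
    stopValidation("mean-scaled score needs at least one up and one down ",
                   "signature gene present")
  if (!length(hk))
    stopValidation("no housekeeping genes present in the expression data")
  hkMean <- colMeans(m[hk, , drop = FALSE])
  zeroHk <- colnames(m)[hkMean == 0]
  if (length(zeroHk))
    stopValidation("housekeeping mean expression is zero for sample(s): ",
                   paste(head(zeroHk, 5L), collapse = ", "))
  score <- (colMeans(m[up, , drop = FALSE]) -
              colMeans(m[down, , drop = FALSE])) / hkMean
  G0Scores(score, method = "mean_scaled",
           nUpUsed = length(up), nDownUsed = length(down))
}

#' Rank-based G0 arrest score
#'
#' A simple rank comparator: per sample, all genes are ranked ascending
#' (mid-ranks for ties) and ranks normalised to [0, 1] as
#' `(rank - 1) / (N - 1)`. The score is the mean normalised rank of the
#' upregulated genes minus that of the downregulated genes.
#'
#' @inheritParams combinedZScore
#' @return A [G0Scores-class] with method `"rank"`.
#' @export
rankScore <- function(expr, sig) {
  m <- .exprs(expr)
  up <- intersect(sig@up, rownames(m))
  down <- intersect(sig@down, rownames(m))
  if (!length(up) && !length(down))
    stopValidation("no signature genes present in the expression data")
  n <- nrow(m)
  if (n < 2L) stopValidation("rank score needs at least 2 genes")
  score <- apply(m, 2L, function(x) {
    r <- (rank(x, ties.method = "average") - 1) / (n - 1)
    upMean <- if (length(up)) mean(r[up]) else 0
    downMean <- if (length(down)) mean(r[down]) else 0
    upMean - downMean
  })
  G0Scores(score, method = "rank",
           nUpUsed = length(up), nDownUsed = length(down))
}

#' Adjust bulk expression for tumour purity
#'
#' Samples below the purity cutoff are removed (default 30%); remaining
#' samples are divided by their purity estimate on the linear scale, so a
#' diluted tumour signal is scaled back up. Log2-scale input (per the
#' `logScale` flag, or `logScale` argument for plain matrices) is
#' exponentiated, divided, and re-logged. `mode = "none"` only applies the
#' purity filter.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix.
#' @param purity named numeric vector in [0, 1] covering every sample.
#' @param minPurity samples with purity below this are dropped
#'   (default 0.3).
#' @param mode `"divide"` (default) or `"none"`.
#' @param logScale used when `expr` is a plain matrix (default TRUE).
#' @return Object of the same kind as `expr`, filtered and scaled.
#' @export
purityAdjust <- function(expr, purity, minPurity = 0.3,
                         mode = c("divide", "none"), logScale = TRUE) {
  mode <- match.arg(mode)
  m <- .exprs(expr)
  if (minPurity <= 0 || minPurity > 1)
    stopValidation("'minPurity' must lie in (0, 1]")
  miss <- setdiff(colnames(m), names(purity))
  if (length(miss))
    stopValidation("missing purity estimate for sample(s): ",
                   paste(head(miss, 5L), collapse = ", "))
  purity <- purity[colnames(m)]
  if (any(purity < 0 | purity > 1, na.rm = TRUE) || anyNA(purity))
    stopValidation("purity values must lie in [0, 1]")
  keep <- purity >= minPurity
  m <- m[, keep, drop = FALSE]
  purity <- purity[keep]
  isLog <- .isLog(expr, logScale)
  if (mode == "divide") {
    if (isLog) {
      lin <- 2^m
      m <- log2(sweep(lin, 2L, purity, "/"))
    } else {
      m <- sweep(m, 2L, purity, "/")
    }
  }
  if (is(expr, "ExpressionMatrix")) ExpressionMatrix(m, isLog) else m
}

#' Call G0 versus proliferating states from scores
#'
#' @param scores a [G0Scores-class] or named numeric vector.
#' @param threshold samples with score strictly greater than this are
#'   called `"G0"` (default 0, the natural midpoint of the combined
#'   Z-score).
#' @param group optional grouping label per sample (e.g. timepoint or
#'   dose), recycled or named.
#' @return data.frame with columns `sample`, `state`
#'   (`"G0"`/`"proliferating"`) and optionally `group`.
#' @export
callStates <- function(scores, threshold = 0, group = NULL) {
  s <- if (is(scores, "G0Scores")) scores(scores) else scores
  if (is.null(names(s))) stopValidation("scores must be named by sample")
  out <- data.frame(sample = names(s),
                    state = ifelse(s > threshold, "G0", "proliferating"),
                    stringsAsFactors = FALSE)
  if (!is.null(group)) {
    if (!is.null(names(group))) group <- group[out$sample]
    out$group <- as.character(group)
  }
  out
}

#' Fraction of arrested samples per group
#'
#' @param labels data.frame as produced by [callStates()]; a missing
#'   `group` column is treated as a single group `"all"`.
#' @return data.frame with one row per group: `group`, `fraction_G0`, `n`.
#' @export
proportionArrested <- function(labels) {
  if (!all(c("sample", "state") %in% names(labels)))
    stopValidation("labels need 'sample' and 'state' columns")
  grp <- if ("group" %in% names(labels)) labels$group else
    rep("all", nrow(labels))
  keep <- !is.na(grp)
  if (any(!keep)) {
    warning("samples with missing group omitted", call. = FALSE)
    labels <- labels[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  if (!nrow(labels)) stopValidation("no labelled samples")
  agg <- lapply(split(labels$state, grp), function(st)
    c(fraction = mean(st == "G0"), n = length(st)))
  data.frame(group = names(agg),
             fraction_G0 = vapply(agg, `[[`, numeric(1L), "fraction"),
             n = vapply(agg, `[[`, numeric(1L), "n"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC AUC of a score against known states
#'
#' Area under the ROC curve via the rank (Mann-Whitney) formulation with
#' mid-rank tie correction: the probability that a randomly chosen G0
#' sample scores higher than a randomly chosen proliferating one (ties
#' counting one half).
#'
#' @param scores a [G0Scores-class] or named numeric vector.
#' @param truth data.frame with `sample` and `state` columns (as from
#'   [callStates()]), or a named character vector of states; must contain
#'   both classes.
#' @return AUC in [0, 1].
#' @export
evaluateAUC <- function(scores, truth) {
  s <- if (is(scores, "G0Scores")) scores(scores) else scores
  if (is.data.frame(truth)) truth <- setNames(truth$state, truth$sample)
  common <- intersect(names(s), names(truth))
  if (!length(common)) stopValidation("no samples shared by scores and truth")
  s <- s[common]
  pos <- truth[common] == "G0"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stopValidation("both classes must be present in 'truth'")
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-group high/low G0 classification by k-means
#'
#' After removing batch (e.g. tissue) structure with [adjustBatch()],
#' samples are clustered with k-means (k = 2, Lloyd's algorithm, 25
#' seeded restarts) on the signature-gene submatrix. The cluster with the
#' higher mean combined Z-score is labelled `"high"`.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix.
#' @param sig a [GeneSignature-class].
#' @param batch optional batch label per sample.
#' @param seed RNG seed for the k-means restarts.
#' @return data.frame with columns `sample` and `level`
#'   (`"high"`/`"low"`).
#' @export
kmeansHighLow <- function(expr, sig, batch = NULL, seed = 1L) {
  m <- .exprs(expr)
  if (ncol(m) < 2L) stopValidation("need at least 2 samples")
  if (!is.null(batch)) m <- adjustBatch(m, batch)
  genes <- intersect(signatureGenes(sig), rownames(m))
  if (!length(genes))
    stopValidation("no signature genes present in the expression data")
  sub <- t(m[genes, , drop = FALSE])
  km <- .withSeed(.deriveSeed(seed, "kmeans"),
                  kmeans(sub, centers = 2L, nstart = 25L, iter.max = 100L,
                         algorithm = "Lloyd"))
  if (length(unique(km$cluster)) < 2L)
    stopValidation("k-means produced a single cluster; the data may be ",
                   "degenerate")
  sc <- scores(combinedZScore(m, sig))
  meanByCluster <- tapply(sc[colnames(m)], km$cluster, mean)
  high <- as.integer(names(which.max(meanByCluster)))
  data.frame(sample = colnames(m),
             level = ifelse(km$cluster == high, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}
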