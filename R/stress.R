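#' Score the five stress-response programmes
#'
#' Applies [combinedZScore()] with each programme signature and with the
#' generic signature, keeping the per-gene z contributions that underlie
#' each programme score (these are the within-sample replicates used by
#' the t test in [assignBulkSubtype()]).
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix.
#' @param sigs a [StressSignatureSet-class].
#' @param generic the generic G0 [GeneSignature-class].
#' @return A [StressScores-class].
#' @export
scoreStressProgrammes <- function(expr, sigs, generic) {
  m <- .exprs(expr)
  contr <- list()
  mat <- matrix(NA_real_, nrow = ncol(m), ncol = length(QUIESCENCE_FORMS),
                dimnames = list(colnames(m), QUIESCENCE_FORMS))
  for (p in QUIESCENCE_FORMS) {
    sig <- programmes(sigs)[[p]]
    if (!length(intersect(signatureGenes(sig), rownames(m))))
      stopValidation("no genes of programme '", p,
                     "' present in the expression data")
    sc <- combinedZScore(m, sig, contributions = TRUE)
    mat[, p] <- scores(sc)[rownames(mat)]
    contr[[p]] <- attr(sc, "contributions")
  }
  gen <- scores(combinedZScore(m, generic))[rownames(mat)]
  new("StressScores", scores = mat, generic = gen, contributions = contr)
}

#' Assign bulk stress-response subtypes
#'
#' Samples without evidence of arrest (generic G0 score at or below
#' `genericThreshold`) are `"uncertain"`. Otherwise the candidate
#' programme is the one with the highest score; it is assigned only if
#' (a) that score exceeds the cohort mean plus one cohort standard
#' deviation of that programme's score distribution, and (b) a two-sided
#' Welch t test comparing the candidate programme's per-gene z
#' contributions in that sample against the pooled contributions of the
#' other four programmes gives p below `alpha` with a higher candidate
#' mean. Samples failing either check are `"uncertain"`.
#'
#' @param ssm a [StressScores-class] from [scoreStressProgrammes()].
#' @param genericThreshold gate on the generic G0 score (default 0).
#' @param alpha t-test significance level (default 0.05).
#' @param sdMultiplier how many cohort SDs above the mean the winning
#'   programme must lie (default 1).
#' @return data.frame with columns `sample` and `subtype` (a programme
#'   label or `"uncertain"`).
#' @export
assignBulkSubtype <- function(ssm, genericThreshold = 0, alpha = 0.05,
                              sdMultiplier = 1) {
  stopifnot(is(ssm, "StressScores"))
  sc <- programmeScores(ssm)
  if (nrow(sc) < 3L)
    stopValidation("cohort SD undefined: need at least 3 samples")
  contr <- zContributions(ssm)
  if (!length(contr)) stopValidation("per-gene contributions missing")
  cohortMean <- colMeans(sc)
  cohortSd <- apply(sc, 2L, sd)
  gate <- cohortMean + sdMultiplier * cohortSd
  subtype <- vapply(rownames(sc), function(smp) {
    if (genericScores(ssm)[smp] <= genericThreshold) return("uncertain")
    cand <- QUIESCENCE_FORMS[which.max(sc[smp, ])]
    if (sc[smp, cand] <= gate[cand]) return("uncertain")
    x <- contr[[cand]][, smp]
    y <- unlist(lapply(setdiff(QUIESCENCE_FORMS, cand),
                       function(p) contr[[p]][, smp]), use.names = FALSE)
    if (length(x) < 2L || length(y) < 2L) return("uncertain")
    tt <- tryCatch(t.test(x, y, alternative = "two.sided"),
                   error = function(e) NULL)
    if (is.null(tt) || tt$p.value >= alpha || mean(x) <= mean(y))
      return("uncertain")
    cand
  }, character(1L))
  data.frame(sample = rownames(sc), subtype = unname(subtype),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify cells by kNN mapping onto reference stress profiles
#'
#' Query cells are mapped onto labelled bulk reference profiles of the
#' five stress programmes: (1) restrict both matrices to shared genes;
#' (2) remove the query/reference batch effect with [adjustBatch()];
#' (3) fit PCA on the combined matrix (centred, not re-scaled) and keep
#' the top `nPcs` components; (4) for each query cell take the `k`
#' nearest reference points by Euclidean distance; a class is assigned if
#' it holds at least `minVotes` of the k neighbours, otherwise the cell
#' is `"uncertain"`. Distance ties at the k-th neighbour are broken by
#' reference sample order for determinism.
#'
#' @param query [ExpressionMatrix-class] or genes x cells matrix.
#' @param ref reference genes x samples matrix (or ExpressionMatrix).
#' @param refLabels programme label per reference sample (named or in
#'   reference column order).
#' @param k number of neighbours (default 3).
#' @param minVotes votes needed for a call (default 2).
#' @param nPcs number of principal components (default 10; clipped to the
#'   available rank with a warning).
#' @return data.frame with columns `sample` and `subtype`.
#' @export
knnProjectClassify <- function(query, ref, refLabels, k = 3L, minVotes = 2L,
                               nPcs = 10L) {
  q <- .exprs(query)
  r <- .exprs(ref)
  if (!is.null(names(refLabels))) refLabels <- refLabels[colnames(r)]
  refLabels <- as.character(refLabels)
  if (length(refLabels) != ncol(r))
    stopValidation("'refLabels' must label every reference sample")
  shared <- intersect(rownames(q), rownames(r))
  if (!length(shared))
    stopValidation("query and reference share no genes")
  if (ncol(r) < k)
    stopValidation("need at least k = ", k, " reference samples")
  comb <- cbind(q[shared, , drop = FALSE], r[shared, , drop = FALSE])
  batch <- rep(c("query", "reference"), c(ncol(q), ncol(r)))
  comb <- adjustBatch(comb, batch)
  pc <- prcomp(t(comb), center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (nPcs > avail) {
    warning("nPcs clipped from ", nPcs, " to the available rank ", avail,
            call. = FALSE)
    nPcs <- avail
  }
  emb <- pc$x[, seq_len(nPcs), drop = FALSE]
  qEmb <- emb[seq_len(ncol(q)), , drop = FALSE]
  rEmb <- emb[ncol(q) + seq_len(ncol(r)), , drop = FALSE]
  subtype <- vapply(seq_len(nrow(qEmb)), function(i) {
    d <- sqrt(colSums((t(rEmb) - qEmb[i, ])^2))
    nn <- order(d)[seq_len(k)]          # order() breaks ties by index
    votes <- table(refLabels[nn])
    if (max(votes) >= minVotes) names(which.max(votes)) else "uncertain"
  }, character(1L))
  data.frame(sample = colnames(q), subtype = subtype,
             row.names = NULL, stringsAsFactors = FALSE)
}
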