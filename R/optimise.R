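#' Repeated random-forest Gini importance of signature genes
#'
#' For every training dataset a random-forest classifier is trained
#' `nRep` times (different seeds) to predict the G0/cycling state of each
#' cell from the expression of the signature genes; per-gene Gini
#' (impurity-decrease) importances are averaged over the repetitions and
#' then min-max normalised to [0, 1] within each dataset. Signature genes
#' absent from a dataset receive importance 0.
#'
#' @param datasets list of `list(expr = , labels = )` pairs; `expr` an
#'   [ExpressionMatrix-class] or genes x cells matrix, `labels` a
#'   data.frame with `sample`/`state` columns or named character vector
#'   with both classes present.
#' @param sig the [GeneSignature-class] whose genes are ranked.
#' @param nRep repetitions per dataset (default 100; 1000 reproduces the
#'   full procedure at a ~10x cost).
#' @param numTrees trees per forest (default 500).
#' @param seed RNG seed.
#' @return genes x datasets matrix of normalised importances.
#' @export
giniImportance <- function(datasets, sig, nRep = 100L, numTrees = 500L,
                           seed = 1L) {
  if (nRep < 1L) stopValidation("'nRep' must be >= 1")
  genes <- signatureGenes(sig)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  imp <- matrix(0, nrow = length(genes), ncol = length(datasets),
                dimnames = list(genes, names(datasets)))
  for (d in names(datasets)) {
    m <- .exprs(datasets[[d]]$expr)
    labels <- datasets[[d]]$labels
    if (is.data.frame(labels)) labels <- setNames(labels$state, labels$sample)
    if (!is.null(names(labels))) labels <- labels[colnames(m)]
    g <- factor(labels)
    if (nlevels(g) != 2L)
      stopValidation("dataset '", d, "' must contain both classes")
    present <- intersect(genes, rownames(m))
    if (!length(present))
      stopValidation("dataset '", d, "' contains no signature genes")
    X <- as.data.frame(t(m[present, , drop = FALSE]))
    total <- rep(0, length(present))
    names(total) <- present
    for (r in seq_len(nRep)) {
      fit <- ranger::ranger(
        x = X, y = g, num.trees = numTrees, importance = "impurity",
        num.threads = 1L,
        seed = .deriveSeed(seed, paste0(d, "_rep_", r)))
      total <- total + fit$variable.importance[present]
    }
    avg <- total / nRep
    rng <- range(avg)
    imp[present, d] <- if (diff(rng) > 0) (avg - rng[1L]) / diff(rng)
                       else 0
  }
  imp
}

#' Candidate gene subsets from an importance threshold sweep
#'
#' For each threshold, the candidate subset holds every gene whose
#' normalised importance exceeds the threshold in at least one dataset.
#' Thresholds producing a subset already seen keep only the smallest
#' threshold.
#'
#' @param imp genes x datasets importance matrix from [giniImportance()].
#' @param thresholds grid in [0, 1] (default 0 to 1 by 0.01).
#' @return list of candidates, each `list(threshold = , genes = )`,
#'   ordered by increasing threshold (so non-increasing subset size).
#' @export
thresholdSweep <- function(imp, thresholds = seq(0, 1, by = 0.01)) {
  if (!length(thresholds)) stopValidation("threshold grid is empty")
  thresholds <- sort(thresholds)
  seen <- character()
  out <- list()
  for (t in thresholds) {
    genes <- rownames(imp)[apply(imp > t, 1L, any)]
    key <- paste(sort(genes), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(threshold = t, genes = genes)
  }
  out
}

#' Validate candidate subsets against experimental measurements
#'
#' Each candidate subset is scored with [combinedZScore()] on a
#' validation expression matrix (directions inherited from the parent
#' signature) and Pearson-correlated with each experimental measurement
#' of quiescence. Candidates whose mean assay correlation is significant
#' (Fisher z test of the mean correlation at `gateAlpha`) are
#' shortlisted; among those whose primary-assay correlation lies within
#' one Fisher-z standard error of the best (statistically
#' indistinguishable at the validation sample size), the largest subset
#' wins — at equal demonstrated performance, retaining more genes hedges
#' against single-cell dropout. Residual ties go to the smaller
#' threshold. If no candidate clears the gate the best primary
#' correlation is returned with a warning.
#'
#' @param cands candidate list from [thresholdSweep()].
#' @param valExpr validation [ExpressionMatrix-class] or matrix.
#' @param measurements named list of numeric vectors (one per assay),
#'   aligned with `valExpr` columns (by name when named).
#' @param sig the parent [GeneSignature-class] providing directions.
#' @param primary name of the assay maximised (default the first).
#' @param gateAlpha significance gate on the mean correlation
#'   (default 0.05).
#' @return The winning candidate: `list(threshold, genes, correlations,
#'   meanCorrelation, p)`.
#' @export
validateSubsets <- function(cands, valExpr, measurements, sig,
                            primary = names(measurements)[1L],
                            gateAlpha = 0.05) {
  if (!length(cands)) stopValidation("no candidate subsets supplied")
  m <- .exprs(valExpr)
  measurements <- lapply(measurements, function(v) {
    if (!is.null(names(v))) v <- v[colnames(m)]
    if (length(v) != ncol(m) || anyNA(v))
      stopValidation("each measurement must cover every validation sample")
    v
  })
  if (!primary %in% names(measurements))
    stopValidation("unknown primary assay: ", primary)
  nVal <- ncol(m)
  evaluated <- lapply(cands, function(cand) {
    up <- intersect(intersect(sig@up, cand$genes), rownames(m))
    down <- intersect(intersect(sig@down, cand$genes), rownames(m))
    if (!length(up) && !length(down)) return(NULL)
    sub <- GeneSignature(paste0("subset_t", cand$threshold),
                         up = up, down = down)
    sc <- scores(combinedZScore(m, sub))
    cors <- vapply(measurements, function(v) cor(sc, v), numeric(1L))
    meanR <- mean(cors)
    ## Fisher z test of the mean correlation against zero
    z <- atanh(max(min(meanR, 1 - 1e-12), -1 + 1e-12)) * sqrt(nVal - 3)
    p <- 2 * pt(-abs(z), df = Inf)
    c(cand, list(correlations = cors, meanCorrelation = meanR, p = p))
  })
  skipped <- vapply(evaluated, is.null, logical(1L))
  if (any(skipped))
    warning(sum(skipped), " candidate(s) with no genes present in the ",
            "validation data were skipped", call. = FALSE)
  evaluated <- evaluated[!skipped]
  if (!length(evaluated))
    stopValidation("no candidate subset could be evaluated")
  primR <- vapply(evaluated, function(e) e$correlations[[primary]],
                  numeric(1L))
  sizes <- vapply(evaluated, function(e) length(e$genes), numeric(1L))
  pass <- vapply(evaluated, function(e) e$p < gateAlpha, logical(1L))
  pool <- if (any(pass)) which(pass) else {
    warning("no candidate cleared the significance gate; returning the ",
            "best primary-assay correlation", call. = FALSE)
    seq_along(evaluated)
  }
  ## one-SE shortlist on the Fisher z scale around the best primary
  ## correlation, then prefer the largest subset
  clamp <- function(r) max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- vapply(primR, function(r) atanh(clamp(r)), numeric(1L))
  se <- 1 / sqrt(nVal - 3)
  near <- pool[z[pool] >= max(z[pool]) - se]
  best <- near[order(-sizes[near],
                     vapply(evaluated[near], `[[`, numeric(1L),
                            "threshold"))][1L]
  evaluated[[best]]
}

#' One-call signature reduction
#'
#' Chains [giniImportance()], [thresholdSweep()] and [validateSubsets()].
#'
#' @inheritParams giniImportance
#' @inheritParams validateSubsets
#' @param thresholds threshold grid for the sweep.
#' @return As [validateSubsets()], plus the importance matrix as
#'   attribute `importance`.
#' @export
optimiseSignature <- function(datasets, sig, valExpr, measurements,
                              primary = names(measurements)[1L],
                              nRep = 100L, numTrees = 500L,
                              thresholds = seq(0, 1, by = 0.01),
                              gateAlpha = 0.05, seed = 1L) {
  imp <- giniImportance(datasets, sig, nRep = nRep, numTrees = numTrees,
                        seed = seed)
  cands <- thresholdSweep(imp, thresholds)
  out <- validateSubsets(cands, valExpr, measurements, sig,
                         primary = primary, gateAlpha = gateAlpha)
  attr(out, "importance") <- imp
  out
}
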