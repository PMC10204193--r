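## Synthetic data with known ground truth. Every generator is a pure
## function of its arguments and seed: one global seed fans out into
## named per-component streams (see .deriveSeed) so sub-simulations stay
## independently reproducible.

## Shared core: two-state log2 expression with signature shifts, optional
## batch offsets and purity mixing.
.simulateTwoState <- function(sig, nSamples, fractionG0, effectSize,
                              nBackground, baselineMean, baselineSd,
                              noiseSd, nBatches, batchOffsets,
                              purityShape, seed, backgroundGenes = NULL) {
  if (fractionG0 < 0 || fractionG0 > 1)
    stopValidation("'fractionG0' must lie in [0, 1]")
  if (fractionG0 %in% c(0, 1))
    warning("single-class simulation (fractionG0 = ", fractionG0, ")",
            call. = FALSE)
  genes <- c(signatureGenes(sig),
             if (is.null(backgroundGenes))
               sprintf("BG%04d", seq_len(nBackground))
             else setdiff(backgroundGenes, signatureGenes(sig)))
  .withSeed(.deriveSeed(seed, "bulk"), {
    mu <- rnorm(length(genes), baselineMean, baselineSd)
    names(mu) <- genes
    samples <- sprintf("S%04d", seq_len(nSamples))
    nG0 <- round(fractionG0 * nSamples)
    state <- rep("proliferating", nSamples)
    state[sample.int(nSamples, nG0)] <- "G0"
    m <- matrix(rnorm(length(genes) * nSamples, sd = noiseSd),
                nrow = length(genes),
                dimnames = list(genes, samples)) + mu
    isG0 <- state == "G0"
    if (any(isG0)) {
      m[sig@up, isG0] <- m[sig@up, isG0] + effectSize
      m[sig@down, isG0] <- m[sig@down, isG0] - effectSize
    }
    batch <- rep_len(sprintf("batch%d", seq_len(nBatches)), nSamples)
    if (is.null(batchOffsets)) batchOffsets <- rep(0, nBatches)
    m <- m + rep(batchOffsets[as.integer(factor(batch))],
                 each = length(genes))
    purity <- rep(1, nSamples)
    if (!is.null(purityShape)) {
      purity <- rbeta(nSamples, purityShape[1L], purityShape[2L])
      ## mix the tumour profile with a fixed "normal" baseline profile on
      ## the linear scale, then re-log
      normalLin <- 2^mu
      lin <- 2^m
      m <- log2(sweep(lin, 2L, purity, "*") +
                  outer(normalLin, 1 - purity))
    }
    names(purity) <- names(state) <- samples
    list(matrix = m, state = state, batch = setNames(batch, samples),
         purity = purity)
  })
}

#' Simulate a bulk two-state expression cohort
#'
#' Log2 expression is drawn per gene around a Normal baseline; samples in
#' the G0 state have the signature's up genes shifted by `+effectSize`
#' and the down genes by `-effectSize`. Optional additive batch offsets
#' and tumour-purity mixing (convex combination with a fixed "normal"
#' profile on the linear scale at weight `1 - purity`) emulate the main
#' nuisance structure of bulk cohorts.
#'
#' @param sig a [GeneSignature-class] defining the shifted genes.
#' @param nSamples number of samples (default 200).
#' @param fractionG0 planted fraction of G0 samples (default 0.5).
#' @param effectSize per-gene log2 shift in G0 samples (default 3).
#' @param nBackground unshifted background genes added (default 100).
#' @param baselineMean,baselineSd Normal parameters of gene baselines on
#'   log2 scale (defaults 5 and 2).
#' @param noiseSd per-measurement noise SD (default 1).
#' @param nBatches,batchOffsets optional batch structure: samples are
#'   assigned round-robin to `nBatches` batches and `batchOffsets[b]` is
#'   added to every value of batch b.
#' @param purityShape optional `c(shape1, shape2)` of a Beta distribution
#'   from which per-sample purities are drawn; `NULL` (default) disables
#'   purity mixing.
#' @param backgroundGenes optional explicit background gene names
#'   (overrides `nBackground`); lets callers plant uninformative genes
#'   with chosen identifiers, e.g. the non-core part of a signature.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `expr` (an [ExpressionMatrix-class], log2 scale) and
#'   `truth` (list with `labels` data.frame, `batch`, `purity`).
#' @export
simulateBulk <- function(sig, nSamples = 200L, fractionG0 = 0.5,
                         effectSize = 3, nBackground = 100L,
                         baselineMean = 5, baselineSd = 2, noiseSd = 1,
                         nBatches = 1L, batchOffsets = NULL,
                         purityShape = NULL, backgroundGenes = NULL, seed) {
  core <- .simulateTwoState(sig, nSamples, fractionG0, effectSize,
                            nBackground, baselineMean, baselineSd,
                            noiseSd, nBatches, batchOffsets, purityShape,
                            seed, backgroundGenes)
  list(expr = ExpressionMatrix(core$matrix, logScale = TRUE),
       truth = list(
         labels = data.frame(sample = colnames(core$matrix),
                             state = unname(core$state),
                             stringsAsFactors = FALSE),
         batch = core$batch, purity = core$purity))
}

#' Simulate a single-cell two-state expression matrix with dropout
#'
#' As [simulateBulk()] (identical values under the same seed), followed
#' by independent Bernoulli(`dropoutRate`) zeroing of individual
#' measurements, emulating single-cell technical dropout.
#'
#' @inheritParams simulateBulk
#' @param nCells number of cells (default 200).
#' @param dropoutRate probability that a measurement is zeroed
#'   (default 0.2).
#' @return As [simulateBulk()]; `truth` additionally records the dropout
#'   mask fraction per cell.
#' @export
simulateSingleCell <- function(sig, nCells = 200L, fractionG0 = 0.5,
                               effectSize = 3, dropoutRate = 0.2,
                               nBackground = 100L, baselineMean = 5,
                               baselineSd = 2, noiseSd = 1,
                               backgroundGenes = NULL, seed) {
  if (dropoutRate < 0 || dropoutRate > 1)
    stopValidation("'dropoutRate' must lie in [0, 1]")
  base <- simulateBulk(sig, nSamples = nCells, fractionG0 = fractionG0,
                       effectSize = effectSize, nBackground = nBackground,
                       baselineMean = baselineMean, baselineSd = baselineSd,
                       noiseSd = noiseSd, backgroundGenes = backgroundGenes,
                       seed = seed)
  m <- exprValues(base$expr)
  if (dropoutRate > 0) {
    mask <- .withSeed(.deriveSeed(seed, "dropout"),
                      matrix(rbinom(length(m), 1L, dropoutRate) == 1L,
                             nrow = nrow(m)))
    m[mask] <- 0
  }
  base$expr <- ExpressionMatrix(m, logScale = TRUE)
  base$truth$dropoutFraction <- colMeans(m == 0)
  base
}

#' Simulate cells occupying the five stress programmes
#'
#' Each arrested cell is assigned one programme; its programme's up genes
#' are shifted by `+effectSize` and its down genes by `-effectSize`. When
#' a `generic` signature is given, arrested cells additionally carry the
#' generic arrest shift (`genericEffect` on the generic up/down genes)
#' and `nProliferating` unshifted cycling cells are added, so the
#' cohort-relative generic score separates arrested from cycling cells as
#' it does in real cohorts. Bulk reference profiles (the same shifts with
#' independent noise) are emitted per programme for kNN
#' reference-mapping.
#'
#' @param sigs a [StressSignatureSet-class].
#' @param generic optional generic G0 [GeneSignature-class] shifted in
#'   every arrested cell.
#' @param nPerProgramme arrested cells per programme (default 100).
#' @param nProliferating cycling cells added when `generic` is given
#'   (default `nPerProgramme`).
#' @param effectSize programme-specific log2 shift (default 2).
#' @param genericEffect generic-arrest log2 shift (default `effectSize`).
#' @param nRefPerProgramme reference profiles per programme (default 3).
#' @param refNoiseSd noise SD of the reference profiles (default 0.3;
#'   bulk references average out cell-level noise).
#' @inheritParams simulateBulk
#' @return list with `expr`, `truth` (`labels` data.frame with `sample`
#'   and `programme`, cycling cells labelled `"proliferating"`) and
#'   `ref` (list with `expr` and `labels`).
#' @export
simulateStress <- function(sigs, generic = NULL, nPerProgramme = 100L,
                           nProliferating = if (is.null(generic)) 0L
                                            else nPerProgramme,
                           effectSize = 2, genericEffect = effectSize,
                           nRefPerProgramme = 3L, nBackground = 100L,
                           baselineMean = 5, baselineSd = 2, noiseSd = 1,
                           refNoiseSd = 0.3, seed) {
  allSigs <- programmes(sigs)
  genes <- unique(c(unlist(lapply(allSigs, signatureGenes),
                           use.names = FALSE),
                    if (!is.null(generic)) signatureGenes(generic),
                    sprintf("BG%04d", seq_len(nBackground))))
  .withSeed(.deriveSeed(seed, "stress"), {
    mu <- rnorm(length(genes), baselineMean, baselineSd)
    names(mu) <- genes
    nCells <- nPerProgramme * length(QUIESCENCE_FORMS) + nProliferating
    cells <- sprintf("C%04d", seq_len(nCells))
    programme <- sample(c(rep(QUIESCENCE_FORMS, each = nPerProgramme),
                          rep("proliferating", nProliferating)))
    genericShift <- rep(0, length(genes))
    names(genericShift) <- genes
    if (!is.null(generic)) {
      genericShift[generic@up] <- genericEffect
      genericShift[generic@down] <- -genericEffect
    }
    shiftFor <- function(p) {
      delta <- rep(0, length(genes))
      names(delta) <- genes
      if (p != "proliferating") {
        delta <- delta + genericShift
        delta[allSigs[[p]]@up] <- delta[allSigs[[p]]@up] + effectSize
        delta[allSigs[[p]]@down] <- delta[allSigs[[p]]@down] - effectSize
      }
      delta
    }
    states <- c(QUIESCENCE_FORMS, "proliferating")
    shifts <- vapply(states, shiftFor, numeric(length(genes)))
    m <- matrix(rnorm(length(genes) * nCells, sd = noiseSd),
                nrow = length(genes), dimnames = list(genes, cells)) +
      mu + shifts[, programme]
    refIds <- sprintf("REF_%s_%d",
                      rep(QUIESCENCE_FORMS, each = nRefPerProgramme),
                      seq_len(nRefPerProgramme))
    refLab <- rep(QUIESCENCE_FORMS, each = nRefPerProgramme)
    refM <- matrix(rnorm(length(genes) * length(refIds), sd = refNoiseSd),
                   nrow = length(genes),
                   dimnames = list(genes, refIds)) + mu + shifts[, refLab]
    list(expr = ExpressionMatrix(m, logScale = TRUE),
         truth = list(labels = data.frame(sample = cells,
                                          programme = programme,
                                          stringsAsFactors = FALSE)),
         ref = list(expr = ExpressionMatrix(refM, logScale = TRUE),
                    labels = setNames(refLab, refIds)))
  })
}

#' Simulate a genomic feature matrix with planted linear effects
#'
#' Binary event features are drawn Bernoulli(`featureProb`); the response
#' is `intercept + X %*% trueCoefs + Normal(0, noiseSd)`. Mutation counts
#' are drawn so a configurable fraction of samples falls below the
#' 50-mutation filter of [ensembleElasticNet()].
#'
#' @param nSamples samples (default 500).
#' @param trueCoefs named numeric vector of planted coefficients; its
#'   names become informative features.
#' @param nNull additional null features with zero coefficient
#'   (default 40).
#' @param featureProb event probability per binary feature (default 0.3).
#' @param noiseSd response noise SD (default 0.5).
#' @param intercept response intercept (default 0).
#' @param fracLowMutation fraction of samples drawn with < 50 mutations
#'   (default 0.1).
#' @param seed RNG seed.
#' @return list with `X` (samples x features matrix), `y` (named
#'   response), `nMutations` and `truth` (planted coefficients and the
#'   low-mutation sample names).
#' @export
simulateGenomic <- function(nSamples = 500L,
                            trueCoefs = c(f1 = 2, f2 = -1.5),
                            nNull = 40L, featureProb = 0.3, noiseSd = 0.5,
                            intercept = 0, fracLowMutation = 0.1, seed) {
  feats <- c(names(trueCoefs), sprintf("null%02d", seq_len(nNull)))
  .withSeed(.deriveSeed(seed, "genomic"), {
    samples <- sprintf("S%04d", seq_len(nSamples))
    X <- matrix(rbinom(nSamples * length(feats), 1L, featureProb),
                nrow = nSamples, dimnames = list(samples, feats))
    beta <- setNames(rep(0, length(feats)), feats)
    beta[names(trueCoefs)] <- trueCoefs
    y <- drop(intercept + X %*% beta + rnorm(nSamples, sd = noiseSd))
    names(y) <- samples
    low <- runif(nSamples) < fracLowMutation
    nMut <- ifelse(low, sample(1:49, nSamples, replace = TRUE),
                   sample(50:500, nSamples, replace = TRUE))
    names(nMut) <- samples
    list(X = X, y = y, nMutations = nMut,
         truth = list(coefficients = trueCoefs,
                      lowMutationSamples = samples[low]))
  })
}

#' Synthetic differential-expression table for the five quiescence forms
#'
#' Builds a deterministic DE table: per programme, `nUpPerForm` genes
#' significant and upregulated for that form only (distinct integer log2
#' fold changes `nUpPerForm .. 1`) and `nDownPerForm` downregulated
#' likewise; optionally `nShared` genes significant with a unidirectional
#' change in all five forms (alternating up/down), feeding the generic
#' refinement. Non-target forms get padj 0.8 and log2FC 0.
#'
#' @param nUpPerForm,nDownPerForm form-specific significant genes per
#'   direction (defaults 25).
#' @param nShared genes significant in all five forms (default 0).
#' @param padjSig adjusted p assigned to significant entries
#'   (default 0.001).
#' @return data.frame with `gene` plus `log2fc_<form>` / `padj_<form>`
#'   columns for every form in `QUIESCENCE_FORMS`.
#' @export
simulateDETable <- function(nUpPerForm = 25L, nDownPerForm = 25L,
                            nShared = 0L, padjSig = 0.001) {
  rows <- list()
  blank <- function(gene) {
    r <- as.list(setNames(rep(0, 2L * length(QUIESCENCE_FORMS)),
                          c(paste0("log2fc_", QUIESCENCE_FORMS),
                            paste0("padj_", QUIESCENCE_FORMS))))
    r[paste0("padj_", QUIESCENCE_FORMS)] <- 0.8
    c(list(gene = gene), r)
  }
  for (form in QUIESCENCE_FORMS) {
    tag <- toupper(substr(gsub("_", "", form), 1L, 4L))
    for (j in seq_len(nUpPerForm)) {
      r <- blank(sprintf("%s_UP%02d", tag, j))
      r[[paste0("log2fc_", form)]] <- nUpPerForm - j + 1
      r[[paste0("padj_", form)]] <- padjSig
      rows[[length(rows) + 1L]] <- r
    }
    for (j in seq_len(nDownPerForm)) {
      r <- blank(sprintf("%s_DN%02d", tag, j))
      r[[paste0("log2fc_", form)]] <- -(nDownPerForm - j + 1)
      r[[paste0("padj_", form)]] <- padjSig
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (nShared > 0L) {
    for (j in seq_len(nShared)) {
      up <- j %% 2L == 1L
      r <- blank(sprintf("SHARED%02d", j))
      r[paste0("log2fc_", QUIESCENCE_FORMS)] <- if (up) 1 + j / 10
                                                else -(1 + j / 10)
      r[paste0("padj_", QUIESCENCE_FORMS)] <- padjSig
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
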