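#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom stats sd cor prcomp kmeans rnorm runif rbinom rbeta quantile
#'   fisher.test p.adjust t.test oneway.test pt complete.cases setNames
#'   coef predict var
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Canonical labels of the five quiescence-inducing stress programmes
#'
#' Fixed order used everywhere a programme axis appears (DE table
#' columns, stress signature sets, stress score matrices).
#' @export
QUIESCENCE_FORMS <- c(
  "spontaneous", "contact_inhibition", "serum_starvation",
  "cdk46_inhibition", "mek_inhibition"
)

#' Gene signature of G0 arrest
#'
#' A named pair of disjoint gene lists: genes upregulated in quiescence and
#' genes downregulated in quiescence. Houses the generic G0 signature, the
#' minimal single-cell signature and the per-programme stress signatures.
#'
#' @slot name single character label.
#' @slot up character vector of upregulated gene identifiers.
#' @slot down character vector of downregulated gene identifiers.
#'
#' @aliases GeneSignature-class
#' @export
setClass("GeneSignature",
  representation(name = "character", up = "character", down = "character")
)

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  if (length(object@up) + length(object@down) == 0L)
    msg <- c(msg, "signature must contain at least one gene")
  if (anyDuplicated(object@up))
    msg <- c(msg, "duplicate identifiers in 'up'")
  if (anyDuplicated(object@down))
    msg <- c(msg, "duplicate identifiers in 'down'")
  both <- intersect(object@up, object@down)
  if (length(both))
    msg <- c(msg, paste0("genes listed as both up and down: ",
                         paste(head(both, 5L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature label.
#' @param up character vector of upregulated genes.
#' @param down character vector of downregulated genes.
#' @return A [GeneSignature-class] object.
#' @examples
#' GeneSignature("toy", up = c("A", "B"), down = "C")
#' @export
GeneSignature <- function(name, up = character(), down = character()) {
  new("GeneSignature", name = as.character(name),
      up = as.character(up), down = as.character(down))
}

#' Set of stress-programme signatures
#'
#' Holds one [GeneSignature-class] per quiescence-inducing stress programme
#' (spontaneous, contact inhibition, serum starvation, CDK4/6 inhibition,
#' MEK inhibition).
#'
#' @slot programmes named list of GeneSignature, names equal to
#'   `QUIESCENCE_FORMS`.
#' @aliases StressSignatureSet-class
#' @export
setClass("StressSignatureSet", representation(programmes = "list"))

setValidity("StressSignatureSet", function(object) {
  p <- object@programmes
  if (!identical(sort(names(p)), sort(QUIESCENCE_FORMS)))
    return(paste0("programmes must be named exactly: ",
                  paste(QUIESCENCE_FORMS, collapse = ", ")))
  if (!all(vapply(p, is, logical(1L), "GeneSignature")))
    return("every programme must be a GeneSignature")
  TRUE
})

#' @param programmes named list of GeneSignature objects, one per programme.
#' @rdname StressSignatureSet-class
#' @export
StressSignatureSet <- function(programmes) {
  new("StressSignatureSet", programmes = programmes[QUIESCENCE_FORMS])
}

#' Expression matrix container
#'
#' Genes x samples (or cells) expression values carried in a
#' SummarizedExperiment, with a flag recording whether values are on log
#' scale (log2 convention throughout the package).
#'
#' @aliases ExpressionMatrix-class
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  m <- SummarizedExperiment::assay(object, "exprs")
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "gene and sample identifiers are required")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate gene identifiers")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must be finite")
  ls <- S4Vectors::metadata(object)$logScale
  if (!is.logical(ls) || length(ls) != 1L || is.na(ls))
    msg <- c(msg, "metadata 'logScale' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames) and samples in
#'   columns (colnames).
#' @param logScale logical; `TRUE` (default) when values are
#'   log2-transformed.
#' @return An [ExpressionMatrix-class].
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, logScale = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    metadata = list(logScale = isTRUE(logScale))
  )
  new("ExpressionMatrix", se)
}

#' Per-sample G0 arrest scores
#'
#' @slot score named numeric vector of per-sample scores (higher = more
#'   G0-arrested).
#' @slot method scoring method label.
#' @slot nUpUsed,nDownUsed number of signature genes found in the data
#'   (after dropout) per direction.
#' @aliases G0Scores-class
#' @export
setClass("G0Scores",
  representation(score = "numeric", method = "character",
                 nUpUsed = "integer", nDownUsed = "integer")
)

setValidity("G0Scores", function(object) {
  if (is.null(names(object@score))) return("scores must be named by sample")
  if (anyDuplicated(names(object@score))) return("duplicate sample names")
  TRUE
})

G0Scores <- function(score, method, nUpUsed = NA_integer_,
                     nDownUsed = NA_integer_) {
  new("G0Scores", score = score, method = method,
      nUpUsed = as.integer(nUpUsed), nDownUsed = as.integer(nDownUsed))
}

#' Stress-programme score matrix
#'
#' Per-sample combined Z-scores for each of the five stress programmes,
#' the generic G0 score, and the per-gene z contributions underlying each
#' programme score (needed by the within-sample t test of
#' [assignBulkSubtype()]).
#'
#' @slot scores samples x 5 numeric matrix, columns `QUIESCENCE_FORMS`.
#' @slot generic named numeric vector of generic G0 scores.
#' @slot contributions named list (per programme) of genes x samples
#'   matrices of per-gene z contributions.
#' @aliases StressScores-class
#' @export
setClass("StressScores",
  representation(scores = "matrix", generic = "numeric",
                 contributions = "list")
)

setValidity("StressScores", function(object) {
  if (!identical(colnames(object@scores), QUIESCENCE_FORMS))
    return("score columns must be the five programmes, in canonical order")
  if (!identical(rownames(object@scores), names(object@generic)))
    return("generic scores must align with the score matrix rows")
  if (!identical(sort(names(object@contributions)), sort(QUIESCENCE_FORMS)))
    return("contributions must cover the five programmes")
  TRUE
})

#' Ensemble elastic-net result
#'
#' @slot iterations list with per-iteration `features` (nonzero-coefficient
#'   feature names) and `coefficients`.
#' @slot consensusFeatures features selected in every iteration.
#' @slot meanCoefficients per-consensus-feature coefficient mean over
#'   iterations.
#' @slot nIter number of iterations run.
#' @slot design the prepared design matrix the ensemble was fitted on
#'   (mutation-filtered, continuous columns standardised).
#' @slot response the matching response vector.
#' @aliases EnsembleResult-class
#' @export
setClass("EnsembleResult",
  representation(iterations = "list", consensusFeatures = "character",
                 meanCoefficients = "numeric", nIter = "integer",
                 design = "matrix", response = "numeric")
)

#' Consensus linear model
#'
#' Linear model whose coefficients are elastic-net coefficients averaged
#' across ensemble iterations; stores training feature means so exact
#' linear Shapley values can be computed.
#'
#' @slot intercept numeric scalar.
#' @slot coefficients named numeric vector.
#' @slot featureMeans named numeric vector, aligned with coefficients.
#' @aliases LinearConsensusModel-class
#' @export
setClass("LinearConsensusModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 featureMeans = "numeric")
)

setValidity("LinearConsensusModel", function(object) {
  if (!identical(names(object@coefficients), names(object@featureMeans)))
    return("coefficients and featureMeans must be aligned")
  TRUE
})
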