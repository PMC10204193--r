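#' @rdname GeneSignature-class
#' @export
setMethod("upGenes", "GeneSignature", function(x) x@up)

#' @rdname GeneSignature-class
#' @export
setMethod("downGenes", "GeneSignature", function(x) x@down)

#' @rdname GeneSignature-class
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) c(x@up, x@down))

#' @rdname GeneSignature-class
#' @export
setMethod("signatureName", "GeneSignature", function(x) x@name)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ",
      length(object@up), " up, ", length(object@down), " down\n", sep = "")
})

#' @rdname StressSignatureSet-class
#' @export
setMethod("programmes", "StressSignatureSet", function(x) x@programmes)

setMethod("show", "StressSignatureSet", function(object) {
  cat("StressSignatureSet with", length(object@programmes), "programmes:\n")
  for (p in names(object@programmes)) {
    s <- object@programmes[[p]]
    cat("  ", format(p, width = 20), length(s@up), "up /",
        length(s@down), "down\n")
  }
})

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("isLogScale", "ExpressionMatrix",
          function(x) isTRUE(S4Vectors::metadata(x)$logScale))

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
      "samples;", if (isLogScale(object)) "log2 scale" else "linear scale",
      "\n")
})

#' @rdname G0Scores-class
#' @export
setMethod("scores", "G0Scores", function(x) x@score)

#' @rdname G0Scores-class
#' @export
setMethod("scoreMethod", "G0Scores", function(x) x@method)

setMethod("show", "G0Scores", function(object) {
  cat("G0Scores (", object@method, "): ", length(object@score),
      " samples; genes used ", object@nUpUsed, " up / ",
      object@nDownUsed, " down\n", sep = "")
  print(head(object@score))
})

#' @describeIn G0Scores-class coerce scores to a data.frame with columns
#'   sample, score, n_up_used, n_down_used.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @export
as.data.frame.G0Scores <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(sample = names(x@score), score = unname(x@score),
             n_up_used = rep_len(x@nUpUsed, length(x@score)),
             n_down_used = rep_len(x@nDownUsed, length(x@score)),
             stringsAsFactors = FALSE)
}

#' @rdname StressScores-class
#' @export
setMethod("programmeScores", "StressScores", function(x) x@scores)

#' @rdname StressScores-class
#' @export
setMethod("genericScores", "StressScores", function(x) x@generic)

#' @rdname StressScores-class
#' @export
setMethod("zContributions", "StressScores", function(x) x@contributions)

setMethod("show", "StressScores", function(object) {
  cat("StressScores:", nrow(object@scores), "samples x",
      ncol(object@scores), "programmes (+ generic score)\n")
})

#' @rdname EnsembleResult-class
#' @export
setMethod("consensusFeatures", "EnsembleResult",
          function(x) x@consensusFeatures)

#' @rdname EnsembleResult-class
#' @export
setMethod("meanCoefficients", "EnsembleResult",
          function(x) x@meanCoefficients)

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult:", object@nIter, "iterations,",
      length(object@consensusFeatures), "consensus features\n")
  if (length(object@consensusFeatures))
    print(round(object@meanCoefficients, 4))
})

setMethod("show", "LinearConsensusModel", function(object) {
  cat("LinearConsensusModel:", length(object@coefficients),
      "features, intercept", signif(object@intercept, 4), "\n")
})

#' Predict from a consensus linear model
#'
#' @param object a [LinearConsensusModel-class].
#' @param newdata samples x features numeric matrix covering the model
#'   features.
#' @param ... unused.
#' @return Named numeric vector of predictions.
#' @export
setMethod("predict", "LinearConsensusModel", function(object, newdata, ...) {
  feats <- names(object@coefficients)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  drop(object@intercept +
         as.matrix(newdata[, feats, drop = FALSE]) %*% object@coefficients)
})
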