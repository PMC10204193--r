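#' @rdname GeneSignature-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname GeneSignature-class
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname G0Scores-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname G0Scores-class
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))

#' @rdname StressScores-class
#' @export
setGeneric("programmeScores", function(x) standardGeneric("programmeScores"))

#' @rdname StressScores-class
#' @export
setGeneric("genericScores", function(x) standardGeneric("genericScores"))

#' @rdname StressScores-class
#' @export
setGeneric("zContributions", function(x) standardGeneric("zContributions"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("consensusFeatures", function(x) standardGeneric("consensusFeatures"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("meanCoefficients", function(x) standardGeneric("meanCoefficients"))

#' @rdname StressSignatureSet-class
#' @export
setGeneric("programmes", function(x) standardGeneric("programmes"))
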