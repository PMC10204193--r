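#' Read an expression matrix
#'
#' Tabular input (TSV/CSV) has genes in rows, a header row of sample IDs
#' and gene IDs in the first column. MatrixMarket input (`format =
#' "mtx"`) needs companion files with one gene/cell identifier per line
#' (defaults: `genes.tsv` and `barcodes.tsv` next to the `.mtx` file).
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension
#'   by default.
#' @param logScale whether values are log2 scale (default TRUE).
#' @param genesFile,barcodesFile companion index files for mtx input.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                           logScale = TRUE, genesFile = NULL,
                           barcodesFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopIO("expression file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  if (format == "mtx") {
    if (is.null(genesFile))
      genesFile <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodesFile))
      barcodesFile <- file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genesFile) || !file.exists(barcodesFile))
      stopIO("mtx input needs companion files: ", genesFile, ", ",
             barcodesFile)
    sm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stopIO("cannot parse ", path, ": ",
                                              conditionMessage(e)))
    genes <- readLines(genesFile, warn = FALSE)
    cells <- readLines(barcodesFile, warn = FALSE)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells))
      stopIO("dimension mismatch: matrix is ", nrow(sm), " x ", ncol(sm),
             " but index files list ", length(genes), " genes and ",
             length(cells), " cells")
    m <- as.matrix(sm)
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- tryCatch(
      read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) stopIO("cannot parse ", path, ": ",
                                 conditionMessage(e)))
    if (ncol(tab) < 2L) stopValidation("expression table needs samples")
    genes <- as.character(tab[[1L]])
    if (anyDuplicated(genes))
      stopValidation("duplicate gene identifiers in ", path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
  }
  ExpressionMatrix(m, logScale = logScale)
}

#' Write an expression matrix
#'
#' @param expr [ExpressionMatrix-class] or matrix.
#' @param path output path; `.mtx` output also writes `genes.tsv` and
#'   `barcodes.tsv` alongside.
#' @param format `"tsv"` or `"mtx"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  m <- .exprs(expr)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "mtx") "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = rownames(m),
                      signif(m, 6L), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write score tables
#'
#' Score TSVs have columns `sample`, `score`, `n_up_used`, `n_down_used`.
#'
#' @param x a [G0Scores-class].
#' @param path file path.
#' @return `writeScores` returns `path` invisibly; `readScores` a
#'   [G0Scores-class].
#' @export
writeScores <- function(x, path) {
  tab <- as.data.frame(x)
  tab$score <- signif(tab$score, 6L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @param method method label recorded on read (default `"unknown"`).
#' @export
readScores <- function(path, method = "unknown") {
  if (!file.exists(path)) stopIO("scores file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "score") %in% names(tab)))
    stopValidation("scores file needs 'sample' and 'score' columns")
  G0Scores(setNames(tab$score, tab$sample), method = method,
           nUpUsed = if ("n_up_used" %in% names(tab))
             tab$n_up_used[1L] else NA_integer_,
           nDownUsed = if ("n_down_used" %in% names(tab))
             tab$n_down_used[1L] else NA_integer_)
}

#' Read and write state/subtype label tables
#'
#' @param labels data.frame with a `sample` column plus `state`,
#'   `subtype` or `level`.
#' @param path file path.
#' @export
writeLabels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stopIO("labels file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab))
    stopValidation("labels file needs a 'sample' column")
  tab
}

#' Serialise a consensus linear model as JSON
#'
#' The JSON records features, averaged coefficients, intercept and
#' training feature means; reloading reproduces predictions exactly.
#'
#' @param model a [LinearConsensusModel-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  obj <- list(intercept = model@intercept,
              features = names(model@coefficients),
              coefficients = unname(model@coefficients),
              feature_means = unname(model@featureMeans))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stopIO("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("LinearConsensusModel",
      intercept = as.numeric(obj$intercept),
      coefficients = setNames(as.numeric(obj$coefficients), obj$features),
      featureMeans = setNames(as.numeric(obj$feature_means), obj$features))
}

#' Read a purity table
#'
#' Two-column TSV `sample<TAB>purity` with purity in [0, 1].
#'
#' @param path file path.
#' @return Named numeric vector.
#' @export
readPurity <- function(path) {
  if (!file.exists(path)) stopIO("purity file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "purity") %in% names(tab)))
    stopValidation("purity file needs 'sample' and 'purity' columns")
  p <- setNames(as.numeric(tab$purity), tab$sample)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stopValidation("purity values must lie in [0, 1]")
  p
}
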