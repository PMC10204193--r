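#' Read a gene signature from file
#'
#' Two dialects are supported: a two-column TSV with header
#' `gene<TAB>direction` (direction `up` or `down`), and GMT, where a
#' signature is carried by one or two sets whose names end in `_UP` / `_DN`.
#' Input order is preserved; duplicated gene/direction rows are collapsed.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"gmt"`.
#' @param name signature label; defaults to the file base name (TSV) or the
#'   common set prefix (GMT).
#' @return A [GeneSignature-class].
#' @seealso [writeSignature()], [g0SignatureFile()]
#' @export
readSignature <- function(path, format = c("tsv", "gmt"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopIO("signature file not found: ", path)
  if (format == "tsv") {
    tab <- tryCatch(
      read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                 colClasses = "character"),
      error = function(e) stopIO("cannot parse signature file ", path, ": ",
                                 conditionMessage(e)))
    if (!all(c("gene", "direction") %in% names(tab)))
      stopValidation("signature TSV needs columns 'gene' and 'direction': ",
                     path)
    if (nrow(tab) == 0L)
      stopValidation("empty signature file: ", path)
    bad <- which(!tab$direction %in% c("up", "down") |
                   is.na(tab$gene) | tab$gene == "")
    if (length(bad))
      stopValidation("malformed signature row at line ", bad[1L] + 1L,
                     " of ", path)
    tab <- tab[!duplicated(tab[c("gene", "direction")]), ]
    up <- tab$gene[tab$direction == "up"]
    down <- tab$gene[tab$direction == "down"]
    if (is.null(name))
      name <- sub("\\.[^.]*$", "", basename(path))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stopValidation("empty signature file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    setNames <- vapply(fields, `[`, character(1L), 1L)
    genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    upSets <- grepl("_UP$", setNames)
    dnSets <- grepl("_DN$", setNames)
    if (!any(upSets | dnSets))
      stopValidation("GMT sets must use the _UP/_DN suffix convention: ",
                     path)
    up <- unique(unlist(genes[upSets], use.names = FALSE))
    down <- unique(unlist(genes[dnSets], use.names = FALSE))
    if (is.null(name))
      name <- unique(sub("_(UP|DN)$", "", setNames[upSets | dnSets]))[1L]
  }
  both <- intersect(up, down)
  if (length(both))
    stopValidation("gene(s) listed as both up and down: ",
                   paste(head(both, 5L), collapse = ", "))
  GeneSignature(name, up = up, down = down)
}

#' Write a gene signature to file
#'
#' @param sig a [GeneSignature-class].
#' @param path output path.
#' @param format `"tsv"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(sig, path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(
      gene = c(sig@up, sig@down),
      direction = c(rep("up", length(sig@up)), rep("down", length(sig@down))),
      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(
      paste(c(paste0(sig@name, "_UP"), sig@name, sig@up), collapse = "\t"),
      paste(c(paste0(sig@name, "_DN"), sig@name, sig@down), collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Vendored signature and housekeeping files
#'
#' Paths to the signature files shipped with the package. These are
#' synthetic stand-ins with the published cardinalities (139 genes for the
#' generic G0 signature, 35 for the minimal single-cell signature, and a
#' 30-gene housekeeping list); the gene identifiers are placeholders, not
#' the published membership, and the files are named accordingly. Replace
#' them with curated lists for use on real data.
#'
#' @param which `"generic"` (139 genes), `"minimal"` (35 genes) or
#'   `"housekeeping"`.
#' @return File path.
#' @examples
#' sig <- readSignature(g0SignatureFile("generic"))
#' length(signatureGenes(sig))
#' @export
g0SignatureFile <- function(which = c("generic", "minimal", "housekeeping")) {
  which <- match.arg(which)
  fn <- switch(which,
               generic = "g0_139_synthetic.tsv",
               minimal = "g0_35_synthetic.tsv",
               housekeeping = "housekeeping_synthetic.tsv")
  system.file("extdata", fn, package = "g0kit", mustWork = TRUE)
}

#' Read a housekeeping gene list
#'
#' One gene identifier per line (a header line `gene` is tolerated).
#'
#' @param path file path; defaults to the vendored synthetic list.
#' @return Character vector of gene identifiers.
#' @export
readHousekeeping <- function(path = g0SignatureFile("housekeeping")) {
  if (!file.exists(path)) stopIO("housekeeping file not found: ", path)
  g <- readLines(path, warn = FALSE)
  g <- g[nzchar(g) & g != "gene"]
  if (!length(g)) stopValidation("empty housekeeping list: ", path)
  unique(g)
}

## Check a differential-expression table covers all five quiescence forms.
## Expected columns: gene, then log2fc_<form> and padj_<form> per form.
.checkDETable <- function(de, forms = QUIESCENCE_FORMS) {
  if (!"gene" %in% names(de))
    stopValidation("DE table needs a 'gene' column")
  need <- c(paste0("log2fc_", forms), paste0("padj_", forms))
  miss <- setdiff(need, names(de))
  if (length(miss))
    stopValidation("DE table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(de$gene))
    stopValidation("DE table must have one row per gene")
  padj <- as.matrix(de[paste0("padj_", forms)])
  if (any(padj < 0 | padj > 1, na.rm = TRUE))
    stopValidation("adjusted p-values must lie in [0, 1]")
  invisible(de)
}

## Filter (3): variability / expression-level / DREAM-correlation filter,
## shared between the generic refinement and the stress constructors.
## Returns the surviving subset of `genes`. Genes absent from expr are
## dropped with a warning. Quantile thresholds are computed over all genes
## of the cohort matrix.
.expressionFilters <- function(genes, expr, sdQuantile, exprQuantile,
                               dreamTargets = NULL, dreamAbsCorMin = 0) {
  m <- .exprs(expr)
  if (ncol(m) < 3L)
    stopValidation("expression cohort needs at least 3 samples")
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from the expression cohort ",
            "were excluded: ", paste(head(absent, 5L), collapse = ", "),
            call. = FALSE)
    genes <- setdiff(genes, absent)
  }
  if (!length(genes)) return(character())
  geneSd <- apply(m, 1L, sd)
  geneMean <- rowMeans(m)
  sdCut <- quantile(geneSd, sdQuantile, names = FALSE)
  exprCut <- quantile(geneMean, exprQuantile, names = FALSE)
  keep <- genes[geneSd[genes] >= sdCut & geneMean[genes] >= exprCut]
  if (!is.null(dreamTargets) && dreamAbsCorMin > 0) {
    dt <- intersect(dreamTargets, rownames(m))
    if (!length(dt))
      stopValidation("no DREAM target genes present in the cohort")
    dreamMean <- colMeans(m[dt, , drop = FALSE])
    if (sd(dreamMean) == 0)
      stopValidation("DREAM target mean expression is constant; ",
                     "correlation filter undefined")
    keep <- keep[vapply(keep, function(g) {
      s <- sd(m[g, ])
      s > 0 && abs(cor(m[g, ], dreamMean)) >= dreamAbsCorMin
    }, logical(1L))]
  }
  keep
}

#' Refine a generic G0 arrest signature from differential expression
#'
#' Starting from differential-expression results comparing cycling cells
#' with cells in each of the five forms of quiescence, the generic
#' signature is built by: (0) keeping genes significant (adjusted p below
#' `padjCut`) in all five forms; (1) keeping genes whose log2 fold change
#' has the same sign in all five forms; (2) removing genes on an explicit
#' exclusion list (e.g. cell-cycle stage genes); (3) removing genes with
#' low across-sample standard deviation or low mean expression in a
#' reference cohort (below the given cohort quantiles), and genes whose
#' absolute Pearson correlation with the mean expression of the DREAM
#' complex transcriptional targets falls below `dreamAbsCorMin`. The
#' direction of each surviving gene is its common fold-change sign.
#'
#' @param de data.frame with columns `gene`, and `log2fc_<form>`,
#'   `padj_<form>` for each form in `QUIESCENCE_FORMS`.
#' @param padjCut adjusted p-value cutoff (default 0.05).
#' @param exclusionList genes removed regardless of statistics.
#' @param expr reference expression cohort ([ExpressionMatrix-class] or
#'   matrix, >= 3 samples) used by filter (3).
#' @param dreamTargets DREAM target gene identifiers.
#' @param sdQuantile,exprQuantile cohort quantiles in (0,1) below which a
#'   gene's SD / mean expression counts as "low" (default 0.1).
#' @param dreamAbsCorMin minimum absolute correlation with DREAM-target
#'   mean expression (default 0.3); set to 0 (or `dreamTargets = NULL`)
#'   to disable.
#' @param name label for the resulting signature.
#' @return A [GeneSignature-class].
#' @export
refineSignature <- function(de, padjCut = 0.05, exclusionList = character(),
                            expr = NULL, dreamTargets = NULL,
                            sdQuantile = 0.1, exprQuantile = 0.1,
                            dreamAbsCorMin = 0.3, name = "g0_refined") {
  .checkDETable(de)
  if (any(c(sdQuantile, exprQuantile) <= 0) ||
      any(c(sdQuantile, exprQuantile) >= 1))
    stopValidation("quantile thresholds must lie in (0, 1)")
  padj <- as.matrix(de[paste0("padj_", QUIESCENCE_FORMS)])
  lfc <- as.matrix(de[paste0("log2fc_", QUIESCENCE_FORMS)])
  rownames(padj) <- rownames(lfc) <- de$gene

  ## (0) significant in all five forms
  sig <- de$gene[rowSums(padj < padjCut) == length(QUIESCENCE_FORMS) &
                   complete.cases(padj)]
  ## (1) unidirectional fold change
  uni <- sig[abs(rowSums(sign(lfc[sig, , drop = FALSE]))) ==
               length(QUIESCENCE_FORMS)]
  ## (2) exclusion list
  kept <- setdiff(uni, exclusionList)
  ## (3) variability / expression / DREAM correlation
  if (!is.null(expr))
    kept <- .expressionFilters(kept, expr, sdQuantile, exprQuantile,
                               dreamTargets, dreamAbsCorMin)
  if (!length(kept))
    stopValidation("no genes survive the refinement filters")
  up <- kept[lfc[kept, 1L] > 0]
  down <- kept[lfc[kept, 1L] < 0]
  GeneSignature(name, up = up, down = down)
}

#' Build the five stress-programme signatures
#'
#' For each quiescence form separately: keep genes significant for that
#' form only (adjusted p below `padjCut`), apply the exclusion-list and
#' low-variability/low-expression filters of [refineSignature()] (filters
#' 2 and 3, without the DREAM-correlation step), rank the survivors by
#' absolute log2 fold change, and keep the top 10 genes per direction.
#' Ties in |log2FC| at the boundary are broken by alphabetical gene
#' identifier for determinism.
#'
#' @inheritParams refineSignature
#' @param nPerDirection genes kept per direction (default 10).
#' @return A [StressSignatureSet-class]; every programme signature has
#'   exactly `nPerDirection` up and down genes.
#' @export
buildStressSignatures <- function(de, padjCut = 0.05,
                                  exclusionList = character(), expr = NULL,
                                  sdQuantile = 0.1, exprQuantile = 0.1,
                                  nPerDirection = 10L) {
  .checkDETable(de)
  out <- lapply(QUIESCENCE_FORMS, function(form) {
    padj <- de[[paste0("padj_", form)]]
    lfc <- de[[paste0("log2fc_", form)]]
    names(lfc) <- de$gene
    cand <- de$gene[!is.na(padj) & padj < padjCut]
    cand <- setdiff(cand, exclusionList)
    if (!is.null(expr))
      cand <- .expressionFilters(cand, expr, sdQuantile, exprQuantile)
    pick <- function(genes, direction) {
      if (length(genes) < nPerDirection)
        stopValidation("fewer than ", nPerDirection, " surviving ",
                       direction, " genes for programme '", form, "' (",
                       length(genes), " available)")
      ord <- order(-abs(lfc[genes]), genes)
      genes[ord][seq_len(nPerDirection)]
    }
    GeneSignature(form,
                  up = pick(cand[lfc[cand] > 0], "up"),
                  down = pick(cand[lfc[cand] < 0], "down"))
  })
  names(out) <- QUIESCENCE_FORMS
  StressSignatureSet(out)
}
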