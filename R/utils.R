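## Internal helpers shared across modules.

## Accept either an ExpressionMatrix or a plain named matrix everywhere.
.exprs <- function(x) {
  if (is(x, "ExpressionMatrix")) return(exprValues(x))
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopValidation("expression matrices need gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stopValidation("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(m)))
    stopValidation("duplicate sample identifiers in expression matrix")
  storage.mode(m) <- "double"
  m
}

.isLog <- function(x, default = TRUE) {
  if (is(x, "ExpressionMatrix")) isLogScale(x) else default
}

## Classed conditions so the CLI can map errors to exit codes
## (2 = validation, 3 = I/O).
stopValidation <- function(...) {
  stop(structure(class = c("g0kit_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

stopIO <- function(...) {
  stop(structure(class = c("g0kit_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

## Deterministic fan-out of one user seed into per-component streams.
## Component streams stay independent so sub-simulations are individually
## reproducible; offsets keep the derived seed inside 32-bit range.
.deriveSeed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Remove batch structure by per-batch location-scale standardisation
#'
#' Each gene is centred and variance-scaled within each batch, then mapped
#' to the pooled mean and standard deviation of that gene. This is a
#' deterministic location-scale adjustment (no empirical-Bayes shrinkage
#' of batch parameters); it removes additive and multiplicative batch
#' offsets exactly.
#'
#' @param expr an [ExpressionMatrix-class] or genes x samples matrix.
#' @param batch batch label per sample (length `ncol(expr)`).
#' @return An object of the same kind as `expr`, adjusted.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' adjustBatch(m, rep(c("a", "b"), each = 5))
#' @export
adjustBatch <- function(expr, batch) {
  m <- .exprs(expr)
  batch <- as.character(batch)
  if (length(batch) != ncol(m))
    stopValidation("'batch' must have one label per sample")
  tab <- table(batch)
  if (any(tab < 2L))
    stopValidation("every batch needs at least 2 samples: ",
                   paste(names(tab)[tab < 2L], collapse = ", "))
  pooledMean <- rowMeans(m)
  pooledSd <- apply(m, 1L, sd)
  out <- m
  for (b in names(tab)) {
    idx <- which(batch == b)
    sub <- m[, idx, drop = FALSE]
    bm <- rowMeans(sub)
    bs <- apply(sub, 1L, sd)
    z <- (sub - bm) / ifelse(bs > 0, bs, 1)
    out[, idx] <- z * pooledSd + pooledMean
  }
  if (is(expr, "ExpressionMatrix")) ExpressionMatrix(out, isLogScale(expr))
  else out
}
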