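## Independent brute-force oracles. These deliberately re-derive each
## quantity with explicit loops / enumeration and must never call the
## package implementation they check.

## Combined Z-score by explicit per-gene loops.
oracleCombinedZ <- function(m, up, down) {
  zrow <- function(g) {
    x <- m[g, ]
    s <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  dirScore <- function(genes) {
    genes <- genes[genes %in% rownames(m)]
    genes <- genes[vapply(genes, function(g) sd(m[g, ]) > 0, logical(1))]
    if (!length(genes)) return(rep(0, ncol(m)))
    acc <- rep(0, ncol(m))
    for (g in genes) acc <- acc + zrow(g)
    acc / sqrt(length(genes))
  }
  dirScore(up) - dirScore(down)
}

## Rank score by explicit sorting per sample.
oracleRankScore <- function(m, up, down) {
  up <- up[up %in% rownames(m)]
  down <- down[down %in% rownames(m)]
  n <- nrow(m)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    r <- (rank(m[, j], ties.method = "average") - 1) / (n - 1)
    names(r) <- rownames(m)
    mu <- if (length(up)) mean(r[up]) else 0
    md <- if (length(down)) mean(r[down]) else 0
    out[j] <- mu - md
  }
  names(out) <- colnames(m)
  out
}

## AUC by counting concordant / tied score pairs.
oracleAUCPairs <- function(score, isPos) {
  pos <- score[isPos]
  neg <- score[!isPos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## AUC by trapezoidal integration of an explicit threshold sweep.
oracleAUCTrapezoid <- function(score, isPos) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(score[isPos] >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(score[!isPos] >= t), numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## Exact Shapley values by exhaustive permutation enumeration for a
## linear value function v(S) = b0 + sum_{k in S} c_k x_k +
## sum_{k not in S} c_k mean_k.
oracleShapPermutation <- function(coefs, means, x) {
  p <- length(coefs)
  perms <- .permutations(seq_len(p))
  v <- function(S) sum(coefs[S] * x[S]) + sum(coefs[setdiff(seq_len(p), S)] *
                                                means[setdiff(seq_len(p), S)])
  phi <- numeric(p)
  for (perm in perms) {
    S <- integer()
    for (k in perm) {
      phi[k] <- phi[k] + (v(c(S, k)) - v(S))
      S <- c(S, k)
    }
  }
  phi / length(perms)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

## Small deterministic expression fixture.
toyExpr <- function(nGenes = 10, nSamples = 6, seed = 42,
                    genes = sprintf("g%02d", seq_len(nGenes))) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, mean = 5, sd = 2), nGenes, nSamples,
         dimnames = list(genes, sprintf("s%02d", seq_len(nSamples))))
}

## Stress signature set + matching generic signature for subtype tests.
stressFixture <- function() {
  de <- simulateDETable(25, 25)
  sigs <- buildStressSignatures(de)
  generic <- readSignature(g0SignatureFile("generic"))
  list(de = de, sigs = sigs, generic = generic)
}
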