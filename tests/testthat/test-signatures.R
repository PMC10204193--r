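test_that("vendored signatures load with the published cardinalities", {
  g139 <- readSignature(g0SignatureFile("generic"))
  expect_s4_class(g139, "GeneSignature")
  expect_length(signatureGenes(g139), 139L)
  g35 <- readSignature(g0SignatureFile("minimal"))
  expect_length(signatureGenes(g35), 35L)
  expect_true(all(signatureGenes(g35) %in% signatureGenes(g139)))
  hk <- readHousekeeping()
  expect_gt(length(hk), 0L)
  expect_length(intersect(hk, signatureGenes(g139)), 0L)
})

test_that("signature files round-trip through TSV and GMT", {
  sig <- GeneSignature("toy", up = c("B1", "A2", "C3"), down = c("D4", "E5"))
  for (fmt in c("tsv", "gmt")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeSignature(sig, path, format = fmt)
    back <- readSignature(path, format = fmt, name = "toy")
    expect_identical(upGenes(back), upGenes(sig))   # order preserved
    expect_identical(downGenes(back), downGenes(sig))
  }
})

test_that("malformed signature input is rejected with informative errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tdirection", empty)
  expect_error(readSignature(empty), "empty")

  both <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tdirection", "X\tup", "X\tdown"), both)
  expect_error(readSignature(both), "both up and down")

  badrow <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tdirection", "A\tup", "B\tsideways"), badrow)
  expect_error(readSignature(badrow), "line 3")

  expect_error(GeneSignature("x", up = character(), down = character()),
               "at least one gene")
  expect_error(GeneSignature("x", up = c("A", "A")), "duplicate")
})

## Constructed 20-gene DE table in which each refinement filter removes a
## known disjoint subset, leaving exactly 7 genes (4 up, 3 down):
##   P1-P3  fail the all-forms significance filter
##   U1-U3  fail the unidirectional filter
##   E1-E2  sit on the exclusion list
##   L1     zero variance in the cohort, L2 low mean expression
##   D1-D3  uncorrelated with the DREAM-target mean
##   K1-K4 up, K5-K7 down survive everything
refineFixture <- function() {
  keepUp <- paste0("K", 1:4); keepDown <- paste0("K", 5:7)
  genes <- c(keepUp, keepDown, paste0("P", 1:3), paste0("U", 1:3),
             paste0("E", 1:2), paste0("L", 1:2), paste0("D", 1:3))
  de <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (f in QUIESCENCE_FORMS) {
    lfc <- ifelse(genes %in% keepDown, -1, 1)
    de[[paste0("log2fc_", f)]] <- lfc
    de[[paste0("padj_", f)]] <- 0.001
  }
  de[de$gene == "P1", "padj_spontaneous"] <- 0.5
  de[de$gene == "P2", "padj_mek_inhibition"] <- 0.5
  de[de$gene == "P3", "padj_serum_starvation"] <- 0.06
  de[de$gene %in% paste0("U", 1:3), "log2fc_contact_inhibition"] <- -1

  nS <- 20L
  set.seed(11)
  dreamPattern <- scale(seq_len(nS))[, 1L]
  ## low-SD/low-mean "background" rows keep the cohort's 10th-percentile
  ## cuts well away from the keeper cluster (mean 5, SD ~2)
  mkRow <- function(kind) {
    switch(kind,
      correlated = 5 + 2 * dreamPattern + rnorm(nS, sd = 0.05),
      flat = rep(5, nS),
      lowmean = -10 + 2 * dreamPattern + rnorm(nS, sd = 0.05),
      uncorrelated = 5 + 2 * rep_len(c(1, -1), nS) + rnorm(nS, sd = 0.05),
      background = 2 + 1 * dreamPattern + rnorm(nS, sd = 0.05))
  }
  kinds <- ifelse(genes == "L1", "flat",
           ifelse(genes == "L2", "lowmean",
           ifelse(genes %in% paste0("D", 1:3), "uncorrelated",
                  "correlated")))
  expr <- t(vapply(kinds, mkRow, numeric(nS)))
  rownames(expr) <- genes
  dream <- t(vapply(1:3, function(i) mkRow("correlated"), numeric(nS)))
  rownames(dream) <- paste0("DR", 1:3)
  bg <- t(vapply(1:30, function(i) mkRow("background"), numeric(nS)))
  rownames(bg) <- sprintf("BG%02d", 1:30)
  expr <- rbind(expr, dream, bg)
  colnames(expr) <- sprintf("s%02d", seq_len(nS))
  list(de = de, expr = expr, dreamTargets = paste0("DR", 1:3),
       exclusion = paste0("E", 1:2),
       keepUp = keepUp, keepDown = keepDown)
}

test_that("refinement filters remove exactly the planted subsets", {
  fx <- refineFixture()
  sig <- refineSignature(fx$de, padjCut = 0.05,
                         exclusionList = fx$exclusion, expr = fx$expr,
                         dreamTargets = fx$dreamTargets,
                         sdQuantile = 0.1, exprQuantile = 0.1,
                         dreamAbsCorMin = 0.3)
  expect_setequal(upGenes(sig), fx$keepUp)
  expect_setequal(downGenes(sig), fx$keepDown)

  ## a gene up in 4 forms and down in 1 is removed (U genes)
  expect_false(any(paste0("U", 1:3) %in% signatureGenes(sig)))
  ## exclusion beats statistics (E genes are otherwise perfect)
  expect_false(any(fx$exclusion %in% signatureGenes(sig)))
})

test_that("refinement is idempotent on its own output", {
  fx <- refineFixture()
  sig1 <- refineSignature(fx$de, exclusionList = fx$exclusion,
                          expr = fx$expr, dreamTargets = fx$dreamTargets)
  de2 <- fx$de[fx$de$gene %in% signatureGenes(sig1), ]
  sig2 <- refineSignature(de2, exclusionList = fx$exclusion,
                          expr = fx$expr, dreamTargets = fx$dreamTargets)
  expect_setequal(signatureGenes(sig2), signatureGenes(sig1))
  expect_setequal(upGenes(sig2), upGenes(sig1))
})

test_that("genes absent from the cohort are excluded with a warning", {
  fx <- refineFixture()
  expr <- fx$expr[setdiff(rownames(fx$expr), "K1"), ]
  expect_warning(
    sig <- refineSignature(fx$de, exclusionList = fx$exclusion,
                           expr = expr, dreamTargets = fx$dreamTargets),
    "absent")
  expect_false("K1" %in% signatureGenes(sig))
})

test_that("stress constructor takes the top 10 per direction by |log2FC|", {
  de <- simulateDETable(nUpPerForm = 25, nDownPerForm = 25)
  sigs <- buildStressSignatures(de)
  for (p in QUIESCENCE_FORMS) {
    s <- programmes(sigs)[[p]]
    expect_length(upGenes(s), 10L)
    expect_length(downGenes(s), 10L)
  }
  ## serum starvation up genes carry log2FC 25..1; top 10 are 25..16,
  ## i.e. the genes numbered 01..10 by construction
  ss <- programmes(sigs)$serum_starvation
  expect_setequal(upGenes(ss), sprintf("SERU_UP%02d", 1:10))
  lfc <- setNames(de$log2fc_serum_starvation, de$gene)
  expect_setequal(lfc[upGenes(ss)], 16:25)
})

test_that("stress constructor errors when a direction has < 10 survivors", {
  de <- simulateDETable(nUpPerForm = 25, nDownPerForm = 9)
  expect_error(buildStressSignatures(de), "down genes.*spontaneous|spontaneous.*down")
})

test_that("|log2FC| ties at the cutoff break alphabetically", {
  de <- simulateDETable(nUpPerForm = 25, nDownPerForm = 25)
  ## force genes 10 and 11 of one form to tie; the alphabetically first
  ## of the boundary pair must win
  de$log2fc_spontaneous[de$gene == "SPON_UP11"] <-
    de$log2fc_spontaneous[de$gene == "SPON_UP10"]
  sigs <- buildStressSignatures(de)
  up <- upGenes(programmes(sigs)$spontaneous)
  expect_true("SPON_UP10" %in% up)
  expect_false("SPON_UP11" %in% up)
})
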