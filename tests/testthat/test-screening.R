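# Multilayer gene screens: fold thresholds, branch attribution, filters,
# rankings, overlap and exclusivity.

.mkTable <- function(m0, records = NULL) {
  genomeRateTable(m0 = m0, records = if (is.null(records)) data.frame()
                  else records)
}

test_that("fold screen thresholds: 2.2 x genome median 0.0909 recovers the
           0.20 rapid-evolution cut", {
  set.seed(7)
  bulk <- data.frame(gene = sprintf("g%03d", 1:199),
                     omega = c(rep(0.0909, 100), runif(99, 0, 0.5)))
  bulk$omega[100] <- 0.0909  # median pinned
  res <- foldScreen(.mkTable(bulk), fold = 2.2)
  expect_equal(res$threshold, 2.2 * median(bulk$omega), tolerance = 1e-12)
  expect_setequal(res$genes, bulk$gene[bulk$omega >= res$threshold])
})

test_that("planted construction: fold 1.5 over median 0.10 returns exactly
           the planted passers", {
  genes <- sprintf("g%03d", 1:201)
  om <- rep(0.10, 201)
  planted <- sample(genes, 50)
  om[match(planted, genes)] <- runif(50, 0.151, 0.9)
  res <- foldScreen(.mkTable(data.frame(gene = genes, omega = om)),
                    fold = 1.5)
  expect_setequal(res$genes, planted)
  ## empty candidate subset screens to the empty set
  expect_length(foldScreen(.mkTable(data.frame(gene = genes, omega = om)),
                           fold = 1.5, genes = character())$genes, 0)
  expect_error(foldScreen(.mkTable(data.frame(gene = character(),
                                              omega = numeric())), 1.5),
               "empty")
})

test_that("screens are monotone in their thresholds and ignore row
           order", {
  g <- simulateGenomeRates(300, seed = 12)
  r1 <- foldScreen(g, 1.5)$genes
  r2 <- foldScreen(g, 2.2)$genes
  r3 <- foldScreen(g, 3.5)$genes
  expect_true(all(r2 %in% r1) && all(r3 %in% r2))
  gs <- g
  set.seed(1)
  gs@m0 <- gs@m0[sample(nrow(gs@m0)), ]
  gs@records <- gs@records[sample(nrow(gs@records)), ]
  expect_identical(foldScreen(gs, 1.5)$genes, r1)
})

test_that("criteria traces reconstruct the pass decision", {
  g <- simulateGenomeRates(100, seed = 13)
  res <- foldScreen(g, 1.5, scope = "any_branch")
  recon <- tapply(res$trace$pass, res$trace$gene, all)
  expect_setequal(res$genes, names(recon)[recon])
})

test_that("GT1 sentinels pass any finite threshold; LOWDIV never passes", {
  m0 <- data.frame(gene = c("a", "b", "c"), omega = c(0.05, 0.05, 0.05))
  rec <- data.frame(gene = c("a", "b", "c"),
                    branch = "Dsec",
                    dN = c(0.05, 0, 0.01), dS = c(0.0001, 0, 0.05),
                    omega = c(NA, NA, 0.2),
                    status = c("GT1", "LOWDIV", "VALUE"))
  res <- foldScreen(genomeRateTable(m0 = m0, records = rec), fold = 100,
                    scope = "any_branch")
  expect_identical(res$genes, "a")
})

test_that("per-branch screen reproduces the published per-species
           thresholds and boundary rules", {
  med <- c(Dmur = 0.152, Dspr = 0.164, Dgri = 0.160)
  expect_equal(unname(med * 1.5), c(0.228, 0.246, 0.240))
  rec <- data.frame(gene = c("g1", "g1", "g2", "g3", "g4"),
                    branch = c("Dmur", "Dspr", "Dgri", "Dmur", "Dspr"),
                    dN = 0.1, dS = 0.3,
                    omega = c(0.34, 0.1, 0.2415, 0.33, 0.2),
                    status = "VALUE")
  tab <- genomeRateTable(m0 = data.frame(gene = paste0("g", 1:4),
                                         omega = 0.1), records = rec)
  res <- hawaiianBranchScreen(tab, absoluteCut = 0.33, foldCut = 1.5,
                              perBranchMedians = med)
  ## g1 (0.34 > 0.33) and g3 (0.33 >= 0.228 fold) pass outright, g2 passes
  ## the fold cut exactly (0.2415 >= 0.240), g4 fails both rules
  expect_setequal(res$genes, c("g1", "g2", "g3"))
  ## with the fold rule disabled the absolute cut is strict: 0.33 fails
  resAbs <- hawaiianBranchScreen(tab, absoluteCut = 0.33, foldCut = 100,
                                 perBranchMedians = med)
  expect_setequal(resAbs$genes, "g1")
  expect_error(hawaiianBranchScreen(tab, perBranchMedians = med[1:2]),
               "missing per-branch median")
})

test_that("branch maxima: numeric maxima, GT1 dominance and ties", {
  upd2 <- data.frame(branch = studySpecies,
                     omega = c(NA, 0.4168, 0.0347, 0.0793, 0.1667),
                     status = c("LOWDIV", rep("VALUE", 4)))
  expect_identical(branchMax(upd2), "Dsec")
  gt <- data.frame(branch = c("A", "B"), omega = c(NA, 0.99),
                   status = c("GT1", "VALUE"))
  expect_identical(branchMax(gt), "A")
  tie <- data.frame(branch = c("A", "B", "C"), omega = c(0.5, 0.5, 0.1),
                    status = "VALUE")
  expect_identical(branchMax(tie), c("A", "B"))
  allLow <- data.frame(branch = "A", omega = NA, status = "LOWDIV")
  expect_error(branchMax(allLow), "LOWDIV")
})

test_that("saturation filter separates saturated, informative and
           low-divergence records", {
  rec <- data.frame(gene = paste0("g", 1:4), branch = "Dsim",
                    dN = c(0.2, 1.6, 0.0005, 0.3),
                    dS = c(0.4, 0.3, 0.0004, 1.55))
  out <- saturationFilter(rec)
  expect_identical(out$kept$gene, "g1")
  expect_setequal(out$saturated$gene, c("g2", "g4"))
  expect_identical(out$lowDivergence$gene, "g3")
  ## boundary: dN or dS > 0.001 is required for inclusion
  rec2 <- data.frame(gene = "h", branch = "b", dN = 0.001, dS = 0.001)
  expect_identical(nrow(saturationFilter(rec2)$lowDivergence), 1L)
})

test_that("top-N upregulation ranking is deterministic and
           permutation-invariant", {
  de <- data.frame(
    gene = c("FBgn0052581", "g2", "g3", "g4", "g5", "g6"),
    context = c(rep("soma", 5), "germ"),
    log2FoldChange = c(10.012, 5.2, 5.2, 8.1, -3, 4),
    pValue = c(1e-8, 1e-4, 1e-4, 0.5, 1e-6, 1e-3),
    direction = c("up", "up", "up", "up", "down", "up"))
  top <- rankTopUpregulated(de, "soma", n = 10)
  expect_identical(top[1], "FBgn0052581")   # highest fold change first
  expect_identical(top, c("FBgn0052581", "g2", "g3"))  # g4 fails P, tie by id
  set.seed(4)
  expect_identical(rankTopUpregulated(de[sample(nrow(de)), ], "soma", 10),
                   top)
  expect_identical(rankTopUpregulated(de, "soma", 2),
                   c("FBgn0052581", "g2"))
  expect_error(rankTopUpregulated(de, "larva", 3), "unknown context")
})

test_that("overlap screen intersects bulk lists, single-cell upregulation
           and the rapid-evolution cut", {
  planted <- c("Drip", "CG3713", "MtnA", "vkg", "Col4a1")
  allGenes <- c(planted, sprintf("x%02d", 1:20))
  bulkTop <- list(early = c(planted[1:3], "x01", "x02"),
                  late = c(planted[4:5], "x03"))
  sc <- data.frame(gene = c(planted, "x01", "x04"),
                   context = c("TFa", "TFa", "TFp", "SHm", "TFa", "CC", "GC"),
                   log2FoldChange = 2, pValue = c(rep(0.01, 6), 0.2),
                   direction = "up")
  m0 <- data.frame(gene = allGenes,
                   omega = ifelse(allGenes %in% c(planted, "x04"), 0.3,
                                  0.05))
  res <- overlapScreen(bulkTop, sc, genomeRateTable(m0 = m0))
  expect_setequal(res, planted)   # x01 fails omega, x04 not in bulk lists
  expect_length(overlapScreen(list(a = "y1"), sc,
                              genomeRateTable(m0 = m0)), 0)
  expect_length(overlapScreen(bulkTop, sc, genomeRateTable(m0 = m0),
                              omegaCut = Inf), 0)
})

test_that("exclusive upregulation pools SH and TF subtypes and recovers
           planted counts", {
  pooling <- c(SHa = "SH", SHm = "SH", TFa = "TF", TFp = "TF", CC = "CC",
               GC = "GC")
  de <- data.frame(gene = c("a", "a", "b", "b", "c"),
                   context = c("SHa", "SHm", "SHa", "TFa", "TFp"),
                   log2FoldChange = 1, pValue = 0.01, direction = "up")
  res <- exclusiveUpregulation(de, pooling)
  expect_identical(res$SH, "a")      # b spans SH and TF: excluded
  expect_identical(res$TF, "c")
  ## planted instance sized to the published counts: 8 SH- and 26
  ## TF-exclusive genes among background multi-type genes
  set.seed(9)
  shG <- sprintf("sh%02d", 1:8); tfG <- sprintf("tf%02d", 1:26)
  mk <- function(g, ctxs) data.frame(gene = g, context = ctxs,
                                     log2FoldChange = 1, pValue = 0.01,
                                     direction = "up")
  de2 <- rbind(
    do.call(rbind, lapply(shG, function(g)
      mk(g, sample(c("SHa", "SHm"), sample(1:2, 1))))),
    do.call(rbind, lapply(tfG, function(g)
      mk(g, sample(c("TFa", "TFp"), sample(1:2, 1))))),
    mk("bg1", c("SHa", "CC")), mk("bg2", c("TFa", "GC")),
    mk("bg3", "CC"))
  res2 <- exclusiveUpregulation(de2, pooling)
  expect_length(res2$SH, 8)
  expect_length(res2$TF, 26)
  expect_error(exclusiveUpregulation(de, pooling[1:2]), "does not cover")
})

test_that("differential-expression records are validated", {
  bad <- data.frame(gene = "g", context = "c", log2FoldChange = -2,
                    pValue = 0.01, direction = "up")
  expect_error(deRecords(bad), "inconsistent")
  bad2 <- data.frame(gene = "g", context = "c", log2FoldChange = 2,
                     pValue = 1.01, direction = "up")
  expect_error(deRecords(bad2), "pValue")
})
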