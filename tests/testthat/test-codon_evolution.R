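# Goldman-Yang rate matrix, pruning likelihood and model fits.

test_that("rate matrix structure: zero rows, single-nucleotide moves only,
           transition/nonsynonymous multipliers", {
  freqs <- equalCodonFreqs()
  Q <- buildRateMatrix(2.3, 0.4, freqs)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(sum(freqs * diag(Q)), -1, tolerance = 1e-12)
  codons <- senseCodons()
  ndiff <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  set.seed(1)
  for (k in 1:200) {
    i <- sample(61, 1); j <- sample(61, 1)
    if (i == j) next
    if (ndiff(codons[i], codons[j]) > 1) expect_identical(Q[i, j], 0)
  }
  ## kappa = 1, omega = 1, equal frequencies: all allowed moves equal
  Q1 <- buildRateMatrix(1, 1, freqs, scale = FALSE)
  off <- Q1[row(Q1) != col(Q1)]
  expect_setequal(round(unique(off), 12), round(c(0, 1 / 61), 12))
})

test_that("detailed balance pi_i q_ij = pi_j q_ji holds for random
           parameters", {
  set.seed(42)
  for (r in 1:3) {
    f <- rgamma(61, 2); f <- f / sum(f)
    names(f) <- senseCodons()
    Q <- buildRateMatrix(runif(1, 0.5, 5), runif(1, 0, 2), f)
    flux <- f * Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
  }
})

test_that("transition probability matrices are stochastic for t >= 0", {
  eig <- .ns$.gyEigen(2, 0.3, equalCodonFreqs())
  for (t in c(0, 1e-6, 0.05, 0.5, 3)) {
    P <- .ns$.probMatrix(eig, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
  expect_equal(.ns$.probMatrix(eig, 0), diag(61), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pruning log-likelihood equals exhaustive enumeration on small
           instances", {
  set.seed(5)
  trees <- list(ape::read.tree(text = "(A:0.1,B:0.25);"),
                ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3);"),
                ape::read.tree(text = "(A:0.05,B:0.4,C:0.2);"))
  for (tr in trees) for (nc in c(1, 3)) {
    kappa <- runif(1, 1, 4); omega <- runif(1, 0.05, 1.5)
    aln <- simulateCodonAlignment(tr, nCodons = nc, kappa = kappa,
                                  omega = omega, seed = sample(1e6, 1))
    struct <- .ns$.treeStruct(tr)
    om <- setNames(rep(omega, length(struct$labels)), struct$labels)
    bl <- setNames(struct$blens, struct$labels)
    params <- new("CodonModelParams", kappa = kappa, omegaMap = om,
                  codonFreqs = equalCodonFreqs(), branchLengths = bl)
    expect_equal(logLikelihood(aln, tr, params),
                 bruteForceLogLik(tr, aln, kappa, omega, equalCodonFreqs()),
                 tolerance = 1e-11)
  }
})

test_that("likelihood is invariant to re-rooting under the reversible
           model", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.05);")
  aln <- simulateCodonAlignment(tr, nCodons = 40, kappa = 2, omega = 0.5,
                                seed = 9)
  llFor <- function(tree) {
    struct <- .ns$.treeStruct(tree)
    om <- setNames(rep(0.5, length(struct$labels)), struct$labels)
    bl <- setNames(struct$blens, struct$labels)
    logLikelihood(aln, tree, new("CodonModelParams", kappa = 2,
                                 omegaMap = om,
                                 codonFreqs = equalCodonFreqs(),
                                 branchLengths = bl))
  }
  base <- llFor(ape::unroot(tr))
  for (og in c("A", "C", "D"))
    expect_equal(llFor(ape::root(ape::unroot(tr), outgroup = og,
                                 resolve.root = TRUE)),
                 base, tolerance = 1e-8)
})

test_that("zero branch lengths with identical sequences give the
           stationary-frequency likelihood", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  seqs <- rep(paste0(rep("ATGTTTGGA", 4), collapse = ""), 3)
  aln <- codonAlignment(setNames(seqs, c("A", "B", "C")))
  struct <- .ns$.treeStruct(tr)
  om <- setNames(rep(0.5, length(struct$labels)), struct$labels)
  bl <- setNames(rep(0, length(struct$labels)), struct$labels)
  ll <- logLikelihood(aln, tr, new("CodonModelParams", kappa = 2,
                                   omegaMap = om,
                                   codonFreqs = equalCodonFreqs(),
                                   branchLengths = bl))
  expect_equal(ll, 12 * log(1 / 61), tolerance = 1e-10)
})

test_that("dN/dS decomposition: equals omega, dN = dS at omega 1, zero at
           t = 0", {
  freqs <- equalCodonFreqs()
  set.seed(3)
  for (r in 1:5) {
    w <- runif(1, 0.05, 3); t <- runif(1, 0.01, 1)
    p <- new("CodonModelParams", kappa = runif(1, 1, 5),
             omegaMap = c(b = w), codonFreqs = freqs,
             branchLengths = c(b = t))
    d <- decomposeBranchRates(p, "b")
    expect_equal(unname(d["dN"] / d["dS"]), w, tolerance = 1e-6)
  }
  p1 <- new("CodonModelParams", kappa = 2, omegaMap = c(b = 1),
            codonFreqs = freqs, branchLengths = c(b = 0.3))
  d1 <- decomposeBranchRates(p1, "b")
  expect_equal(unname(d1["dN"]), unname(d1["dS"]), tolerance = 1e-9)
  p0 <- new("CodonModelParams", kappa = 2, omegaMap = c(b = 0.5),
            codonFreqs = freqs, branchLengths = c(b = 0))
  expect_equal(unname(decomposeBranchRates(p0, "b")), c(0, 0))
})

test_that("M0 and free-ratio fits are nested (free-ratio lnL >= M0 lnL) and
           recover simulated parameters on one replicate", {
  tree <- melanogasterTree()
  aln <- simulateCodonAlignment(tree, nCodons = 600, kappa = 2, omega = 0.3,
                                seed = 21)
  m0 <- fitM0(aln, tree)
  fr <- fitFreeRatio(aln, tree)
  expect_gte(fr@logLik, m0@logLik - 1e-6)
  expect_equal(m0@params@omegaMap[[1]], 0.3, tolerance = 0.2)
  expect_equal(m0@params@kappa, 2, tolerance = 0.35)
  expect_identical(m0@convergence, 0L)
})

test_that("free-ratio applies the sentinel conventions: no substitutions ->
           LOWDIV, nonsynonymous-only divergence -> GT1", {
  tree <- ape::read.tree(text = "((A:0.08,B:0.08):0.04,C:0.1,D:0.1);")
  ## plant a zero-length branch
  tree$edge.length[tree$edge[, 2] == which(tree$tip.label == "C")] <- 0
  aln <- simulateCodonAlignment(tree, nCodons = 400, kappa = 2, omega = 0.2,
                                seed = 33)
  fr <- fitFreeRatio(aln, tree)
  br <- fr@branchRates
  expect_identical(br$status[br$branch == "C"], "LOWDIV")
  ## purely nonsynonymous divergence on one tip: dS ~ 0, dN > 0.001 -> GT1
  ## (GGA -> GAA is a nonsynonymous, GGA -> GGG/GGC a synonymous single
  ## change, so the branch-specific substitution classes are unambiguous)
  base <- rep("GGA", 200)
  mk <- function(x) paste0(x, collapse = "")
  A <- base; A[21:35] <- "GAA"
  C <- base; C[1:10] <- "GGG"
  D <- base; D[11:20] <- "GGC"
  aln2 <- codonAlignment(c(A = mk(A), B = mk(base), C = mk(C), D = mk(D)))
  tree2 <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,C:0.05,D:0.05);")
  fr2 <- fitFreeRatio(aln2, tree2)
  br2 <- fr2@branchRates
  expect_identical(br2$status[br2$branch == "A"], "GT1")
  a <- decomposeBranchRates(fr2@params, "A")
  expect_gt(a[["dN"]], 0.001)
  expect_lt(a[["dS"]], 0.001)
})

test_that("an alignment of identical sequences is flagged as
           low-divergence", {
  seqs <- rep(paste0(rep("ATGGCCAAA", 10), collapse = ""), 5)
  names(seqs) <- studySpecies
  aln <- codonAlignment(seqs)
  expect_warning(fit <- fitM0(aln, melanogasterTree()),
                 "low-divergence")
  expect_lt(sum(fit@params@branchLengths), 1e-4)
})

test_that("branch-site LRT: nesting always holds, foreground label is
           validated, strong selection is detected", {
  tree <- melanogasterTree()
  set.seed(8)
  cls <- sample(1:2, 120, replace = TRUE, prob = c(0.7, 0.3))
  aln <- simulateCodonAlignment(tree, nCodons = 120, kappa = 2, seed = 61,
                                siteClasses = cls,
                                classOmega = list(0.2, 1.0))
  expect_error(branchSiteTest(aln, tree, foreground = "Dxxx"), "not found")
  bs <- branchSiteTest(aln, tree, foreground = "Dsec")
  expect_gte(bs@lnLAlt, bs@lnLNull)
  expect_gte(bs@statistic, 0)
  expect_equal(sum(bs@siteClassProps), 1, tolerance = 1e-9)
  ## overwhelming foreground selection on 20% of sites is detected
  cls2 <- sample(1:3, 800, replace = TRUE, prob = c(0.55, 0.25, 0.20))
  om3 <- studyOmegaMap(0.2, Dsec = 10)
  aln2 <- simulateCodonAlignment(tree, nCodons = 800, kappa = 2, seed = 62,
                                 siteClasses = cls2,
                                 classOmega = list(0.2, 1.0, om3))
  bs2 <- branchSiteTest(aln2, tree, foreground = "Dsec")
  expect_lt(bs2@pValue, 0.05)
  expect_gte(bs2@omega2, 1)
})
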