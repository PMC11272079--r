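## Generators for every input the pipeline consumes. Each generator is a
## pure function of its arguments plus an explicit seed, so the same call
## reproduces the same object byte for byte.

#' Five-species melanogaster-subgroup study tree
#'
#' A rooted five-taxon phylogeny with the topology of the melanogaster
#' subgroup (((Dsim,Dsec),Dmel),(Dyak,Dere)). The published analyses do not
#' print maximum-likelihood branch lengths, so the lengths here are synthetic
#' stand-ins on the scale of substitutions per codon typical for this clade;
#' they are used by the simulators and as a default covariance tree.
#'
#' @return An `ape` phylo object with 5 tips.
#' @export
#' @examples
#' plot(melanogasterTree())
melanogasterTree <- function() {
  ape::read.tree(text = paste0(
    "(((Dsim:0.04,Dsec:0.05):0.04,Dmel:0.09):0.05,",
    "(Dyak:0.08,Dere:0.08):0.05);"))
}

#' Ovariole numbers per female for the five study species
#'
#' Mean ovariole counts per female reported for the melanogaster subgroup:
#' D. melanogaster 39.2, D. simulans 33.9, D. sechellia 17.0, D. yakuba 25.8,
#' D. erecta 27.0.
#'
#' @return Named numeric vector.
#' @export
ovarioleNumbers <- function() {
  c(Dsim = 33.9, Dsec = 17.0, Dmel = 39.2, Dyak = 25.8, Dere = 27.0)
}

## Draw child states given parent states and a transition matrix,
## vectorised over the distinct parent states present.
.evolveStates <- function(parentStates, P) {
  out <- integer(length(parentStates))
  for (s in unique(parentStates)) {
    idx <- which(parentStates == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

#' Simulate a codon alignment on a tree under the GY94 model
#'
#' Root codons are drawn from the equilibrium frequencies and evolved along
#' each branch by sampling from the matrix-exponential transition
#' probabilities of the branch's scaled rate matrix. `omega` may be a single
#' value, a named per-branch map (free-ratio simulation), or site classes
#' may be supplied via `siteClasses`/`classOmega` for branch-site data: each
#' codon column belongs to one class, and a class's omega may itself be a
#' per-branch map.
#'
#' @param tree `phylo` with branch lengths (substitutions per codon).
#' @param nCodons Number of codon columns.
#' @param kappa Transition/transversion ratio.
#' @param omega Single value or named per-branch map (ignored when
#'   `siteClasses` is given).
#' @param codonFreqs 61-vector of equilibrium frequencies.
#' @param seed Mandatory integer seed.
#' @param siteClasses Optional integer vector of length `nCodons` assigning
#'   each column to a class `1..K`.
#' @param classOmega Optional list of length `K`; element k is the omega
#'   (single value or per-branch named map) of class k.
#' @param classProps Optional class proportions used for the shared rate
#'   normalisation (defaults to the realised proportions of `siteClasses`).
#'   As in site-mixture codon models, all classes on a branch share one
#'   class-weighted normalising constant, so purifying classes accumulate
#'   proportionally fewer substitutions than neutral or selected classes.
#' @return A [CodonAlignment-class].
#' @export
simulateCodonAlignment <- function(tree, nCodons, kappa = 2, omega = 0.2,
                                   codonFreqs = equalCodonFreqs(), seed,
                                   siteClasses = NULL, classOmega = NULL,
                                   classProps = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  .checkFreqs(codonFreqs)
  struct <- .treeStruct(tree)
  if (is.null(struct$blens)) stop("tree must have branch lengths")
  if (is.null(siteClasses)) {
    siteClasses <- rep(1L, nCodons)
    classOmega <- list(omega)
  } else {
    stopifnot(length(siteClasses) == nCodons, !is.null(classOmega))
  }
  K <- length(classOmega)
  if (is.null(classProps))
    classProps <- tabulate(siteClasses, K) / length(siteClasses)
  fl <- .gyFlux(kappa, codonFreqs)
  tab <- .codonTables()
  nn <- struct$ntip + struct$nnode
  statesAt <- matrix(NA_integer_, nn, nCodons)
  statesAt[struct$root, ] <- sample.int(tab$n, nCodons, replace = TRUE,
                                        prob = codonFreqs)
  omegaAt <- function(wk, lab) {
    if (length(wk) > 1 || !is.null(names(wk)))
      .expandOmega(wk, struct$labels)[[lab]] else wk
  }
  ## per edge (preorder), per class transition matrix; one class-weighted
  ## normalising constant per branch
  for (e in rev(seq_along(struct$child))) {
    p <- struct$parent[e]; ch <- struct$child[e]
    lab <- struct$labels[e]
    ws <- vapply(classOmega, omegaAt, 0, lab = lab)
    cb <- sum(classProps * (ws * fl$A + fl$B))
    for (k in seq_len(K)) {
      cols <- which(siteClasses == k)
      if (!length(cols)) next
      eig <- .gyEigen(kappa, ws[k], codonFreqs, scale = FALSE)
      P <- .probMatrix(eig, struct$blens[e] / cb)
      P <- P / rowSums(P)
      statesAt[ch, cols] <- .evolveStates(statesAt[p, cols], P)
    }
  }
  seqs <- vapply(seq_len(struct$ntip), function(i)
    paste0(tab$codons[statesAt[i, ]], collapse = ""), "")
  codonAlignment(stats::setNames(seqs, struct$tree$tip.label))
}

#' Simulate an RPKM-style expression matrix with controlled specificity
#'
#' Each gene is assigned an expression breadth k (number of conditions with
#' nonzero expression, drawn uniformly from `breadthRange` unless fixed);
#' expressed conditions receive log-normal positive values (or a constant
#' when `noiseSd = 0`), all others zero. The realised tau of a gene with
#' breadth k and equal values is exactly (n - k)/(n - 1).
#'
#' @param nGenes Number of genes.
#' @param nConditions Number of tissue/stage conditions (59 in the reference
#'   compendium).
#' @param breadthRange Integer range from which each gene's breadth is drawn.
#' @param meanLog,noiseSd Log-normal location and sd of expressed values.
#' @param seed Mandatory seed.
#' @return List with `values` (genes x conditions matrix, dimnames set) and
#'   `breadth` (the generating breadth per gene).
#' @export
simulateExpression <- function(nGenes, nConditions = 59,
                               breadthRange = c(1, 59), meanLog = 3,
                               noiseSd = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  br <- if (breadthRange[1] == breadthRange[2]) rep(breadthRange[1], nGenes)
        else sample(seq(breadthRange[1], breadthRange[2]), nGenes,
                    replace = TRUE)
  m <- matrix(0, nGenes, nConditions,
              dimnames = list(sprintf("gene%04d", seq_len(nGenes)),
                              sprintf("cond%02d", seq_len(nConditions))))
  for (i in seq_len(nGenes)) {
    on <- sample.int(nConditions, br[i])
    m[i, on] <- if (noiseSd == 0) exp(meanLog) else
      stats::rlnorm(br[i], meanLog, noiseSd)
  }
  list(values = m, breadth = br)
}

#' Simulate a genome-wide rate table
#'
#' Per-gene M0 omegas are drawn from a right-skewed gamma distribution whose
#' scale is set so the median matches `medianOmega` (0.09 by default, the
#' genome-wide median implied by the published 0.20 = 2.2 x median screening
#' threshold). Per-branch positive-selection flags are drawn independently
#' at the given per-branch frequencies. Per-branch omegas are the gene's M0
#' omega jittered by a gamma multiplier. `planted` genes receive fixed high
#' omegas at known identities so screens can be validated by construction.
#'
#' @param nGenes Number of genes.
#' @param branches Branch (species) labels.
#' @param medianOmega Target genome-wide median M0 omega.
#' @param shape Gamma shape of the omega distribution.
#' @param psFreq Named per-branch positive-selection frequencies (recycled
#'   if a single value).
#' @param planted Optional named numeric of gene -> M0 omega to plant.
#' @param seed Mandatory seed.
#' @return A [GenomeRateTable-class].
#' @export
simulateGenomeRates <- function(nGenes, branches = names(ovarioleNumbers()),
                                medianOmega = 0.09, shape = 1.5,
                                psFreq = 0.12, planted = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  genes <- sprintf("FBgnS%06d", seq_len(nGenes))
  scale <- medianOmega / stats::qgamma(0.5, shape)
  m0 <- stats::rgamma(nGenes, shape, scale = 1) * scale
  if (!is.null(planted)) {
    stopifnot(all(names(planted) %in% genes))
    m0[match(names(planted), genes)] <- planted
  }
  if (is.null(names(psFreq)))
    psFreq <- stats::setNames(rep(psFreq, length(branches)), branches)
  rec <- expand.grid(gene = genes, branch = branches,
                     stringsAsFactors = FALSE)
  mult <- stats::rgamma(nrow(rec), 4, 4)
  omega <- m0[match(rec$gene, genes)] * mult
  dS <- stats::runif(nrow(rec), 0.02, 0.6)
  rec$dN <- omega * dS
  rec$dS <- dS
  rec$omega <- omega
  rec$status <- "VALUE"
  flags <- rec[, c("gene", "branch")]
  flags$selected <- stats::runif(nrow(flags)) < psFreq[flags$branch]
  methods::new("GenomeRateTable",
               m0 = data.frame(gene = genes, omega = m0),
               records = rec, flags = flags)
}

#' Simulate tip phenotypes linear in omega with Brownian-motion residuals
#'
#' y = intercept + slope * x + e, with e multivariate normal of covariance
#' `bmSigma2 * bmCovariance(tree)`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param x Named per-tip predictor (e.g. branch dN/dS).
#' @param intercept,slope Regression parameters.
#' @param bmSigma2 Brownian rate of the residuals (0 gives exact linearity).
#' @param seed Mandatory seed.
#' @return Named numeric phenotype per tip.
#' @export
simulatePhenotypeOnTree <- function(tree, x, intercept, slope, bmSigma2,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  V <- bmCovariance(tree)
  tips <- rownames(V)
  if (!all(tips %in% names(x))) stop("x must be named by tip label")
  mu <- intercept + slope * x[tips]
  if (bmSigma2 == 0) return(mu)
  L <- chol(bmSigma2 * V)
  mu + as.vector(t(L) %*% stats::rnorm(length(tips)))
}
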