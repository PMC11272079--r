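# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, path walking, direct
# formulas) so it stays independent of the implementation it checks.

options(ovarioleEvo.verbose = FALSE)

.ns <- asNamespace("ovarioleEvo")

# Exhaustive codon likelihood: sum over all internal-node state assignments.
bruteForceLogLik <- function(tree, aln, kappa, omega, freqs) {
  struct <- .ns$.treeStruct(tree)
  st <- codonStates(aln)[struct$tree$tip.label, , drop = FALSE]
  eig <- .ns$.gyEigen(kappa, omega, freqs)
  P <- lapply(struct$blens, function(t) .ns$.probMatrix(eig, t))
  ntip <- struct$ntip
  internals <- sort(unique(struct$parent))
  total <- 0
  for (col in seq_len(ncol(st))) {
    s <- st[, col]
    grid <- do.call(expand.grid, rep(list(1:61), length(internals)))
    colLike <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- as.integer(grid[g, ])
      stateOf <- function(node) {
        if (node <= ntip) s[node] else assign[match(node, internals)]
      }
      p <- freqs[stateOf(struct$root)]
      for (e in seq_along(struct$child))
        p <- p * P[[e]][stateOf(struct$parent[e]), stateOf(struct$child[e])]
      colLike <- colLike + p
    }
    total <- total + log(colLike)
  }
  unname(total)
}

# Brute-force Brownian covariance: shared root-to-MRCA path length found by
# walking tip-to-root paths.
bruteForceBM <- function(tree) {
  ntip <- length(tree$tip.label)
  pathToRoot <- function(tip) {
    edges <- integer(0); node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      edges <- c(edges, e); node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(ntip), pathToRoot)
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  V
}

# Symbolic 2-parameter GLS solution, straight from the normal equations.
glsByHand <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  as.numeric(beta)
}

# Fixed five-taxon study labels (terminal branches).
studySpecies <- c("Dsim", "Dsec", "Dmel", "Dyak", "Dere")

# Per-branch omega map covering every branch of the (rooted) study tree.
studyOmegaMap <- function(base = 0.1, ...) {
  om <- stats::setNames(rep(base, 8),
                        c(studySpecies, "node7", "node8", "node9"))
  dots <- c(...)
  om[names(dots)] <- dots
  om
}
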