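## Felsenstein pruning over codon site patterns.
##
## All likelihood computations work on compressed site patterns: a codon
## column is a vector of states (1..61, NA = gap/ambiguity) over the taxa,
## and identical columns are collapsed with multiplicity weights. Partial
## likelihoods are npatterns x 61 matrices so that the per-branch update is a
## single BLAS matrix product. Per-node rescaling guards against underflow.

## Postorder tree bookkeeping. Branches are addressed by their child node:
## tip branches carry the tip label, internal branches "node<child id>".
.treeStruct <- function(tree, taxaNames = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  if (!is.null(taxaNames)) {
    missing <- setdiff(tr$tip.label, taxaNames)
    if (length(missing))
      stop("tree tips absent from alignment: ", paste(missing, collapse = ", "))
  }
  parent <- tr$edge[, 1]
  child <- tr$edge[, 2]
  root <- setdiff(parent, child)[1]
  labels <- ifelse(child <= ntip, tr$tip.label[child], paste0("node", child))
  childrenOf <- split(seq_along(child), parent)   # edge indices per parent
  list(tree = tr, ntip = ntip, nnode = tr$Nnode, parent = parent,
       child = child, root = root, labels = labels,
       edgeOf = stats::setNames(seq_along(child), child),
       childrenOf = childrenOf,
       blens = if (is.null(tr$edge.length)) NULL else tr$edge.length)
}

## Compress codon columns into unique site patterns.
.sitePatterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = sum(first))),
       map = map)
}

## Rescale a partial-likelihood matrix, returning the matrix and the log of
## the per-pattern scaling factors removed. For small trees (few taxa) the
## partial products cannot underflow a double and rescaling is skipped.
.maybeRescale <- function(m, fast) {
  if (fast) return(list(m = m, ls = 0))
  .rescale(m)
}

.rescale <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx[mx <= 0] <- 1
  list(m = m / mx, ls = log(mx))
}

## Contribution of one edge to its parent: an npat x 61 matrix whose (pat, i)
## entry is P(data below child | parent state i). For a tip child this is a
## row-indexing of t(P) (with an all-ones row for missing codons).
.tipContrib <- function(P, tipStates) {
  Pt <- rbind(t(P), rep(1, ncol(P)))
  idx <- tipStates
  idx[is.na(idx)] <- nrow(Pt)
  Pt[idx, , drop = FALSE]
}

## Full pruning pass. Plist: one 61x61 transition matrix per edge (postorder
## order of struct). states: ntip x npat integer matrix (rows follow
## tree$tip.label order). Returns per-pattern log-likelihood.
.pruneLL <- function(struct, Plist, states, rootFreq) {
  npat <- ncol(states)
  fast <- struct$ntip <= 12
  partial <- vector("list", struct$ntip + struct$nnode)
  lsOf <- vector("list", struct$ntip + struct$nnode)
  for (node in unique(struct$parent)) {   # postorder guarantees children first
    acc <- NULL; ls <- 0
    for (e in struct$childrenOf[[as.character(node)]]) {
      ch <- struct$child[e]
      if (ch <= struct$ntip) {
        contrib <- .tipContrib(Plist[[e]], states[ch, ])
      } else {
        contrib <- partial[[ch]] %*% t(Plist[[e]])
        ls <- ls + lsOf[[ch]]
      }
      acc <- if (is.null(acc)) contrib else acc * contrib
    }
    sc <- .maybeRescale(acc, fast)
    partial[[node]] <- sc$m
    lsOf[[node]] <- ls + sc$ls
  }
  like <- as.vector(partial[[struct$root]] %*% rootFreq)
  log(like) + lsOf[[struct$root]]
}

## Edge context for edge-local likelihood evaluation: for every edge e with
## child c and parent p, D[[e]] is P(data outside subtree(c) | state at p)
## (an npat x 61 matrix, log-scalers in lsD[[e]]) and does not depend on the
## transition matrix of e itself; up[[e]] is the partial of c (NULL for
## tips). The total likelihood through edge e is
##   sum_i pi_i D[pat,i] (P_e up_c)[pat,i].
.edgeContext <- function(struct, Plist, states, rootFreq) {
  npat <- ncol(states)
  fast <- struct$ntip <= 12
  nn <- struct$ntip + struct$nnode
  partial <- vector("list", nn); lsOf <- vector("list", nn)
  contrib <- vector("list", length(struct$child))
  lsContrib <- vector("list", length(struct$child))
  for (node in unique(struct$parent)) {
    acc <- NULL; ls <- 0
    for (e in struct$childrenOf[[as.character(node)]]) {
      ch <- struct$child[e]
      if (ch <= struct$ntip) {
        contrib[[e]] <- .tipContrib(Plist[[e]], states[ch, ])
        lsContrib[[e]] <- rep(0, npat)
      } else {
        contrib[[e]] <- partial[[ch]] %*% t(Plist[[e]])
        lsContrib[[e]] <- lsOf[[ch]]
      }
      acc <- if (is.null(acc)) contrib[[e]] else acc * contrib[[e]]
      ls <- ls + lsContrib[[e]]
    }
    sc <- .maybeRescale(acc, fast)
    partial[[node]] <- sc$m
    lsOf[[node]] <- ls + sc$ls
  }
  ## preorder sweep for the complements
  down <- vector("list", nn); lsDown <- vector("list", nn)
  down[[struct$root]] <- matrix(1, npat, 61)
  lsDown[[struct$root]] <- rep(0, npat)
  D <- vector("list", length(struct$child))
  lsD <- vector("list", length(struct$child))
  for (e in rev(seq_along(struct$child))) {   # reverse postorder = preorder
    p <- struct$parent[e]; ch <- struct$child[e]
    sibs <- setdiff(struct$childrenOf[[as.character(p)]], e)
    acc <- down[[p]]; ls <- lsDown[[p]]
    for (s in sibs) {
      acc <- acc * contrib[[s]]
      ls <- ls + lsContrib[[s]]
    }
    sc <- .maybeRescale(acc, fast)
    D[[e]] <- sc$m; lsD[[e]] <- ls + sc$ls
    if (ch > struct$ntip) {
      ## reversibility: P(state x at p | y at c) = P_e[y, x], so the
      ## complement conditioned on the child state is D %*% t(P).
      dn <- .maybeRescale(D[[e]] %*% t(Plist[[e]]), fast)
      down[[ch]] <- dn$m
      lsDown[[ch]] <- lsD[[e]] + dn$ls
    }
  }
  list(partial = partial, lsOf = lsOf, D = D, lsD = lsD,
       contrib = contrib, lsContrib = lsContrib)
}

## Per-pattern log-likelihood evaluated through edge e with a trial
## transition matrix P (everything else fixed in ctx).
.edgeLL <- function(struct, ctx, e, P, states, rootFreq) {
  ch <- struct$child[e]
  if (ch <= struct$ntip) {
    contrib <- .tipContrib(P, states[ch, ])
    lsUp <- 0
  } else {
    contrib <- ctx$partial[[ch]] %*% t(P)
    lsUp <- ctx$lsOf[[ch]]
  }
  v <- as.vector((ctx$D[[e]] * contrib) %*% rootFreq)
  log(v) + ctx$lsD[[e]] + lsUp
}

## Like .edgeContext but computes the complement D only for one target
## edge: the up pass is full, the down pass only follows the path from the
## root to the target edge's parent.
.edgeContextFor <- function(struct, Plist, states, rootFreq, target) {
  npat <- ncol(states)
  fast <- struct$ntip <= 12
  nn <- struct$ntip + struct$nnode
  partial <- vector("list", nn); lsOf <- vector("list", nn)
  contrib <- vector("list", length(struct$child))
  lsContrib <- vector("list", length(struct$child))
  for (node in unique(struct$parent)) {
    acc <- NULL; ls <- 0
    for (e in struct$childrenOf[[as.character(node)]]) {
      ch <- struct$child[e]
      if (ch <= struct$ntip) {
        contrib[[e]] <- .tipContrib(Plist[[e]], states[ch, ])
        lsContrib[[e]] <- rep(0, npat)
      } else {
        contrib[[e]] <- partial[[ch]] %*% t(Plist[[e]])
        lsContrib[[e]] <- lsOf[[ch]]
      }
      acc <- if (is.null(acc)) contrib[[e]] else acc * contrib[[e]]
      ls <- ls + lsContrib[[e]]
    }
    sc <- .maybeRescale(acc, fast)
    partial[[node]] <- sc$m
    lsOf[[node]] <- ls + sc$ls
  }
  ## path of edges from the root down to the target edge
  path <- integer(0); e <- target
  repeat {
    path <- c(e, path)
    p <- struct$parent[e]
    if (p == struct$root) break
    e <- struct$edgeOf[[as.character(p)]]
  }
  down <- matrix(1, npat, 61); lsDown <- rep(0, npat)
  D <- NULL; lsD <- NULL
  for (e in path) {
    p <- struct$parent[e]
    acc <- down; ls <- lsDown
    for (s in setdiff(struct$childrenOf[[as.character(p)]], e)) {
      acc <- acc * contrib[[s]]
      ls <- ls + lsContrib[[s]]
    }
    sc <- .maybeRescale(acc, fast)
    D <- sc$m; lsD <- ls + sc$ls
    if (e != target) {
      dn <- .maybeRescale(D %*% t(Plist[[e]]), fast)
      down <- dn$m
      lsDown <- lsD + dn$ls
    }
  }
  Dl <- vector("list", length(struct$child))
  lsDl <- vector("list", length(struct$child))
  Dl[[target]] <- D; lsDl[[target]] <- lsD
  list(partial = partial, lsOf = lsOf, D = Dl, lsD = lsDl)
}

#' Codon-model log-likelihood of an alignment on a tree
#'
#' Sum over codon columns of the log pruning likelihood under the
#' Goldman-Yang model, with transition probabilities obtained by matrix
#' exponential of each branch's scaled rate matrix. The model is reversible,
#' so the value is invariant to the (arbitrary) rooting of the tree.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree An `ape` phylo tree whose tip labels are a subset of the
#'   alignment's taxa. Branch lengths are taken from `params`.
#' @param params A [CodonModelParams-class]; `omegaMap` may name a single
#'   shared value (recycled) or one value per branch label.
#' @return The log-likelihood (numeric scalar).
#' @export
logLikelihood <- function(aln, tree, params) {
  stopifnot(methods::is(aln, "CodonAlignment"),
            methods::is(params, "CodonModelParams"))
  struct <- .treeStruct(tree, taxa(aln))
  st <- codonStates(aln)[struct$tree$tip.label, , drop = FALSE]
  pat <- .sitePatterns(st)
  om <- .expandOmega(params@omegaMap, struct$labels)
  bl <- .expandBranch(params@branchLengths, struct$labels)
  Plist <- .plistFor(struct, params@kappa, om, bl, params@codonFreqs)
  sum(pat$weights *
        .pruneLL(struct, Plist, pat$states, params@codonFreqs))
}

.expandOmega <- function(omegaMap, labels) {
  if (length(omegaMap) == 1 && is.null(names(omegaMap)))
    return(stats::setNames(rep(omegaMap, length(labels)), labels))
  if (!all(labels %in% names(omegaMap)))
    stop("omegaMap missing branches: ",
         paste(setdiff(labels, names(omegaMap)), collapse = ", "))
  omegaMap[labels]
}

.expandBranch <- function(bl, labels) {
  if (length(bl) == 1 && is.null(names(bl)))
    return(stats::setNames(rep(bl, length(labels)), labels))
  if (!all(labels %in% names(bl)))
    stop("branchLengths missing branches: ",
         paste(setdiff(labels, names(bl)), collapse = ", "))
  bl[labels]
}

## Transition matrices for all edges given per-branch omega/branch length.
.plistFor <- function(struct, kappa, omegaByLabel, blByLabel, freqs) {
  eigCache <- list()
  lapply(seq_along(struct$child), function(e) {
    lab <- struct$labels[e]
    key <- format(omegaByLabel[[lab]], digits = 15)
    if (is.null(eigCache[[key]]))
      eigCache[[key]] <<- .gyEigen(kappa, omegaByLabel[[lab]], freqs)
    .probMatrix(eigCache[[key]], blByLabel[[lab]])
  })
}
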