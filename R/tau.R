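## Expression specificity (tau) and cell-type profile clustering.

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / max(x)) / (n - 1) over n conditions, computed on
#' the raw expression values exactly as printed (no log transform by
#' default; an optional log2(x + 1) pre-transform can be enabled). tau is 1
#' for single-condition expression, 0 for perfectly uniform expression, and
#' is invariant to positive rescaling of the vector.
#'
#' @param x Nonnegative expression vector over n >= 2 conditions, or a
#'   genes x conditions matrix (tau computed per row; genes whose maximum is
#'   zero are dropped with a logged count).
#' @param log2Transform Apply log2(x + 1) first (off by default).
#' @return Numeric tau in `[0, 1]` (vector input) or a named vector (matrix
#'   input).
#' @export
#' @examples
#' computeTau(c(10, 0, 0, 0))                 # 1: fully specific
#' computeTau(rep(5, 59))                     # 0: uniform
computeTau <- function(x, log2Transform = FALSE) {
  if (is.matrix(x)) {
    mx <- apply(x, 1, max)
    drop <- mx <= 0
    if (any(drop))
      .logStage("tau", nrow(x), sum(!drop), dropped_all_zero = sum(drop))
    return(vapply(which(!drop), function(i)
      computeTau(x[i, ], log2Transform), 0))
  }
  if (length(x) < 2) stop("tau requires at least 2 conditions")
  if (any(x < 0)) stop("negative expression value")
  if (log2Transform) x <- log2(x + 1)
  mx <- max(x)
  if (mx <= 0) stop("tau undefined for an all-zero expression vector")
  sum(1 - x / mx) / (length(x) - 1)
}

#' Classify a tau value as highly specific or broad
#'
#' Genes with tau strictly above the cutoff (0.90 by published convention)
#' are called highly specific.
#'
#' @param tau Numeric in `[0, 1]`.
#' @param cutoff Specificity threshold (strict inequality).
#' @return Character vector in `c("highly_specific", "broad")`.
#' @export
classifySpecific <- function(tau, cutoff = 0.90) {
  if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]")
  ifelse(tau > cutoff, "highly_specific", "broad")
}

#' Standardize expression per gene
#'
#' Subtracts the mean and divides by the standard deviation across
#' conditions, per gene. Zero-variance genes cannot be standardized and are
#' dropped with a logged count.
#'
#' @param values Genes x conditions numeric matrix.
#' @return Standardized matrix (possibly fewer rows).
#' @export
standardizeExpression <- function(values) {
  sds <- apply(values, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  .logStage("standardize", nrow(values), sum(keep),
            dropped_constant = sum(!keep))
  t(scale(t(values[keep, , drop = FALSE])))[, , drop = FALSE]
}

#' Average-linkage hierarchical clustering of condition profiles
#'
#' Clusters the condition (cell-type) columns of an average standardized
#' expression matrix by agglomerative average linkage (UPGMA-style merging),
#' the procedure used to group larval-ovary cell types by transcriptome
#' similarity. The distance is Euclidean on the standardized profiles by
#' default, with a correlation-distance option. Ties are broken
#' deterministically by lexicographic label order.
#'
#' @param values Genes x conditions matrix (already standardized, or raw with
#'   `standardize = TRUE`).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param standardize Standardize genes first?
#' @return List with `hclust` (the stats::hclust tree) and `newick` (the
#'   dendrogram as a newick string with condition labels and merge heights).
#' @export
clusterConditions <- function(values, distance = c("euclidean",
                                                   "correlation"),
                              standardize = FALSE) {
  distance <- match.arg(distance)
  if (ncol(values) < 3) stop("clustering requires at least 3 conditions")
  if (standardize) values <- standardizeExpression(values)
  values <- values[, order(colnames(values)), drop = FALSE]  # fixed tie-break
  d <- if (distance == "euclidean") stats::dist(t(values))
       else stats::as.dist(1 - stats::cor(values))
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}
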