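## Phylogenetic generalized least squares of a tip phenotype on per-branch
## dN/dS under Brownian-motion covariance, with the sentinel-imputation
## conventions of the published prediction tables.

#' Brownian-motion tip covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds each tip's root-to-tip depth. Requires a rooted tree with
#' branch lengths (unrooted input must be rooted explicitly first).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return Symmetric positive semi-definite matrix with tip dimnames.
#' @export
#' @examples
#' bmCovariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
bmCovariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  if (!ape::is.rooted(tree)) {
    ## a pure star is unambiguous (the hub is the root); any other
    ## unrooted tree has an arbitrary basal trifurcation whose placement
    ## changes the covariance, so it must be rooted explicitly
    basalKids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
    if (any(basalKids > ntip))
      stop("tree must be rooted for a Brownian covariance; ",
           "root it explicitly")
  }
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  depth <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge))))   # preorder
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + tr$edge.length[e]
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  mrca <- ape::mrca(tree)
  for (i in seq_len(ntip)) for (j in i:ntip) {
    a <- if (i == j) i else mrca[i, j]
    V[i, j] <- V[j, i] <- depth[a]
  }
  diag(V) <- depth[seq_len(ntip)]
  V
}

#' Impute sentinel omega values for regression
#'
#' Replaces GT1 sentinel branches (dN/dS > 1, dS ~ 0) by `gt1Value` and
#' LOWDIV branches (no measurable divergence) by `lowdivValue`. The defaults
#' (1.5 and 0) are the values that exactly reproduce the published
#' prediction tables from the printed intercepts and slopes, verified across
#' every affected row; both are configurable and the substitution is logged.
#' Genes with GT1 sentinels on `excludeGT1AtLeast` or more branches are
#' considered untestable (near-zero dS in several branches) and rejected.
#'
#' @param records One gene's branch records (columns `branch`, `omega`,
#'   `status`), one row per tip branch.
#' @param gt1Value Imputed omega for GT1 branches (default 1.5).
#' @param lowdivValue Imputed omega for LOWDIV branches (default 0).
#' @param excludeGT1AtLeast Reject genes with at least this many GT1
#'   branches (default 2).
#' @return Named numeric omega per branch.
#' @export
imputeSentinels <- function(records, gt1Value = 1.5, lowdivValue = 0,
                            excludeGT1AtLeast = 2) {
  stopifnot(all(c("branch", "omega", "status") %in% names(records)))
  if (anyDuplicated(records$branch)) stop("one record per branch required")
  nGT1 <- sum(records$status == "GT1")
  if (nGT1 >= excludeGT1AtLeast)
    stop("gene untestable: dN/dS diverges (GT1) in ", nGT1, " branches")
  x <- ifelse(records$status == "GT1", gt1Value,
              ifelse(records$status == "LOWDIV", lowdivValue,
                     records$omega))
  if (nGT1 || any(records$status == "LOWDIV"))
    .logStage("imputeSentinels", nrow(records), nrow(records),
              GT1 = nGT1, LOWDIV = sum(records$status == "LOWDIV"))
  stats::setNames(as.numeric(x), records$branch)
}

#' Phylogenetic generalized least squares fit
#'
#' Generalized least squares of the tip phenotype y on the per-tip predictor
#' x with design (1, x) and error covariance proportional to the
#' Brownian-motion matrix V: beta = (X' V^-1 X)^-1 X' V^-1 y. The slope
#' P-value is a two-sided t test at n - 2 degrees of freedom (df = 3 for
#' the five-species clade). With a star phylogeny of equal depths the fit
#' reduces exactly to ordinary least squares.
#'
#' @param y Named numeric phenotype per tip.
#' @param x Named numeric predictor per tip (e.g. imputed branch dN/dS).
#' @param vcv Tip covariance matrix (e.g. from [bmCovariance]); its
#'   dimnames fix the species order.
#' @return A [PGLSFit-class].
#' @export
pglsFit <- function(y, x, vcv) {
  tips <- rownames(vcv)
  if (is.null(tips)) stop("vcv needs tip dimnames")
  if (!all(tips %in% names(y)) || !all(tips %in% names(x)))
    stop("y and x must be named by the vcv tips")
  n <- length(tips)
  if (n < 3) stop("at least 3 tips required")
  y <- y[tips]; x <- x[tips]
  X <- cbind(intercept = 1, slope = x)
  Vi <- tryCatch(solve(vcv), error = function(e)
    stop("singular covariance matrix: ", conditionMessage(e)))
  XtVi <- t(X) %*% Vi
  A <- XtVi %*% X
  beta <- solve(A, XtVi %*% y)
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
  covb <- sigma2 * solve(A)
  se <- sqrt(diag(covb))
  tval <- as.numeric(beta[2] / se[2])
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  methods::new("PGLSFit",
               coefficients = stats::setNames(as.numeric(beta),
                                              c("intercept", "slope")),
               se = stats::setNames(as.numeric(se), c("intercept", "slope")),
               slopeP = pval, sigma2 = sigma2, vcv = vcv,
               tips = tips, x = as.numeric(x), y = as.numeric(y))
}

#' Predict phenotype from dN/dS under a PGLS fit
#'
#' yhat = intercept + slope * x. `digits = 2` reproduces the display
#' convention of the published prediction tables; use `digits = NULL` for
#' unrounded values.
#'
#' @param fit A [PGLSFit-class], or a list/vector with `intercept` and
#'   `slope` (so published coefficients can be used directly).
#' @param x Numeric omega values (optionally named by species).
#' @param digits Rounding for display (default 2); NULL to disable.
#' @return Numeric predictions, names preserved.
#' @export
pglsPredict <- function(fit, x, digits = 2) {
  cf <- if (methods::is(fit, "PGLSFit")) fit@coefficients
        else unlist(fit)[c("intercept", "slope")]
  yhat <- cf[["intercept"]] + cf[["slope"]] * x
  if (!is.null(digits)) yhat <- round(yhat, digits)
  yhat
}

setMethod("show", "PGLSFit", function(object) {
  cf <- object@coefficients
  cat("PGLS fit (Brownian-motion covariance,", length(object@tips),
      "tips)\n")
  cat(sprintf("  intercept = %.4f  slope = %.4f (se %.4f)  slope P = %.4g\n",
              cf[1], cf[2], object@se[2], object@slopeP))
})
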