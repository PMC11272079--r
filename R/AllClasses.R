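#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats optim optimize pchisq pt qt rgamma rlnorm rnorm runif
#'   setNames median quantile sd hclust dist as.dist complete.cases
NULL

#' In-frame codon alignment
#'
#' An aligned set of protein-coding sequences over the 61 sense codons, one
#' row per taxon. Sequences are stored as a [Biostrings::DNAStringSet];
#' validity enforces equal lengths divisible by three, unique taxon names and
#' the absence of stop codons under the declared genetic code. Gap or
#' ambiguous codons are permitted and treated as missing data by the
#' likelihood machinery.
#'
#' @slot sequences A `DNAStringSet`, one entry per taxon.
#' @slot code Genetic-code identifier (only `"universal"`).
#' @export
setClass("CodonAlignment",
  slots = c(sequences = "DNAStringSet", code = "character"))

setValidity("CodonAlignment", function(object) {
  s <- object@sequences
  nm <- names(s)
  if (length(s) == 0) return("alignment has no sequences")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    return("taxon names must be present and unique")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1)
    return("ragged alignment: sequences differ in length")
  if (w[1] %% 3 != 0)
    return("alignment length is not divisible by 3")
  if (!identical(object@code, "universal"))
    return("only the universal genetic code is supported")
  stops <- .codonTables(object@code)$stops
  chars <- as.matrix(s)
  nc <- w[1] %/% 3
  for (i in seq_len(nc)) {
    cod <- paste0(chars[, 3 * i - 2], chars[, 3 * i - 1], chars[, 3 * i])
    bad <- which(cod %in% stops)
    if (length(bad))
      return(sprintf("stop codon %s in taxon '%s' at codon %d",
                     cod[bad[1]], nm[bad[1]], i))
  }
  TRUE
})

#' Parameters of a fitted codon substitution model
#'
#' @slot kappa Transition/transversion rate ratio.
#' @slot omegaMap Named numeric, dN/dS per branch label (a single shared value
#'   is repeated over branches for M0).
#' @slot codonFreqs Equilibrium frequencies over the 61 sense codons.
#' @slot branchLengths Named numeric, expected substitutions per codon per
#'   branch.
#' @export
setClass("CodonModelParams",
  slots = c(kappa = "numeric", omegaMap = "numeric",
            codonFreqs = "numeric", branchLengths = "numeric"))

setValidity("CodonModelParams", function(object) {
  if (object@kappa <= 0) return("kappa must be > 0")
  if (any(object@omegaMap < 0)) return("omega must be >= 0")
  if (any(object@branchLengths < 0)) return("branch lengths must be >= 0")
  ok <- try(.checkFreqs(object@codonFreqs), silent = TRUE)
  if (inherits(ok, "try-error")) return("invalid codon frequencies")
  TRUE
})

#' Fitted codon model (M0 or free-ratio)
#'
#' @slot params A [CodonModelParams-class].
#' @slot logLik Maximised log-likelihood.
#' @slot tree The `phylo` tree used (branch lengths as fitted).
#' @slot model `"M0"` or `"free-ratio"`.
#' @slot branchRates For free-ratio fits, a data.frame with one row per
#'   branch: label, dN, dS, numeric omega, and the sentinel status
#'   (`VALUE`/`GT1`/`LOWDIV`).
#' @slot convergence Integer optimizer code (0 = converged).
#' @export
setClass("CodonModelFit",
  slots = c(params = "CodonModelParams", logLik = "numeric",
            tree = "ANY", model = "character",
            branchRates = "data.frame", convergence = "integer"))

#' Branch-site model A fit and likelihood ratio test
#'
#' @slot lnLAlt Log-likelihood of model A (foreground omega2 free, >= 1).
#' @slot lnLNull Log-likelihood of the null (omega2 fixed at 1).
#' @slot siteClassProps Proportions of site classes 0, 1, 2a, 2b under the
#'   alternative.
#' @slot omega0 Purifying-class omega (0 < omega0 < 1).
#' @slot omega2 Foreground selected-class omega (>= 1).
#' @slot statistic 2 * (lnLAlt - lnLNull), clamped at zero.
#' @slot pValue Upper chi-squared(1 df) tail probability of the statistic.
#' @slot foreground Foreground branch label.
#' @export
setClass("BranchSiteFit",
  slots = c(lnLAlt = "numeric", lnLNull = "numeric",
            siteClassProps = "numeric", omega0 = "numeric",
            omega2 = "numeric", statistic = "numeric", pValue = "numeric",
            foreground = "character"))

setValidity("BranchSiteFit", function(object) {
  tol <- 1e-6
  if (object@lnLAlt < object@lnLNull - 1e-4)
    return("alternative log-likelihood below null beyond tolerance")
  if (abs(sum(object@siteClassProps) - 1) > tol)
    return("site-class proportions must sum to 1")
  if (object@statistic < 0) return("LRT statistic must be clamped at 0")
  TRUE
})

#' Genome-wide per-gene, per-branch rate table
#'
#' Container for a genome-scale collection of M0 dN/dS values, per-branch
#' free-ratio records with the table sentinel conventions, and per-branch
#' positive-selection flags.
#'
#' @slot m0 data.frame with columns `gene`, `omega` (one row per gene).
#' @slot records data.frame with columns `gene`, `branch`, `dN`, `dS`,
#'   `omega` (numeric, NA for sentinels) and `status` in
#'   `c("VALUE","GT1","LOWDIV")`.
#' @slot flags data.frame with columns `gene`, `branch`, `selected` (logical
#'   branch-site positive-selection calls at P < 0.05).
#' @export
setClass("GenomeRateTable",
  slots = c(m0 = "data.frame", records = "data.frame", flags = "data.frame"))

setValidity("GenomeRateTable", function(object) {
  if (nrow(object@m0) && anyDuplicated(object@m0$gene))
    return("one M0 omega per gene required")
  need <- c("gene", "branch", "dN", "dS", "omega", "status")
  if (nrow(object@records) && !all(need %in% names(object@records)))
    return("records must have columns gene, branch, dN, dS, omega, status")
  if (nrow(object@records)) {
    bad <- !object@records$status %in% c("VALUE", "GT1", "LOWDIV")
    if (any(bad)) return("unknown sentinel status in records")
    v <- object@records$status == "VALUE"
    if (any(v & (!is.finite(object@records$omega) | object@records$omega < 0)))
      return("VALUE records need finite nonnegative omega")
  }
  if (nrow(object@flags) && !is.logical(object@flags$selected))
    return("flags$selected must be logical")
  TRUE
})

#' Phylogenetic generalized least squares fit
#'
#' @slot coefficients Named numeric: intercept and slope.
#' @slot se Standard errors of the coefficients.
#' @slot slopeP Two-sided t-test P-value for the slope at n - 2 df.
#' @slot sigma2 Estimated residual rate parameter.
#' @slot vcv Tip covariance matrix used for the fit.
#' @slot tips Species order of the covariance matrix.
#' @slot x Predictor (per-tip dN/dS) used for the fit.
#' @slot y Response (per-tip phenotype) used for the fit.
#' @export
setClass("PGLSFit",
  slots = c(coefficients = "numeric", se = "numeric", slopeP = "numeric",
            sigma2 = "numeric", vcv = "matrix", tips = "character",
            x = "numeric", y = "numeric"))

setValidity("PGLSFit", function(object) {
  V <- object@vcv
  if (!isSymmetric(unname(V), tol = 1e-8))
    return("vcv must be symmetric")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    return("vcv must be positive semi-definite")
  TRUE
})
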