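## Bundled reference tables: the per-branch dN/dS values, M0/tau summaries
## and PGLS coefficients reported for the 42 candidate ovariole-related
## genes of the melanogaster subgroup. These are *inputs* to the package
## (screening examples, sentinel handling, prediction reproduction); the
## package never claims to recompute them from sequence data, which would
## require the original genome-wide alignments.

.extdata <- function(file)
  system.file("extdata", file, package = "ovarioleEvo", mustWork = TRUE)

#' Reported per-branch dN/dS for the candidate ovariole-related genes
#'
#' Long-format branch records for the 42 candidate genes (27 from the
#' signaling/connector RNAi set, 10 from the bulk soma-upregulated set, 5
#' from the bulk/single-cell overlap set) across the five terminal branches
#' Dsim, Dsec, Dmel, Dyak, Dere, with the sentinel conventions: `">1"`
#' means dN/dS diverged (dS ~ 0, dN > 0.001, inferring positive selection),
#' `"-"` means both dN and dS were below 0.001.
#'
#' @return A [GenomeRateTable-class]; M0 omega and tau are attached for the
#'   genes whose source tables report them (see [ovarioleGeneInfo]).
#' @export
ovarioleGeneRates <- function() {
  wide <- utils::read.delim(.extdata("ovariole_gene_branch_rates.tsv"),
                            colClasses = "character", check.names = FALSE)
  branches <- c("Dsim", "Dsec", "Dmel", "Dyak", "Dere")
  long <- do.call(rbind, lapply(branches, function(b)
    data.frame(gene = wide$gene, branch = b, omega = wide[[b]])))
  tok <- trimws(long$omega)
  status <- ifelse(tok == ">1", "GT1", ifelse(tok == "-", "LOWDIV", "VALUE"))
  num <- suppressWarnings(as.numeric(tok))
  eps <- 0.001
  rec <- data.frame(gene = long$gene, branch = long$branch,
                    dN = ifelse(status == "LOWDIV", 0,
                         ifelse(status == "GT1", 2 * eps, num * 0.3)),
                    dS = ifelse(status == "VALUE", 0.3, 0),
                    omega = ifelse(status == "VALUE", num, NA_real_),
                    status = status)
  info <- ovarioleGeneInfo()
  m0 <- info[!is.na(info$m0), c("gene", "m0")]
  names(m0)[2] <- "omega"
  genomeRateTable(m0 = m0, records = rec)
}

#' Reported M0 dN/dS, tau and fold-change for the expression-derived genes
#'
#' Gene-level metadata for the candidate genes: symbol, which screen the
#' gene came from (`signaling`, `bulkSoma`, `overlap`), and -- for the
#' expression-derived sets that report them -- the clade-wide M0 dN/dS, the
#' bulk soma/germline log2 fold change and the tau expression-specificity
#' index over 59 tissues/stages.
#'
#' @return data.frame with columns gene, symbol, sourceTable,
#'   log2FoldChange, m0, tau (NA where not reported).
#' @export
ovarioleGeneInfo <- function() {
  wide <- utils::read.delim(.extdata("ovariole_gene_branch_rates.tsv"),
                            colClasses = "character", check.names = FALSE)
  mt <- utils::read.delim(.extdata("ovariole_gene_m0_tau.tsv"))
  out <- data.frame(gene = wide$gene, symbol = wide$symbol,
                    sourceTable = wide$sourceTable)
  idx <- match(out$gene, mt$gene)
  out$log2FoldChange <- mt$log2FoldChange[idx]
  out$m0 <- mt$m0[idx]
  out$tau <- mt$tau[idx]
  out
}

#' Reported PGLS coefficients and ovariole-number predictions
#'
#' Intercept, slope, fit P-value and the per-species predicted ovariole
#' numbers for the 17 candidate genes whose branch dN/dS significantly
#' predicted ovariole number under PGLS. The predictions are reproduced
#' exactly by `intercept + slope * omega` with the default sentinel
#' imputation (GT1 -> 1.5, LOWDIV -> 0) applied to the branch rates of
#' [ovarioleGeneRates].
#'
#' @return data.frame with columns gene, symbol, pValue, intercept, slope,
#'   Dsim, Dsec, Dmel, Dyak, Dere.
#' @export
pglsCoefficients <- function() {
  utils::read.delim(.extdata("pgls_coefficients.tsv"), check.names = FALSE)
}
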