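## Sentinel-aware rate tables, divergence summaries, configuration and
## stage logging.
##
## Rate-table dialect (tab-separated, columns gene, branch, dN, dS, omega):
## the omega cell is a number, ">1" (dN/dS diverged because dS ~ 0 while
## dN > 0.001, inferring positive selection) or "-" (dN and dS both below
## 0.001: too little divergence to determine dN/dS).

#' Classify (dN, dS) pairs into VALUE / GT1 / LOWDIV
#'
#' Exactly one sentinel class applies to any nonnegative pair: `LOWDIV` when
#' both dN and dS fall below the low-divergence threshold, `GT1` when dS is
#' below it while dN exceeds it (the ratio diverges), `VALUE` otherwise.
#'
#' @param dN,dS Nonnegative numeric vectors.
#' @param lowDivThreshold Divergence floor (default 0.001).
#' @return Character vector in `c("VALUE","GT1","LOWDIV")`.
#' @export
#' @examples
#' classifyOmega(c(0.2, 0.05, 0.0005), c(0.4, 0.0001, 0.0004))
classifyOmega <- function(dN, dS, lowDivThreshold = 0.001) {
  if (any(dN < 0) || any(dS < 0)) stop("dN and dS must be nonnegative")
  ifelse(dN < lowDivThreshold & dS < lowDivThreshold, "LOWDIV",
         ifelse(dS < lowDivThreshold, "GT1", "VALUE"))
}

#' Build a genome rate table from data frames
#'
#' @param m0 data.frame with columns `gene`, `omega`.
#' @param records data.frame with columns `gene`, `branch`, `dN`, `dS`,
#'   `omega` (NA for sentinel rows), `status`.
#' @param flags data.frame with columns `gene`, `branch`, `selected`.
#' @return A [GenomeRateTable-class].
#' @export
genomeRateTable <- function(m0 = data.frame(gene = character(),
                                            omega = numeric()),
                            records = data.frame(),
                            flags = data.frame()) {
  methods::new("GenomeRateTable", m0 = m0, records = records, flags = flags)
}

#' @describeIn genomeRateTable M0 table accessor.
#' @param x A `GenomeRateTable`.
#' @export
m0Table <- function(x) x@m0

#' @describeIn genomeRateTable Per-branch records accessor.
#' @export
branchRecords <- function(x) x@records

#' @describeIn genomeRateTable Positive-selection flags accessor.
#' @export
selectionFlags <- function(x) x@flags

setMethod("show", "GenomeRateTable", function(object) {
  cat("GenomeRateTable:", nrow(object@m0), "genes with M0 omega;",
      nrow(object@records), "branch records;",
      nrow(object@flags), "selection flags\n")
  if (nrow(object@records)) {
    tab <- table(object@records$status)
    cat("  sentinel statuses:",
        paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  }
})

#' Read a sentinel-aware per-branch rate table
#'
#' Parses the TSV dialect of the per-gene, per-branch dN/dS tables: numeric
#' omega cells become `VALUE` records, `">1"` becomes the `GT1` sentinel and
#' `"-"` the `LOWDIV` sentinel. An optional companion M0 table (columns
#' `gene`, `omega`) populates the genome-wide M0 values.
#'
#' @param path TSV file with columns `gene`, `branch`, `dN`, `dS`, `omega`.
#'   `dN`/`dS` columns may be absent, in which case sentinel-consistent
#'   placeholders are reconstructed from the omega cell.
#' @param m0Path Optional TSV with columns `gene`, `omega`.
#' @param flagsPath Optional TSV with columns `gene`, `branch`, `selected`.
#' @param lowDivThreshold Divergence floor used for validating sentinels.
#' @return A [GenomeRateTable-class].
#' @export
readRateTable <- function(path, m0Path = NULL, flagsPath = NULL,
                          lowDivThreshold = 0.001) {
  d <- utils::read.delim(path, colClasses = "character",
                         check.names = FALSE)
  need <- c("gene", "branch", "omega")
  if (!all(need %in% names(d)))
    stop("rate table must have columns gene, branch, omega")
  tok <- trimws(d$omega)
  status <- ifelse(tok == ">1", "GT1", ifelse(tok == "-", "LOWDIV", "VALUE"))
  num <- suppressWarnings(as.numeric(tok))
  bad <- status == "VALUE" & is.na(num)
  if (any(bad))
    stop("unknown omega token(s): ", paste(unique(tok[bad]), collapse = ", "))
  if (any(num[status == "VALUE"] < 0, na.rm = TRUE))
    stop("negative omega in rate table")
  eps <- lowDivThreshold
  hasDN <- all(c("dN", "dS") %in% names(d))
  if (hasDN) {
    dN <- as.numeric(d$dN); dS <- as.numeric(d$dS)
    if (any(dN < 0, na.rm = TRUE) || any(dS < 0, na.rm = TRUE))
      stop("negative dN or dS in rate table")
  } else {
    ## reconstruct sentinel-consistent placeholders
    dN <- ifelse(status == "LOWDIV", 0,
                 ifelse(status == "GT1", 2 * eps, num * 0.3))
    dS <- ifelse(status == "LOWDIV", 0, ifelse(status == "GT1", 0, 0.3))
  }
  rec <- data.frame(gene = d$gene, branch = d$branch, dN = dN, dS = dS,
                    omega = ifelse(status == "VALUE", num, NA_real_),
                    status = status)
  m0 <- if (!is.null(m0Path)) {
    m <- utils::read.delim(m0Path)
    data.frame(gene = as.character(m$gene), omega = as.numeric(m$omega))
  } else data.frame(gene = character(), omega = numeric())
  flags <- if (!is.null(flagsPath)) {
    f <- utils::read.delim(flagsPath)
    data.frame(gene = as.character(f$gene), branch = as.character(f$branch),
               selected = as.logical(f$selected))
  } else data.frame()
  genomeRateTable(m0 = m0, records = rec, flags = flags)
}

#' Write the per-branch records of a rate table in the sentinel dialect
#'
#' @param table A [GenomeRateTable-class].
#' @param path Output TSV path.
#' @export
writeRateTable <- function(table, path) {
  r <- branchRecords(table)
  out <- data.frame(gene = r$gene, branch = r$branch,
                    dN = r$dN, dS = r$dS,
                    omega = ifelse(r$status == "GT1", ">1",
                            ifelse(r$status == "LOWDIV", "-",
                                   format(r$omega, digits = 10,
                                          trim = TRUE, scientific = FALSE))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome-wide divergence summary
#'
#' Percentiles of per-branch dN and dS and the median M0 omega, computed
#' over `VALUE` records only, with linear interpolation between order
#' statistics (the default quantile rule; stated here because published
#' percentile conventions vary).
#'
#' @param table A [GenomeRateTable-class].
#' @param q Percentile in (0, 100) for dN and dS (e.g. 95).
#' @return Named numeric: `dN`, `dS` (q-th percentiles) and `m0Median`.
#' @export
summarizeDivergence <- function(table, q = 95) {
  stopifnot(q > 0, q < 100)
  r <- branchRecords(table)
  v <- r[r$status == "VALUE", , drop = FALSE]
  if (!nrow(v)) stop("no VALUE records to summarise")
  m0 <- m0Table(table)$omega
  c(dN = unname(stats::quantile(v$dN, q / 100, type = 7)),
    dS = unname(stats::quantile(v$dS, q / 100, type = 7)),
    m0Median = if (length(m0)) stats::median(m0) else NA_real_)
}

#' Read an expression matrix (genes x conditions TSV)
#'
#' First column gene identifiers, header row of condition names.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and condition colnames.
#' @export
readExpressionMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("condition labels must be unique")
  m
}

#' Read a pipeline configuration file
#'
#' A structured YAML key-value file holding the thresholds and seeds that
#' control the screens; values given in the file override the documented
#' defaults.
#'
#' @param path YAML file path (NULL returns the defaults).
#' @return Named list of settings.
#' @export
pipelineConfig <- function(path = NULL) {
  def <- list(lowDivThreshold = 0.001, saturationCap = 1.5,
              foldSignal = 1.5, foldExpression = 2.2,
              omegaCut = 0.20, hawaiianAbsoluteCut = 0.33,
              hawaiianFoldCut = 1.5, tauCut = 0.90,
              pSinglec = 0.05, pBulk = 0.01,
              gt1Value = 1.5, lowdivValue = 0.0, seed = 1L)
  if (is.null(path)) return(def)
  usr <- yaml::read_yaml(path)
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  def[names(usr)] <- usr
  def
}

## Stage logging: every screen reports genes in/out and active thresholds so
## multistage screens stay auditable. Controlled by
## options(ovarioleEvo.verbose = TRUE/FALSE).
.logStage <- function(stage, nIn, nOut, ...) {
  if (!isTRUE(getOption("ovarioleEvo.verbose", TRUE))) return(invisible())
  extras <- c(...)
  message(sprintf("[%s] %d in -> %d out%s", stage, nIn, nOut,
                  if (length(extras))
                    paste0(" (", paste(names(extras), extras, sep = "=",
                                       collapse = ", "), ")") else ""))
}
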