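## Multilayer gene screens: fold-over-genome-median dN/dS thresholds,
## branch-max attribution, saturation filtering, top-N upregulation
## ranking, cross-dataset overlap and exclusive/pooled upregulation.
##
## Threshold conventions (documented next to each rule): fold screens use
## ">=" (matching the published ">= 1.5-fold" and ">= 0.20" wording); the
## absolute Hawaiian cut uses strict ">" (matching "dN/dS > 0.33"); the GT1
## sentinel denotes dN/dS > 1 and therefore passes any finite omega
## threshold; LOWDIV records never pass. Ties everywhere break by
## lexicographic gene id.

.screenResult <- function(trace) {
  passed <- tapply(trace$pass, trace$gene, all)
  list(genes = sort(names(passed)[passed]),
       trace = trace[order(trace$gene), , drop = FALSE])
}

#' Validate differential-expression records
#'
#' Checks the contract of the upstream differential-expression tables
#' (bulk RNA-seq or single-cell): columns `gene`, `context`,
#' `log2FoldChange`, `pValue`, `direction`; P in `[0,1]`; direction
#' consistent with the fold-change sign.
#'
#' @param de data.frame of differential-expression records.
#' @return The validated data.frame (invisibly usable in pipes).
#' @export
deRecords <- function(de) {
  need <- c("gene", "context", "log2FoldChange", "pValue", "direction")
  if (!all(need %in% names(de)))
    stop("missing columns: ", paste(setdiff(need, names(de)), collapse = ", "))
  if (any(de$pValue < 0 | de$pValue > 1)) stop("pValue outside [0, 1]")
  if (!all(de$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  bad <- (de$direction == "up" & de$log2FoldChange < 0) |
         (de$direction == "down" & de$log2FoldChange > 0)
  if (any(bad)) stop("direction inconsistent with log2FoldChange sign")
  de
}

#' Fold-over-genome-median dN/dS screen
#'
#' A gene passes when its statistic (M0 omega, or the maximum per-branch
#' omega for `scope = "any_branch"`) is at least `fold` times the
#' genome-wide median of the M0 values. GT1 sentinel branches pass any
#' finite threshold; LOWDIV branches never pass.
#'
#' @param table A [GenomeRateTable-class] providing the genome-wide M0
#'   distribution and (for branch scope) per-branch records.
#' @param fold Threshold multiplier (> 0), e.g. 1.5 for conserved signaling
#'   genes, 2.2 for the 0.20 expression-set cut.
#' @param scope `"m0"` or `"any_branch"`.
#' @param genes Optional subset of gene ids to screen (default: all genes in
#'   the table).
#' @return List with `genes` (sorted passers), `threshold`, `median` and a
#'   per-gene criteria `trace`.
#' @export
foldScreen <- function(table, fold, scope = c("m0", "any_branch"),
                       genes = NULL) {
  scope <- match.arg(scope)
  stopifnot(fold > 0)
  m0 <- m0Table(table)
  if (!nrow(m0)) stop("empty rate table")
  med <- stats::median(m0$omega)
  thr <- fold * med
  if (is.null(genes)) genes <- m0$gene
  if (!length(genes))
    return(list(genes = character(), threshold = thr, median = med,
                trace = data.frame()))
  if (scope == "m0") {
    val <- m0$omega[match(genes, m0$gene)]
    pass <- !is.na(val) & val >= thr
  } else {
    r <- branchRecords(table)
    r <- r[r$gene %in% genes, , drop = FALSE]
    agg <- vapply(genes, function(g) {
      rg <- r[r$gene == g, , drop = FALSE]
      if (any(rg$status == "GT1")) return(Inf)
      v <- rg$omega[rg$status == "VALUE"]
      if (length(v)) max(v) else NA_real_
    }, 0)
    val <- agg
    pass <- !is.na(val) & val >= thr
  }
  trace <- data.frame(gene = genes,
                      criterion = paste0("fold_", scope),
                      value = val, threshold = thr, pass = pass)
  out <- .screenResult(trace)
  .logStage("foldScreen", length(genes), length(out$genes),
            fold = fold, median = signif(med, 4), scope = scope)
  c(out, list(threshold = thr, median = med))
}

#' Per-branch screen with absolute and fold cuts
#'
#' A gene passes when any of its branches has omega strictly above
#' `absoluteCut`, or at least `foldCut` times that branch's genome-wide
#' median. Used for the outgroup-clade scan where per-branch medians differ
#' by species.
#'
#' @param table A [GenomeRateTable-class].
#' @param absoluteCut Absolute omega cut (strict `>`, e.g. 0.33).
#' @param foldCut Fold multiplier over the per-branch median (`>=`).
#' @param perBranchMedians Named numeric of genome-wide median omega per
#'   branch; every branch referenced by the records must be present.
#' @return List with `genes` and `trace`.
#' @export
hawaiianBranchScreen <- function(table, absoluteCut = 0.33, foldCut = 1.5,
                                 perBranchMedians) {
  r <- branchRecords(table)
  if (!nrow(r)) stop("empty rate table")
  miss <- setdiff(unique(r$branch), names(perBranchMedians))
  if (length(miss))
    stop("missing per-branch median for: ", paste(miss, collapse = ", "))
  thr <- perBranchMedians[r$branch] * foldCut
  passRec <- r$status == "GT1" |
    (r$status == "VALUE" & (r$omega > absoluteCut | r$omega >= thr))
  pass <- tapply(passRec, r$gene, any)
  genes <- sort(names(pass)[pass])
  trace <- data.frame(gene = r$gene, branch = r$branch,
                      criterion = "branch_cut",
                      value = ifelse(r$status == "GT1", Inf, r$omega),
                      threshold = pmin(absoluteCut, thr), pass = passRec)
  .logStage("hawaiianBranchScreen", length(unique(r$gene)), length(genes),
            absoluteCut = absoluteCut, foldCut = foldCut)
  list(genes = genes, trace = trace)
}

#' Branch(es) with the maximal dN/dS for one gene
#'
#' GT1 sentinel branches (dN/dS > 1) outrank any numeric value; ties return
#' every maximal branch. All-LOWDIV input has no defined maximum.
#'
#' @param records data.frame of one gene's branch records (columns `branch`,
#'   `omega`, `status`).
#' @return Character vector of branch labels.
#' @export
branchMax <- function(records) {
  stopifnot(all(c("branch", "omega", "status") %in% names(records)))
  gt1 <- records$status == "GT1"
  if (any(gt1)) return(sort(records$branch[gt1]))
  v <- records[records$status == "VALUE", , drop = FALSE]
  if (!nrow(v)) stop("undefined branch maximum: all records are LOWDIV")
  mx <- max(v$omega)
  sort(v$branch[v$omega == mx])
}

#' Saturation and low-divergence filtering of branch records
#'
#' Branch records with dN or dS at or above the saturation cap (default 1.5
#' substitutions per site, beyond which distances are unreliable) are
#' flagged and excluded from downstream screens; records with both dN and
#' dS at or below the low-divergence floor (failing the "dN or dS > 0.001"
#' inclusion rule) are likewise excluded.
#'
#' @param records data.frame with columns `dN`, `dS` (any other columns are
#'   carried along).
#' @param cap Saturation threshold (> 0).
#' @param lowDivThreshold Inclusion floor.
#' @return List of data.frames: `kept`, `saturated`, `lowDivergence`.
#' @export
saturationFilter <- function(records, cap = 1.5, lowDivThreshold = 0.001) {
  stopifnot(cap > 0)
  sat <- records$dN >= cap | records$dS >= cap
  low <- !sat & !(records$dN > lowDivThreshold | records$dS > lowDivThreshold)
  keep <- !sat & !low
  .logStage("saturationFilter", nrow(records), sum(keep),
            saturated = sum(sat), low_divergence = sum(low), cap = cap)
  list(kept = records[keep, , drop = FALSE],
       saturated = records[sat, , drop = FALSE],
       lowDivergence = records[low, , drop = FALSE])
}

#' Top-N upregulated genes in a context
#'
#' Filters to significantly upregulated records in the given context, sorts
#' by log2 fold change (descending) with deterministic gene-id tie-breaks,
#' and returns the top n gene ids.
#'
#' @param de Differential-expression records (see [deRecords]).
#' @param context Cell type or stage label.
#' @param n Number of genes to return (all available if fewer).
#' @param pCut Significance gate (default 0.01, the bulk RNA-seq
#'   convention; single-cell comparisons use 0.05).
#' @return Character vector of gene ids, ranked.
#' @export
rankTopUpregulated <- function(de, context, n, pCut = 0.01) {
  stopifnot(n >= 1)
  de <- deRecords(de)
  if (!context %in% de$context) stop("unknown context: ", context)
  d <- de[de$context == context & de$direction == "up" & de$pValue < pCut, ,
          drop = FALSE]
  d <- d[order(-d$log2FoldChange, d$gene), , drop = FALSE]
  utils::head(d$gene, n)
}

#' Cross-dataset overlap screen
#'
#' Genes present in the per-stage bulk top lists, upregulated in at least
#' one single-cell type at the significance gate, and with M0 omega strictly
#' above the rapid-evolution cut.
#'
#' @param bulkTop List (one per stage) of ranked gene-id vectors from the
#'   bulk dataset.
#' @param singlecUp Single-cell differential-expression records.
#' @param rates A [GenomeRateTable-class] with M0 values.
#' @param omegaCut Rapid-evolution cut (strict `>`, default 0.20).
#' @param pCut Single-cell significance gate (default 0.05).
#' @return Sorted character vector of gene ids.
#' @export
overlapScreen <- function(bulkTop, singlecUp, rates, omegaCut = 0.20,
                          pCut = 0.05) {
  stopifnot(omegaCut > 0)
  bulk <- unique(unlist(bulkTop))
  sc <- deRecords(singlecUp)
  scGenes <- unique(sc$gene[sc$direction == "up" & sc$pValue < pCut])
  m0 <- m0Table(rates)
  rapid <- m0$gene[m0$omega > omegaCut]
  out <- sort(intersect(intersect(bulk, scGenes), rapid))
  .logStage("overlapScreen", length(bulk), length(out),
            omegaCut = omegaCut, pCut = pCut)
  out
}

#' Exclusive upregulation within pooled cell-type groups
#'
#' Assigns a gene to a pooled group (e.g. SH = SHa + SHm, TF = TFa + TFp)
#' if and only if every cell type in which it is significantly upregulated
#' falls within that single group.
#'
#' @param de Differential-expression records.
#' @param pooling Named character vector mapping each cell type to its
#'   pooled group; every cell type present in `de` must be covered.
#' @param pCut Significance gate (default 0.05).
#' @param genes Optional subset of genes to consider.
#' @return Named list of sorted gene-id vectors, one per pooled group.
#' @export
exclusiveUpregulation <- function(de, pooling, pCut = 0.05, genes = NULL) {
  de <- deRecords(de)
  up <- de[de$direction == "up" & de$pValue < pCut, , drop = FALSE]
  if (!is.null(genes)) up <- up[up$gene %in% genes, , drop = FALSE]
  miss <- setdiff(unique(up$context), names(pooling))
  if (length(miss))
    stop("pooling does not cover cell types: ", paste(miss, collapse = ", "))
  groups <- sort(unique(pooling))
  byGene <- split(pooling[up$context], up$gene)
  out <- lapply(groups, function(g) {
    sort(names(byGene)[vapply(byGene, function(gs) all(gs == g), TRUE)])
  })
  stats::setNames(out, groups)
}
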