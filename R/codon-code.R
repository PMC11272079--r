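## Genetic-code bookkeeping for the Goldman-Yang codon model.
##
## The state space is the 61 sense codons of the universal code; stop codons
## are excluded. All structural quantities (which codon pairs differ at a
## single nucleotide, whether that change is a transition, whether it is
## synonymous) are precomputed once at load time.

.codonEnv <- new.env(parent = emptyenv())

.baseOrder <- c("T", "C", "A", "G")

#' Sense codons of the universal genetic code
#'
#' Returns the 61 stop-free codons, in the fixed TCAG-nested order used for
#' every rate matrix, frequency vector and simulator state index in the
#' package.
#'
#' @param code Genetic-code identifier; only `"universal"` is supported.
#' @return Character vector of 61 codons.
#' @export
#' @examples
#' head(senseCodons())
senseCodons <- function(code = "universal") {
  if (!identical(code, "universal"))
    stop("only the universal genetic code is supported, got '", code, "'")
  .codonTables(code)$codons
}

## amino acid per sense codon (universal code)
.codonAmino <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

.codonTables <- function(code = "universal") {
  key <- paste0("tab_", code)
  if (!is.null(.codonEnv[[key]])) return(.codonEnv[[key]])
  all64 <- as.vector(t(outer(
    as.vector(t(outer(.baseOrder, .baseOrder, paste0))), .baseOrder, paste0)))
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  codons <- all64[!all64 %in% stops]          # 61 sense codons
  n <- length(codons)
  aa <- .codonAmino(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  ## pairwise single-nucleotide change classification:
  ## 0 = not a single-nt change; 1 = syn transversion; 2 = syn transition;
  ## 3 = nonsyn transversion; 4 = nonsyn transition
  cls <- matrix(0L, n, n)
  isTs <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (pos in 1:3) {
    same <- outer(cmat[, pos], cmat[, pos], "==")
    othersSame <- Reduce("&", lapply(setdiff(1:3, pos), function(p)
      outer(cmat[, p], cmat[, p], "==")))
    single <- !same & othersSame
    ts <- outer(cmat[, pos], cmat[, pos], isTs)
    syn <- outer(aa, aa, "==")
    cls[single & !ts & syn]  <- 1L
    cls[single & ts  & syn]  <- 2L
    cls[single & !ts & !syn] <- 3L
    cls[single & ts  & !syn] <- 4L
  }
  diag(cls) <- 0L
  out <- list(codons = codons, aa = aa, class = cls,
              stops = stops, n = n)
  .codonEnv[[key]] <- out
  out
}

#' Goldman-Yang instantaneous rate matrix
#'
#' Builds the 61 x 61 GY94 rate matrix for one branch. Off-diagonal entries
#' are zero for multi-nucleotide changes and otherwise proportional to the
#' target codon frequency, multiplied by `kappa` for transitions and by
#' `omega` for nonsynonymous changes. Rows sum to zero. With `scale = TRUE`
#' the matrix is normalised so the expected number of substitutions per codon
#' per unit time equals one, so branch lengths are measured in substitutions
#' per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codonFreqs Numeric vector of 61 equilibrium codon frequencies
#'   summing to one; defaults to equal frequencies.
#' @param scale Normalise the mean rate to one?
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
#' @examples
#' Q <- buildRateMatrix(2, 0.5)
#' max(abs(rowSums(Q)))  # rows sum to zero
buildRateMatrix <- function(kappa, omega, codonFreqs = equalCodonFreqs(),
                            scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  tab <- .codonTables()
  .checkFreqs(codonFreqs)
  cls <- tab$class
  R <- matrix(0, tab$n, tab$n, dimnames = list(tab$codons, tab$codons))
  fac <- c(1, kappa, omega, kappa * omega)   # class 1..4 multipliers
  idx <- which(cls > 0L)
  R[idx] <- fac[cls[idx]] * codonFreqs[(idx - 1L) %/% tab$n + 1L]
  diag(R) <- -rowSums(R)
  if (scale) {
    mu <- -sum(codonFreqs * diag(R))
    if (mu > 0) R <- R / mu
  }
  R
}

#' Equal sense-codon frequencies
#' @return Numeric vector of 61 values 1/61, named by codon.
#' @export
equalCodonFreqs <- function() {
  tab <- .codonTables()
  stats::setNames(rep(1 / tab$n, tab$n), tab$codons)
}

#' Empirical F3x4 codon frequencies from an alignment
#'
#' Estimates codon frequencies as the product of the observed nucleotide
#' frequencies at each codon position, renormalised over the 61 sense codons.
#'
#' @param aln A [CodonAlignment-class].
#' @return Numeric vector of 61 frequencies summing to one.
#' @export
f3x4Freqs <- function(aln) {
  tab <- .codonTables()
  mat <- codonStates(aln)                 # ntaxa x ncodons, values 1..61, NA ok
  codons <- tab$codons[mat[!is.na(mat)]]
  cmat <- do.call(rbind, strsplit(codons, ""))
  pos <- lapply(1:3, function(p) {
    f <- table(factor(cmat[, p], levels = .baseOrder))
    as.numeric(f) / sum(f)
  })
  cs <- do.call(rbind, strsplit(tab$codons, ""))
  f <- pos[[1]][match(cs[, 1], .baseOrder)] *
       pos[[2]][match(cs[, 2], .baseOrder)] *
       pos[[3]][match(cs[, 3], .baseOrder)]
  stats::setNames(f / sum(f), tab$codons)
}

.checkFreqs <- function(f) {
  if (length(f) != 61 || any(f < 0) || abs(sum(f) - 1) > 1e-6)
    stop("codonFreqs must be 61 nonnegative values summing to 1")
  invisible(TRUE)
}

## Mean substitution rate of the *unscaled* GY94 matrix, split into the
## nonsynonymous part (proportional to omega) and the synonymous part:
## mu(omega) = omega * A + B.  Used for rate scaling and dN/dS decomposition.
.gyFlux <- function(kappa, codonFreqs) {
  tab <- .codonTables()
  cls <- tab$class
  base <- matrix(0, tab$n, tab$n)
  fac <- c(1, kappa, 1, kappa)
  idx <- which(cls > 0L)
  base[idx] <- fac[cls[idx]] * codonFreqs[(idx - 1L) %/% tab$n + 1L]
  w <- codonFreqs
  nonsyn <- cls == 3L | cls == 4L
  A <- sum(w * rowSums(base * nonsyn))
  B <- sum(w * rowSums(base * (!nonsyn & cls > 0L)))
  list(A = A, B = B)
}

## Eigendecomposition of the (scaled or unscaled) reversible GY94 matrix via
## symmetrisation:  S = D^{1/2} Q D^{-1/2} with D = diag(pi) is symmetric.
## P(t) = D^{-1/2} U exp(L t) U' D^{1/2}.
.gyEigen <- function(kappa, omega, codonFreqs, scale = TRUE) {
  Q <- buildRateMatrix(kappa, omega, codonFreqs, scale = scale)
  sq <- sqrt(codonFreqs)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left  = e$vectors / sq,      # D^{-1/2} U   (61 x 61)
       right = t(e$vectors * sq))   # U' D^{1/2}
}

## Transition probability matrix for elapsed time t (possibly rescaled by a
## mixture normalising constant handled by the caller).
.probMatrix <- function(eig, t) {
  if (t < 0) stop("negative branch length")
  P <- eig$left %*% (exp(eig$values * t) * eig$right)
  ## numerical cleanup: tiny negatives from roundoff
  P[P < 0] <- 0
  P
}
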