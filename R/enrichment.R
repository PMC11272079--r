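## One-tailed chi-squared enrichment of positive-selection frequency.

#' One-tailed chi-squared goodness-of-fit enrichment test
#'
#' Compares the observed count of positively selected genes in a set of n
#' genes against the genome-wide proportion p0 with a Pearson
#' goodness-of-fit statistic over the two cells (k, n - k) vs
#' (n p0, n (1 - p0)). With `yates = TRUE` the continuity correction
#' subtracts 0.5 from |O - E| before squaring. The one-tailed P halves the
#' two-sided chi-squared(1) tail when the deviation is in the enrichment
#' direction (k >= n p0) and is 1 minus half the tail otherwise -- the only
#' reading consistent with the published one-tailed values. Both variants
#' are exposed because published P-values mix the two conventions; the
#' default is uncorrected.
#'
#' @param observedK Count of genes with positive selection (0 <= k <= n).
#' @param n Gene-set size (>= 1).
#' @param p0 Genome-wide positive-selection proportion, in (0, 1).
#' @param yates Apply the Yates continuity correction?
#' @return List with `observedK`, `n`, `p0`, `expected`, `chi2`,
#'   `pOneTailed`, `pTwoTailed`, `yates`.
#' @export
#' @examples
#' chiSquareEnrichment(6, 27, 0.12)$pOneTailed          # ~0.051
#' chiSquareEnrichment(2, 8, 0.054, yates = TRUE)$pOneTailed  # ~0.047
chiSquareEnrichment <- function(observedK, n, p0, yates = FALSE) {
  stopifnot(n >= 1, observedK >= 0, observedK <= n)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  e <- c(n * p0, n * (1 - p0))
  o <- c(observedK, n - observedK)
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  p2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p1 <- if (observedK >= e[1]) p2 / 2 else 1 - p2 / 2
  list(observedK = observedK, n = n, p0 = p0, expected = e[1],
       chi2 = chi2, pOneTailed = p1, pTwoTailed = p2, yates = yates)
}
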