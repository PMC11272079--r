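#' Construct a codon alignment
#'
#' @param sequences Named character vector of aligned in-frame nucleotide
#'   sequences, or a `DNAStringSet`.
#' @param code Genetic-code identifier.
#' @return A [CodonAlignment-class].
#' @export
#' @examples
#' aln <- codonAlignment(c(a = "ATGTTT", b = "ATGTTC"))
#' nCodons(aln)
codonAlignment <- function(sequences, code = "universal") {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  methods::new("CodonAlignment", sequences = sequences, code = code)
}

#' @describeIn codonAlignment Taxon names of the alignment.
#' @param x A `CodonAlignment`.
#' @export
taxa <- function(x) names(x@sequences)

#' @describeIn codonAlignment Number of codon columns.
#' @export
nCodons <- function(x) Biostrings::width(x@sequences)[1] %/% 3L

#' @describeIn codonAlignment Integer codon-state matrix (taxa x codon
#'   columns, values 1..61, `NA` for gap/ambiguous codons).
#' @export
codonStates <- function(x) {
  tab <- .codonTables(x@code)
  chars <- as.matrix(x@sequences)
  nc <- ncol(chars) %/% 3L
  cod <- matrix(paste0(chars[, 3 * seq_len(nc) - 2, drop = FALSE],
                       chars[, 3 * seq_len(nc) - 1, drop = FALSE],
                       chars[, 3 * seq_len(nc), drop = FALSE]),
                nrow = nrow(chars))
  st <- matrix(match(cod, tab$codons), nrow = nrow(chars),
               dimnames = list(taxa(x), NULL))
  st
}

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment with", length(object@sequences), "taxa and",
      nCodons(object), "codon columns (", object@code, "code )\n")
  cat("  taxa:", paste(utils::head(taxa(object), 6), collapse = ", "),
      if (length(object@sequences) > 6) "..." else "", "\n")
})

#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' FASTA is the canonical alignment format; sequential PHYLIP is accepted
#' read-only. The reading frame is trusted; alignments containing stop codons
#' are rejected with an error naming the taxon and codon index.
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"`.
#' @param code Genetic-code identifier.
#' @return A [CodonAlignment-class].
#' @export
readCodonAlignment <- function(path, format = c("fasta", "phylip"),
                               code = "universal") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
  } else {
    d <- ape::read.dna(path, format = "sequential", as.character = TRUE)
    seqs <- Biostrings::DNAStringSet(
      setNames(apply(d, 1, paste0, collapse = ""), rownames(d)))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  }
  codonAlignment(seqs, code = code)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [CodonAlignment-class].
#' @param path Output file path.
#' @export
writeCodonAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@sequences, path, width = 60L)
  invisible(path)
}
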