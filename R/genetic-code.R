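#' The standard genetic code with selenocysteine excluded
#'
#' Returns the standard nuclear genetic code as used throughout the package:
#' 61 sense codons mapped to the 20 standard amino acids (three-letter
#' symbols), with \code{TAA}, \code{TAG} and \code{TGA} as stop codons.
#' UGA-encoded selenocysteine is deliberately excluded: treating UGA as a
#' sense codon would contaminate codon-usage counts with stop-codon
#' annotations, so the SeC anticodon (TCA) is never part of the decoding
#' potential graph.
#'
#' @return An object of class \code{genetic_code}: a list with
#'   \item{table}{named character vector, codon (DNA, 5'->3') -> amino-acid
#'     three-letter symbol, \code{"Stop"} for stop codons}
#'   \item{sense_codons}{sorted character vector of the 61 sense codons}
#'   \item{stop_codons}{\code{c("TAA","TAG","TGA")}}
#' @examples
#' code <- standard_genetic_code()
#' length(code$sense_codons)  # 61
#' code$table[["ATG"]]        # "Met"
#' @export
standard_genetic_code <- function() {
  gc1 <- Biostrings::GENETIC_CODE  # codon -> one-letter AA, "*" for stop
  aa3 <- Biostrings::AMINO_ACID_CODE
  tab <- vapply(names(gc1), function(codon) {
    a <- gc1[[codon]]
    if (a == "*") "Stop" else unname(aa3[[a]])
  }, character(1))
  stops <- sort(names(tab)[tab == "Stop"])
  sense <- sort(setdiff(names(tab), stops))
  stopifnot(length(sense) == 61L, identical(stops, c("TAA", "TAG", "TGA")))
  structure(list(table = tab, sense_codons = sense, stop_codons = stops),
            class = "genetic_code")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between codons and anticodons
#'
#' Codons and anticodons are both stored in the DNA alphabet, 5'->3'.  An
#' anticodon is the reverse complement of its cognate codon, so the wobble
#' position (tRNA position 34) is the anticodon's first base and pairs the
#' codon's third base.
#'
#' @param anticodon,codon character vector of 3-mers.
#' @return character vector of 3-mers.
#' @export
anticodon_to_codon <- function(anticodon) revcomp(anticodon)

#' @rdname anticodon_to_codon
#' @export
codon_to_anticodon <- function(codon) revcomp(codon)

#' All sense anticodons under a genetic code
#'
#' @param code a \code{genetic_code}.
#' @return sorted character vector of the 61 anticodons whose cognate codons
#'   are sense codons. Anticodons of stop codons (TTA, CTA, TCA) are absent.
#' @export
sense_anticodons <- function(code = standard_genetic_code()) {
  sort(codon_to_anticodon(code$sense_codons))
}

#' Isotype (amino acid) of an anticodon
#'
#' @param anticodon character vector of anticodon 3-mers.
#' @param code a \code{genetic_code}.
#' @return character vector of three-letter amino-acid symbols.
#' @export
anticodon_isotype <- function(anticodon, code = standard_genetic_code()) {
  unname(code$table[anticodon_to_codon(anticodon)])
}

# internal: wobble base (position 34) = first character of the anticodon
wobble_base <- function(anticodon) substr(anticodon, 1L, 1L)
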