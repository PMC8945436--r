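#' Sequence alphabet helpers
#'
#' Mature miRNAs are handled as RNA (with `U`), genomic sequence (3'UTRs,
#' alignment rows, reads) as DNA (with `T`). Conversion happens explicitly at
#' module boundaries; nothing downstream guesses the alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname alphabet
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' Reverse complement of DNA strings
#'
#' `N` complements to `N`; any other character is an error.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) {
    stop("non-ACGTN character in DNA sequence: ", x[which(bad)[1]])
  }
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# All match start positions of a fixed pattern in a subject, including
# overlapping occurrences (gregexpr with a lookahead). Returns 0-based offsets.
overlap_match_offsets <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# Random sequence of length n over the given alphabet (uniform by default).
random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
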