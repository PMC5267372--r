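# Small sequence helpers shared across modules. Sequences are plain upper-case
# character scalars over A,C,G,T,N; heavy lifting is delegated to Biostrings.

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to protein in frame +1
#'
#' The input length must be a multiple of 3. Codons containing N translate
#' to X; stop codons translate to `*`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  bad <- nchar(x) %% 3L != 0L
  if (any(bad)) {
    stop("sequence length not a multiple of 3 (", nchar(x)[bad][1L], " nt)")
  }
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(x), if.fuzzy.codon = "X")
  ))
}

# number of mismatching positions between two raw vectors of equal length
.mismatches <- function(a, b) sum(a != b)

# character scalar -> raw vector (byte per character)
.as_raw <- function(s) charToRaw(s)
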