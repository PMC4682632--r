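# Sequence validation and amino-acid alphabets.

# the 20 standard residues
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# tolerated non-standard letters: ambiguity codes and rare residues.
# Sites whose N+1 is one of these get a missing intrinsic half-time.
AA_NONSTANDARD <- c("X", "B", "Z", "J", "U", "O")

#' Validate a protein sequence
#'
#' Upper-cases and checks that every character is a standard one-letter
#' amino-acid code or a tolerated non-standard letter (X, B, Z, J, U, O).
#'
#' @param sequence Character scalar, the protein sequence.
#' @return The validated, upper-cased sequence.
#' @export
validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence is empty", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(AA_STANDARD, AA_NONSTANDARD))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  sequence
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]
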