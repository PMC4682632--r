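# Discovery of internal Asn sites and the N-glycosylation sequon flag.

#' Find internal asparagine sites
#'
#' Scans a protein sequence for asparagines at internal positions
#' (2..L-1). Terminal asparagines are excluded: deamidation at the amino or
#' carboxyl terminus follows different chemistry and is out of scope.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param protein_id Identifier carried into the result.
#' @return A data frame with one row per internal Asn, columns
#'   `protein_id`, `position` (1-based), `n_plus_1` and `is_sequon`
#'   (`TRUE` where the Asn sits in an N\[^P\]\[ST\] motif and may be
#'   glycosylated, which would prevent deamidation).
#' @examples
#' find_asn_sites("MANGSANAK", "demo")
#' @export
find_asn_sites <- function(sequence, protein_id = "") {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  pos <- which(chars == "N")
  pos <- pos[pos > 1L & pos < L]
  data.frame(
    protein_id = rep(protein_id, length(pos)),
    position = pos,
    n_plus_1 = chars[pos + 1L],
    is_sequon = vapply(pos, function(p) is_sequon(sequence, p), logical(1L)),
    stringsAsFactors = FALSE
  )
}

#' Test for the N-glycosylation sequon
#'
#' `TRUE` iff the residue at `position` is Asn and starts an N\[^P\]\[ST\]
#' motif: the next residue exists and is not Pro, and the residue after that
#' is Ser or Thr. Glycosylated asparagines do not deamidate, so sequon sites
#' are flagged (not suppressed — occupancy cannot be known from sequence).
#'
#' @param sequence Protein sequence.
#' @param position 1-based index of an Asn residue.
#' @return Logical scalar.
#' @export
is_sequon <- function(sequence, position) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  if (position < 1L || position > length(chars)) {
    stop("position out of range", call. = FALSE)
  }
  if (chars[position] != "N") {
    stop(sprintf("residue at position %d is '%s', not 'N'",
                 position, chars[position]), call. = FALSE)
  }
  position + 2L <= length(chars) &&
    chars[position + 1L] != "P" &&
    chars[position + 2L] %in% c("S", "T")
}
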