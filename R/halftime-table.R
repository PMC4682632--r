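# Intrinsic (dipeptide-scale) deamidation half-times, keyed by the N+1 residue.

#' Read a dipeptide half-time table
#'
#' Reads a tab-separated table with columns `residue`, `t50_days` and
#' (optionally) `source`, giving the intrinsic deamidation half-time of the
#' Asn-(N+1) dipeptide in unstructured model peptides for each N+1 residue.
#' Lines starting with `#` are comments. All half-times must be positive and
#' Gly, the fastest-deamidating N+1 residue, must hold the minimum value —
#' a safeguard against transposed or mis-keyed tables.
#'
#' @param path Path to the TSV file. Defaults to the packaged table
#'   (pentapeptide measurements at pH 7.4, 37 degC).
#' @return An object of class `halftime_table`: a named numeric vector of
#'   half-times in days with attribute `source_label`.
#' @examples
#' tab <- read_halftime_table()
#' tab[["G"]]   # Asn-Gly, the fastest
#' @export
read_halftime_table <- function(path = system.file("extdata", "halftimes.tsv",
                                                   package = "ngome")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "t50_days") %in% names(df))) {
    stop("half-time table needs columns 'residue' and 't50_days'", call. = FALSE)
  }
  src <- if ("source" %in% names(df)) paste(unique(df$source), collapse = "; ") else ""
  halftime_table(stats::setNames(as.numeric(df$t50_days), toupper(df$residue)),
                 source_label = src)
}

#' Construct a half-time table from a named vector
#'
#' @param entries Named numeric vector: one-letter N+1 residue code to
#'   half-time in days. All values must be positive; if a `G` entry is
#'   present it must be the minimum.
#' @param source_label Free-text provenance tag.
#' @return A `halftime_table` object.
#' @export
halftime_table <- function(entries, source_label = "") {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("half-time table entries must be named by residue", call. = FALSE)
  }
  entries <- stats::setNames(as.numeric(entries), toupper(names(entries)))
  if (anyDuplicated(names(entries))) {
    stop("duplicate residue in half-time table", call. = FALSE)
  }
  if (any(is.na(entries)) || any(entries <= 0)) {
    stop("all half-times must be positive", call. = FALSE)
  }
  if ("G" %in% names(entries) && entries[["G"]] > min(entries)) {
    stop("Asn-Gly must have the minimum half-time in the table", call. = FALSE)
  }
  structure(entries, source_label = source_label, class = "halftime_table")
}

#' @export
print.halftime_table <- function(x, ...) {
  cat(sprintf("Dipeptide deamidation half-time table (%d N+1 residues)\n",
              length(x)))
  if (nzchar(attr(x, "source_label"))) {
    cat("source:", attr(x, "source_label"), "\n")
  }
  print(sort(unclass(x)))
  invisible(x)
}

#' Intrinsic deamidation half-time for a site
#'
#' Looks up the half-time of the Asn-(N+1) dipeptide for a site's N+1
#' residue. With `strict = TRUE` (the default) a missing residue is an
#' error; with `strict = FALSE` it yields `NA`, which downstream code
#' reports as a missing half-time rather than silently dropping the site
#' (relevant for Asn-Pro and non-standard N+1 residues).
#'
#' @param n_plus_1 One-letter code of the residue C-terminal to the Asn.
#' @param table A `halftime_table`.
#' @param strict Error on a missing residue?
#' @return Half-time in days (or `NA_real_` when absent and not strict).
#' @export
intrinsic_half_time <- function(n_plus_1, table, strict = TRUE) {
  stopifnot(inherits(table, "halftime_table"))
  n_plus_1 <- toupper(as.character(n_plus_1))
  out <- unclass(table)[n_plus_1]
  missing <- is.na(out)
  if (strict && any(missing)) {
    stop(sprintf("no intrinsic half-time for N+1 residue '%s'",
                 n_plus_1[which(missing)[1L]]), call. = FALSE)
  }
  unname(out)
}
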