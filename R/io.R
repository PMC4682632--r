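# FASTA ingestion and report rendering.

#' Read a multi-FASTA file of protein sequences
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. Record ids are the
#' first whitespace-delimited token of each header, sequences are
#' upper-cased, and `*` stop characters are stripped with a warning.
#' Duplicate ids and empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("FASTA file contains no records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA id '%s'", dup[1L]), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("'*' stop characters stripped from sequences", call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop(sprintf("FASTA record '%s' is empty", ids[empty[1L]]), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

# report formatting: display columns at 3 significant figures, with full
# precision preserved in companion *_exact columns
format_site_table <- function(df) {
  out <- df
  for (col in intersect(c("t50_sequence", "t50_ngome"), names(df))) {
    out[[paste0(col, "_exact")]] <- df[[col]]
  }
  for (col in intersect(c("t50_sequence", "t50_ngome", "protection",
                          "pct_at_horizon", "D"), names(out))) {
    out[[col]] <- signif(out[[col]], 3)
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Render the standard report tables for one protein
#'
#' Writes the four site tables and the per-position track file for a
#' prediction: real asparagines sorted by position (table 1) and by
#' predicted half-time (table 2), then the hypothetical per-position scan
#' with the same two orders (tables 3 and 4), and finally a track file with
#' `log10 t50` (predicted and intrinsic) and the protection factor at every
#' internal position — the data behind a per-residue profile plot. Tables 1
#' and 2 (and 3 and 4) contain identical row sets in different orders. All
#' outputs are plain TSV without timestamps, so a rerun on the same input
#' is byte-identical.
#'
#' @param prediction An `ngome_prediction` from [predict_protein()].
#' @param scan The matching data frame from [hypothetical_scan()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, defaulting to the protein id.
#' @return Invisibly, a named character vector of the five file paths.
#' @export
render_reports <- function(prediction, scan, dir,
                           prefix = prediction$protein_id) {
  stopifnot(inherits(prediction, "ngome_prediction"), is.data.frame(scan))
  if (!nzchar(prefix)) prefix <- "protein"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sites <- format_site_table(prediction$sites)
  scan_f <- format_site_table(scan)
  tracks <- data.frame(
    position = scan$position,
    is_real_asn = scan$is_real_asn,
    log10_t50_ngome = signif(log10(scan$t50_ngome), 6),
    log10_t50_sequence = signif(log10(scan$t50_sequence), 6),
    protection = signif(scan$protection, 6)
  )
  paths <- c(
    table1 = file.path(dir, paste0(prefix, "_sites_by_position.tsv")),
    table2 = file.path(dir, paste0(prefix, "_sites_by_t50.tsv")),
    table3 = file.path(dir, paste0(prefix, "_scan_by_position.tsv")),
    table4 = file.path(dir, paste0(prefix, "_scan_by_t50.tsv")),
    tracks = file.path(dir, paste0(prefix, "_tracks.tsv"))
  )
  write_tsv(sites[order(sites$position), , drop = FALSE], paths[["table1"]])
  write_tsv(sites[order(prediction$sites$t50_ngome, sites$position), ,
                  drop = FALSE], paths[["table2"]])
  write_tsv(scan_f[order(scan_f$position), , drop = FALSE], paths[["table3"]])
  write_tsv(scan_f[order(scan$t50_ngome, scan$position), , drop = FALSE],
            paths[["table4"]])
  write_tsv(tracks, paths[["tracks"]])
  invisible(paths)
}
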