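# Structural profiles: per-residue helix flags and disorder scores, either
# parsed from external predictor output or computed by bundled fallbacks.

#' Build a structural profile from secondary-structure and disorder tracks
#'
#' Combines a three-state secondary-structure track (H/E/C) and a disorder
#' track into the per-residue profile the deamidation model consumes. Only
#' the helix state protects: H maps to flag 1, while E and C both map to 0
#' (strand propensity was evaluated during model development but carried no
#' predictive signal for deamidation).
#'
#' @param sequence Protein sequence the tracks describe.
#' @param ss A `ss_track` from [parse_horizontal_ss()] or [fallback_helix()].
#' @param disorder A `disorder_track` from [parse_disorder_table()] or
#'   [fallback_disorder()].
#' @param sequence_id Identifier recorded in the profile.
#' @return An object of class `ngome_profile`: list with `sequence_id`,
#'   `helix` (integer 0/1 per residue), `disorder` (numeric in \[0,1\] per
#'   residue) and `provenance` (`"parsed-external"` unless either track
#'   came from a fallback predictor, then `"fallback"`).
#' @export
build_profile <- function(sequence, ss, disorder, sequence_id = "") {
  sequence <- validate_sequence(sequence)
  L <- nchar(sequence)
  stopifnot(inherits(ss, "ss_track"), inherits(disorder, "disorder_track"))
  if (length(ss$states) != L) {
    stop(sprintf("secondary-structure track length %d does not match sequence length %d",
                 length(ss$states), L), call. = FALSE)
  }
  if (length(disorder$scores) != L) {
    stop(sprintf("disorder track length %d does not match sequence length %d",
                 length(disorder$scores), L), call. = FALSE)
  }
  prov <- if (identical(ss$source, "fallback") || identical(disorder$source, "fallback")) {
    "fallback"
  } else {
    "parsed-external"
  }
  structure(
    list(sequence_id = sequence_id,
         helix = as.integer(ss$states == "H"),
         disorder = as.numeric(disorder$scores),
         provenance = prov),
    class = "ngome_profile"
  )
}

#' @export
print.ngome_profile <- function(x, ...) {
  cat(sprintf("Structural profile '%s': %d residues, %d in helix, mean disorder %.2f (%s)\n",
              x$sequence_id, length(x$helix), sum(x$helix),
              mean(x$disorder), x$provenance))
  invisible(x)
}

check_profile <- function(profile, sequence = NULL) {
  stopifnot(inherits(profile, "ngome_profile"))
  if (length(profile$helix) != length(profile$disorder)) {
    stop("helix and disorder tracks differ in length", call. = FALSE)
  }
  if (any(!profile$helix %in% c(0L, 1L))) {
    stop("helix flags must be 0 or 1", call. = FALSE)
  }
  if (any(is.na(profile$disorder)) ||
      any(profile$disorder < 0 | profile$disorder > 1)) {
    stop("disorder scores must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(sequence) && length(profile$helix) != nchar(sequence)) {
    stop(sprintf("profile length %d does not match sequence length %d",
                 length(profile$helix), nchar(sequence)), call. = FALSE)
  }
  invisible(profile)
}

#' Parse a horizontal secondary-structure string
#'
#' Reads the single-line (possibly wrapped) H/E/C dialect used by common
#' secondary-structure predictors. Whitespace is stripped and `-` (no
#' prediction) is read as coil.
#'
#' @param text Character scalar (may contain newlines) or character vector
#'   of lines.
#' @param source Provenance tag stored in the track.
#' @return An object of class `ss_track`: list with `states` (character
#'   vector over \{H,E,C\}) and `source`.
#' @export
parse_horizontal_ss <- function(text, source = "parsed-external") {
  text <- paste(text, collapse = "")
  text <- gsub("[[:space:]]", "", toupper(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  chars[chars == "-"] <- "C"
  bad <- which(!chars %in% c("H", "E", "C"))
  if (length(bad)) {
    stop(sprintf("invalid secondary-structure character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(list(states = chars, source = source), class = "ss_track")
}

#' Write a secondary-structure track as a horizontal string
#'
#' @param track A `ss_track`.
#' @param width Line-wrap width; `Inf` for a single line.
#' @return Character scalar.
#' @export
write_horizontal_ss <- function(track, width = Inf) {
  stopifnot(inherits(track, "ss_track"))
  s <- paste(track$states, collapse = "")
  if (is.finite(width) && nchar(s) > width) {
    starts <- seq(1L, nchar(s), by = width)
    s <- paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               collapse = "\n")
  }
  s
}

#' Parse a per-residue disorder score table
#'
#' Reads the conventional three-column per-residue output of disorder
#' predictors: index, residue, score. `#` comment lines are allowed, rows
#' may be in any order but indices must be contiguous from 1, and scores
#' must already lie in \[0,1\] — out-of-range scores are an error, never
#' clamped. If a reference sequence is supplied the residue column is
#' checked against it.
#'
#' @param text Character scalar or vector of lines, or a file path via
#'   [readLines()] upstream.
#' @param sequence Optional reference sequence for residue validation.
#' @param source Provenance tag.
#' @return An object of class `disorder_track`: list with `scores` and
#'   `source`.
#' @export
parse_disorder_table <- function(text, sequence = NULL, source = "parsed-external") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("disorder table is empty", call. = FALSE)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("disorder table row %d has fewer than 3 fields",
                 which(nf < 3L)[1L]), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  res <- toupper(vapply(fields, `[[`, "", 2L))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(idx)) || any(is.na(score))) {
    stop("disorder table has non-numeric index or score", call. = FALSE)
  }
  ord <- order(idx)
  idx <- idx[ord]; res <- res[ord]; score <- score[ord]
  if (!identical(idx, seq_along(idx))) {
    stop("disorder table indices are not contiguous from 1", call. = FALSE)
  }
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range)) {
    stop(sprintf("disorder score %.3f at index %d outside [0, 1]",
                 score[out_of_range[1L]], idx[out_of_range[1L]]), call. = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- validate_sequence(sequence)
    chars <- seq_chars(sequence)
    if (length(chars) != length(res)) {
      stop(sprintf("disorder table has %d rows but sequence has %d residues",
                   length(res), length(chars)), call. = FALSE)
    }
    mism <- which(res != chars)
    if (length(mism)) {
      stop(sprintf("disorder table residue '%s' at index %d does not match sequence residue '%s'",
                   res[mism[1L]], mism[1L], chars[mism[1L]]), call. = FALSE)
    }
  }
  structure(list(scores = score, source = source), class = "disorder_track")
}

# ---- bundled fallback predictors --------------------------------------------
# Deterministic, dependency-free stand-ins for external secondary-structure
# and disorder services. Profiles built from them carry provenance
# "fallback"; case-study-grade fidelity requires ingesting real predictor
# output files instead.

read_propensity_table <- function(path = system.file("extdata", "helix_propensity.tsv",
                                                     package = "ngome")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$propensity), toupper(df$residue))
}

# sliding-window mean with symmetric shrinkage at the termini
window_mean <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1L))
}

#' Fallback helix predictor
#'
#' Deterministic propensity-smoothing predictor used when no external
#' secondary-structure file is supplied: per-residue Chou-Fasman-style
#' helix propensities are averaged over a sliding window and positions
#' whose window mean exceeds the cutoff are called H, all others C. Windows
#' shrink symmetrically at the termini. This is a coarse approximation of a
#' modern alignment-based predictor and is tagged as such in the profile
#' provenance.
#'
#' @param sequence Protein sequence.
#' @param window Odd window length in residues.
#' @param cutoff Window-mean propensity above which a residue is called
#'   helical (1.0 is an indifferent former on the Chou-Fasman scale).
#' @param propensities Named vector of per-residue propensities; defaults
#'   to the packaged table. Letters absent from the table (non-standard
#'   codes) count as propensity 1.
#' @return A `ss_track` with source `"fallback"`.
#' @export
fallback_helix <- function(sequence, window = 7L, cutoff = 1.05,
                           propensities = read_propensity_table()) {
  sequence <- validate_sequence(sequence)
  stopifnot(window >= 1L, window %% 2L == 1L)
  chars <- seq_chars(sequence)
  p <- unname(propensities[chars])
  p[is.na(p)] <- 1
  m <- window_mean(p, (window - 1L) %/% 2L)
  structure(list(states = ifelse(m > cutoff, "H", "C"), source = "fallback"),
            class = "ss_track")
}

# Kyte-Doolittle hydrophobicity
KD_SCALE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)

#' Fallback disorder predictor
#'
#' Deterministic charge-hydropathy predictor used when no external disorder
#' file is supplied. For each residue an unfoldability index
#' `u = 2.785 * <hydrophobicity> - |<net charge>| - 1.151` is computed over
#' a 21-residue window (hydrophobicity on the Kyte-Doolittle scale rescaled
#' to \[0,1\]; K/R charge +1, D/E charge -1), with symmetric window
#' shrinkage at the termini. Positive `u` marks foldable segments, so the
#' disorder score is the logistic squash `1 / (1 + exp(k * u))`, which maps
#' `u = 0` to 0.5 and stays in \[0,1\].
#'
#' @param sequence Protein sequence.
#' @param window Odd window length (21 residues by default, the window
#'   scale at which disorder predictors assess local interactions).
#' @param steepness Logistic steepness `k`.
#' @return A `disorder_track` with source `"fallback"`.
#' @export
fallback_disorder <- function(sequence, window = 21L, steepness = 6) {
  sequence <- validate_sequence(sequence)
  stopifnot(window >= 1L, window %% 2L == 1L)
  chars <- seq_chars(sequence)
  hyd <- (unname(KD_SCALE[chars]) + 4.5) / 9
  hyd[is.na(hyd)] <- 0.5
  chg <- ifelse(chars %in% c("K", "R"), 1, ifelse(chars %in% c("D", "E"), -1, 0))
  half <- (window - 1L) %/% 2L
  u <- 2.785 * window_mean(hyd, half) - abs(window_mean(chg, half)) - 1.151
  structure(list(scores = 1 / (1 + exp(steepness * u)), source = "fallback"),
            class = "disorder_track")
}

#' Build a profile using the bundled fallback predictors
#'
#' Convenience wrapper: [fallback_helix()] + [fallback_disorder()] +
#' [build_profile()].
#'
#' @inheritParams build_profile
#' @return An `ngome_profile` with provenance `"fallback"`.
#' @export
fallback_profile <- function(sequence, sequence_id = "") {
  build_profile(sequence, fallback_helix(sequence), fallback_disorder(sequence),
                sequence_id = sequence_id)
}
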