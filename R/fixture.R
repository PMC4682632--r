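# Synthetic fixture generator: sequences with planted Asn sites in
# controlled structural contexts, matching tracks, and labels drawn from
# the model itself plus label noise. Everything downstream of the seed is
# deterministic, so fixtures regenerate bit-identically.

FIXTURE_CONTEXTS <- c("disordered_coil", "ordered_helix", "ordered_coil")

# disorder-score band sampled per context: coil outside structure is
# disordered (D in [0.7, 1]); structured contexts are ordered (D in [0, 0.3])
context_disorder <- function(context, n) {
  switch(context,
         disordered_coil = stats::runif(n, 0.7, 1),
         ordered_helix = stats::runif(n, 0, 0.3),
         ordered_coil = stats::runif(n, 0, 0.3),
         stop("unknown context ", context, call. = FALSE))
}

#' Generate a synthetic deamidation benchmark
#'
#' Emits `n_sequences` random protein sequences, each carrying exactly one
#' planted internal Asn-X site inside a region of controlled structural
#' context, together with helix/disorder tracks consistent with that
#' context and binary deamidation labels derived from the model itself:
#' a site is labeled positive when its model half-time under the planted
#' weights is at most `cutoff_days`, and each label is then flipped with
#' probability `label_noise`. Contexts are `disordered_coil` (H = 0,
#' D ~ U(0.7, 1): unprotected), `ordered_helix` (H = 1, D ~ U(0, 0.3)) and
#' `ordered_coil` (H = 0, D ~ U(0, 0.3)); background positions are coil
#' with intermediate disorder. The N+1 residue is drawn uniformly from the
#' half-time table, so intrinsic half-times span the full dynamic range.
#'
#' Because the labels come from the same functional form the trainer fits,
#' [grid_train()] on a fixture is a parameter-recovery experiment with a
#' known ground truth.
#'
#' @param n_sequences Number of sequences.
#' @param length Residues per sequence (at least 11).
#' @param context_mix Named fractions over the three contexts; must sum
#'   to 1.
#' @param label_noise Per-label flip probability in \[0, 0.5).
#' @param weights Planted protection weights.
#' @param table Half-time table the labels are computed from.
#' @param cutoff_days Half-time cutoff separating positive from negative
#'   labels. The default (800 days) places the label boundary inside the
#'   intrinsic half-time ladder in all three structural contexts once
#'   protection is applied, so that both weights are identifiable from the
#'   labels — a well-posedness requirement for parameter-recovery
#'   experiments.
#' @param seed Integer seed (required).
#' @return List of class `ngome_fixture`: `sequences` (named character
#'   vector), `profiles` (named list of `ngome_profile`, provenance
#'   `"synthetic"`), `sites` (data frame `protein_id`, `position`,
#'   `n_plus_1`, `context`, `H`, `D`, `t50_sequence`, `t50_model`, `label`,
#'   `flipped`) and `params`.
#' @export
generate_fixture <- function(n_sequences = 300L, length = 80L,
                             context_mix = c(disordered_coil = 1 / 3,
                                             ordered_helix = 1 / 3,
                                             ordered_coil = 1 / 3),
                             label_noise = 0.05,
                             weights = ngome_weights(wH = 1, wO = 3),
                             table = read_halftime_table(),
                             cutoff_days = 800, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_sequences >= 1L, length >= 11L,
            label_noise >= 0, label_noise < 0.5)
  if (is.null(names(context_mix)) ||
      !all(names(context_mix) %in% FIXTURE_CONTEXTS) ||
      any(context_mix < 0) || abs(sum(context_mix) - 1) > 1e-8) {
    stop("context_mix must be named fractions over the three contexts summing to 1",
         call. = FALSE)
  }
  background <- setdiff(AA_STANDARD, "N")  # planted Asn is the only Asn
  n_plus_1_pool <- setdiff(names(table), "N")  # keep exactly one site/sequence
  ids <- sprintf("synth_%04d", seq_len(n_sequences))

  with_seed(seed, {
    contexts <- sample(names(context_mix), n_sequences, replace = TRUE,
                       prob = context_mix)
    sequences <- character(n_sequences)
    profiles <- vector("list", n_sequences)
    pos <- integer(n_sequences); n1s <- character(n_sequences)
    Hs <- integer(n_sequences); Ds <- numeric(n_sequences)
    flips <- logical(n_sequences)
    for (i in seq_len(n_sequences)) {
      chars <- sample(background, length, replace = TRUE)
      p <- sample(5:(length - 4L), 1L)
      n1 <- sample(n_plus_1_pool, 1L)
      chars[p] <- "N"; chars[p + 1L] <- n1
      win <- max(1L, p - 3L):min(length, p + 3L)
      helix <- integer(length)
      disorder <- stats::runif(length, 0.3, 0.7)  # background: ambiguous coil
      if (contexts[i] == "ordered_helix") helix[win] <- 1L
      disorder[win] <- context_disorder(contexts[i], base::length(win))
      sequences[i] <- paste(chars, collapse = "")
      profiles[[i]] <- structure(
        list(sequence_id = ids[i], helix = helix, disorder = disorder,
             provenance = "synthetic"),
        class = "ngome_profile")
      pos[i] <- p; n1s[i] <- n1; Hs[i] <- helix[p]; Ds[i] <- disorder[p]
      flips[i] <- stats::runif(1L) < label_noise
    }
    t50_seq <- intrinsic_half_time(n1s, table)
    t50_model <- t50_seq * protection_factor(Hs, Ds, weights)
    labs <- xor(t50_model <= cutoff_days, flips)
    structure(
      list(sequences = stats::setNames(sequences, ids),
           profiles = stats::setNames(profiles, ids),
           sites = data.frame(
             protein_id = ids, position = pos, n_plus_1 = n1s,
             context = contexts, H = Hs, D = Ds,
             t50_sequence = t50_seq, t50_model = t50_model,
             label = ifelse(labs, "positive", "negative"), flipped = flips,
             stringsAsFactors = FALSE),
           params = list(n_sequences = n_sequences, length = length,
                         context_mix = context_mix, label_noise = label_noise,
                         weights = weights, cutoff_days = cutoff_days,
                         seed = seed)),
      class = "ngome_fixture")
  })
}

#' Write a fixture to disk
#'
#' Emits `sequences.fasta`, a combined per-residue `tracks.tsv`
#' (`protein_id`, `position`, `residue`, `ss_state`, `disorder`), the
#' labeled-site table `sites.tsv`, and `params.txt`. Output contains no
#' timestamps: identical fixtures write identical bytes.
#'
#' @param fixture An `ngome_fixture`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "ngome_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(paste0(">", names(fixture$sequences), "\n", fixture$sequences),
             fasta)
  tracks <- do.call(rbind, lapply(names(fixture$profiles), function(id) {
    pr <- fixture$profiles[[id]]
    data.frame(protein_id = id,
               position = seq_along(pr$helix),
               residue = seq_chars(fixture$sequences[[id]]),
               ss_state = ifelse(pr$helix == 1L, "H", "C"),
               disorder = signif(pr$disorder, 6),
               stringsAsFactors = FALSE)
  }))
  tracks_path <- write_tsv(tracks, file.path(dir, "tracks.tsv"))
  sites <- fixture$sites
  sites$D <- signif(sites$D, 6)
  sites$t50_sequence <- signif(sites$t50_sequence, 6)
  sites$t50_model <- signif(sites$t50_model, 6)
  sites_path <- write_tsv(sites, file.path(dir, "sites.tsv"))
  params <- fixture$params
  params_path <- file.path(dir, "params.txt")
  writeLines(c(
    sprintf("n_sequences=%d", params$n_sequences),
    sprintf("length=%d", params$length),
    sprintf("context_mix=%s",
            paste(sprintf("%s:%g", names(params$context_mix),
                          params$context_mix), collapse = ",")),
    sprintf("label_noise=%g", params$label_noise),
    sprintf("wH=%g", params$weights[["wH"]]),
    sprintf("wO=%g", params$weights[["wO"]]),
    sprintf("cutoff_days=%g", params$cutoff_days),
    sprintf("seed=%d", params$seed)
  ), params_path)
  invisible(c(fasta = fasta, tracks = tracks_path, sites = sites_path,
              params = params_path))
}
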