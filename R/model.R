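# The deamidation model: intrinsic half-time times a structural protection
# factor, plus the derived per-site and per-protein quantities.

#' Structural protection factor
#'
#' Fold slow-down of deamidation imposed by local structure:
#' `P = exp(wH * H + wO * (1 - D))`, where `H` is the helix flag and `D`
#' the disorder score at the asparagine. For non-negative weights `P >= 1`,
#' with equality only for a fully disordered coil (`H = 0`, `D = 1`).
#'
#' @param H Helix flag(s), 0 or 1.
#' @param D Disorder score(s) in \[0,1\].
#' @param weights Named vector with `wH` and `wO`, see [ngome_weights()].
#' @return Dimensionless protection factor(s).
#' @examples
#' protection_factor(0, 1)                 # unprotected coil -> 1
#' protection_factor(1, 0)                 # helical, fully ordered
#' @export
protection_factor <- function(H, D, weights = ngome_weights()) {
  if (any(!H %in% c(0, 1))) stop("H must be 0 or 1", call. = FALSE)
  if (any(is.na(D)) || any(D < 0 | D > 1)) {
    stop("disorder score D must lie in [0, 1]", call. = FALSE)
  }
  weights <- ngome_weights(weights[["wH"]], weights[["wO"]])
  exp(weights[["wH"]] * H + weights[["wO"]] * (1 - D))
}

#' Percent deamidation after a time horizon
#'
#' Assuming first-order (exponential) decay with half-time `t50`, the
#' percentage of molecules deamidated after `t` days is
#' `100 * (1 - 2^(-t / t50))`.
#'
#' @param t50 Half-time(s) in days, positive.
#' @param t Elapsed time in days, non-negative.
#' @return Percentage in \[0, 100).
#' @examples
#' percent_deamidated(10, 10)  # one half-time -> 50
#' percent_deamidated(1, 2)    # two half-times -> 75
#' @export
percent_deamidated <- function(t50, t) {
  if (any(!is.na(t50) & t50 <= 0)) stop("t50 must be positive", call. = FALSE)
  if (any(t < 0)) stop("elapsed time must be non-negative", call. = FALSE)
  100 * (1 - 2^(-t / t50))
}

#' Whole-protein first-deamidation half-time
#'
#' Half-time until the first deamidation event anywhere in the protein,
#' assuming the sites deamidate independently with first-order kinetics.
#' The minimum of independent exponential clocks is exponential with the
#' summed rate, so `t50(Protein) = 1 / sum(1 / t50_i)`. Sites with missing
#' half-times (`NA`) are excluded.
#'
#' @param site_t50s Per-site half-times in days.
#' @return Half-time in days, or `NA_real_` when no usable site remains
#'   (the "no sites" signal, distinct from an error).
#' @examples
#' protein_half_time(c(10, 10))   # 5: two equal clocks
#' protein_half_time(c(1, 1000))  # ~1: dominated by the fast site
#' @export
protein_half_time <- function(site_t50s) {
  site_t50s <- site_t50s[!is.na(site_t50s)]
  if (!length(site_t50s)) return(NA_real_)
  if (any(site_t50s <= 0)) stop("site half-times must be positive", call. = FALSE)
  1 / sum(1 / site_t50s)
}

#' Classify a site against a half-time threshold
#'
#' A site is called positive (deamidation-prone) when its predicted
#' half-time is at or below the threshold; the tie goes to positive, the
#' conservative call for a degradation-risk screen. Thresholds are
#' typically set at a target false-positive rate via [threshold_at_fpr()].
#'
#' @param t50_pred Predicted half-time(s) in days.
#' @param threshold Positive threshold in days.
#' @return `"positive"` or `"negative"` per site (`NA` for missing t50).
#' @export
classify_site <- function(t50_pred, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stop("threshold must be a positive number of days", call. = FALSE)
  }
  ifelse(is.na(t50_pred), NA_character_,
         ifelse(t50_pred <= threshold, "positive", "negative"))
}

# shared worker: per-position prediction given H/D/n+1 already extracted
predict_rows <- function(protein_id, position, n_plus_1, is_sequon, H, D,
                         weights, table, horizon, threshold) {
  t50_seq <- intrinsic_half_time(n_plus_1, table, strict = FALSE)
  P <- protection_factor(H, D, weights)
  t50_pred <- t50_seq * P
  data.frame(
    protein_id = protein_id,
    position = as.integer(position),
    n_plus_1 = n_plus_1,
    is_sequon = is_sequon,
    H = as.integer(H),
    D = as.numeric(D),
    t50_sequence = t50_seq,
    protection = P,
    t50_ngome = t50_pred,
    pct_at_horizon = percent_deamidated(t50_pred, horizon),
    label = if (is.null(threshold)) rep(NA_character_, length(t50_pred))
            else classify_site(t50_pred, threshold),
    stringsAsFactors = FALSE
  )
}

#' Predict deamidation for one or more asparagine sites
#'
#' Evaluates the model at each site: the intrinsic half-time of the
#' Asn/N+1 dipeptide times the protection factor computed from the helix
#' flag and disorder score at the asparagine's own position.
#'
#' @param sites Data frame from [find_asn_sites()] (columns `protein_id`,
#'   `position`, `n_plus_1`, `is_sequon`).
#' @param profile An `ngome_profile` covering the sequence.
#' @param weights Protection weights, see [ngome_weights()].
#' @param table A `halftime_table`.
#' @param horizon Time horizon in days for the percent-deamidation column.
#' @param threshold Optional half-time threshold (days) for the
#'   positive/negative call; when `NULL` the `label` column is `NA`.
#' @return A data frame with one row per site: the site columns plus `H`,
#'   `D`, `t50_sequence`, `protection`, `t50_ngome` (days),
#'   `pct_at_horizon` and `label`. Sites whose N+1 residue has no table
#'   entry (e.g. Pro, non-standard codes) carry `NA` half-times.
#' @export
predict_sites <- function(sites, profile, weights = ngome_weights(),
                          table = read_halftime_table(), horizon = 2,
                          threshold = NULL) {
  check_profile(profile)
  stopifnot(is.data.frame(sites),
            all(c("position", "n_plus_1") %in% names(sites)))
  if (nrow(sites) && max(sites$position) > length(profile$helix)) {
    stop("profile does not cover all site positions", call. = FALSE)
  }
  if (!nrow(sites)) {
    return(predict_rows(character(), integer(), character(), logical(),
                        integer(), numeric(), weights, table, horizon, threshold))
  }
  predict_rows(
    protein_id = if ("protein_id" %in% names(sites)) sites$protein_id else "",
    position = sites$position,
    n_plus_1 = sites$n_plus_1,
    is_sequon = if ("is_sequon" %in% names(sites)) sites$is_sequon else NA,
    H = profile$helix[sites$position],
    D = profile$disorder[sites$position],
    weights = weights, table = table, horizon = horizon, threshold = threshold
  )
}

#' Predict deamidation for a whole protein
#'
#' Runs [find_asn_sites()] and [predict_sites()] on a sequence and composes
#' the per-site half-times into the whole-protein first-deamidation
#' half-time via [protein_half_time()].
#'
#' @inheritParams predict_sites
#' @param sequence Protein sequence.
#' @param profile An `ngome_profile`; defaults to the bundled fallback
#'   predictors (provenance `"fallback"`).
#' @param protein_id Identifier.
#' @return A list of class `ngome_prediction`: `protein_id`, `sites` (the
#'   per-site data frame), `t50_protein` (days; `NA` when the protein has
#'   no internal Asn with a usable half-time) and `provenance`.
#' @examples
#' p <- predict_protein("MANGSANAKQLV", protein_id = "demo")
#' p$sites[, c("position", "n_plus_1", "t50_ngome")]
#' @export
predict_protein <- function(sequence, profile = NULL,
                            weights = ngome_weights(),
                            table = read_halftime_table(), horizon = 2,
                            threshold = NULL, protein_id = "") {
  sequence <- validate_sequence(sequence)
  if (is.null(profile)) profile <- fallback_profile(sequence, protein_id)
  check_profile(profile, sequence)
  sites <- find_asn_sites(sequence, protein_id)
  preds <- predict_sites(sites, profile, weights, table, horizon, threshold)
  structure(
    list(protein_id = protein_id,
         sites = preds,
         t50_protein = protein_half_time(preds$t50_ngome),
         provenance = profile$provenance),
    class = "ngome_prediction"
  )
}

#' @export
print.ngome_prediction <- function(x, ...) {
  cat(sprintf("Deamidation prediction for '%s' (%d internal Asn, tracks: %s)\n",
              x$protein_id, nrow(x$sites), x$provenance))
  if (nrow(x$sites)) {
    ord <- order(x$sites$t50_ngome)
    df <- x$sites[ord, c("position", "n_plus_1", "is_sequon", "t50_sequence",
                         "protection", "t50_ngome", "pct_at_horizon")]
    df$t50_sequence <- signif(df$t50_sequence, 3)
    df$protection <- signif(df$protection, 3)
    df$t50_ngome <- signif(df$t50_ngome, 3)
    df$pct_at_horizon <- signif(df$pct_at_horizon, 3)
    print(df, row.names = FALSE)
    cat(sprintf("t50(Protein) = %s days (first deamidation event, independent sites)\n",
                format(signif(x$t50_protein, 3))))
  }
  invisible(x)
}

#' Hypothetical asparagine scan
#'
#' Evaluates the model at every internal position of a sequence as if that
#' position held an asparagine, keeping the wild-type structural tracks and
#' using the actual residue at position+1 as the N+1 residue. This asks
#' where a point mutation introducing an Asn would deamidate. Positions
#' that already hold an Asn are flagged and their rows equal the real
#' predictions.
#'
#' @inheritParams predict_protein
#' @return A data frame as in [predict_sites()] plus a logical
#'   `is_real_asn` column, one row per position 2..L-1.
#' @export
hypothetical_scan <- function(sequence, profile = NULL,
                              weights = ngome_weights(),
                              table = read_halftime_table(), horizon = 2,
                              threshold = NULL, protein_id = "") {
  sequence <- validate_sequence(sequence)
  if (is.null(profile)) profile <- fallback_profile(sequence, protein_id)
  check_profile(profile, sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < 3L) {
    out <- predict_rows(character(), integer(), character(), logical(),
                        integer(), numeric(), weights, table, horizon, threshold)
    out$is_real_asn <- logical(0)
    return(out)
  }
  pos <- 2:(L - 1L)
  # sequon status of the hypothetical N-X-S/T window at each position
  seq_flag <- chars[pos + 1L] != "P" &
    ifelse(pos + 2L <= L, chars[pmin(pos + 2L, L)] %in% c("S", "T"), FALSE)
  out <- predict_rows(
    protein_id = rep(protein_id, length(pos)),
    position = pos,
    n_plus_1 = chars[pos + 1L],
    is_sequon = seq_flag,
    H = profile$helix[pos],
    D = profile$disorder[pos],
    weights = weights, table = table, horizon = horizon, threshold = threshold
  )
  out$is_real_asn <- chars[pos] == "N"
  out
}
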