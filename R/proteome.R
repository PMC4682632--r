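# Proteome-scale batch prediction and the turnover-correlation analysis.

#' Batch deamidation prediction over many sequences
#'
#' Runs [predict_protein()] on every sequence of a set. Structural profiles
#' are taken from `profiles` when supplied (a named list keyed by sequence
#' id) and computed with the bundled fallback predictors otherwise.
#' Per-sequence failures are caught and reported; the run continues.
#'
#' @param sequences Named character vector of protein sequences (names are
#'   the protein ids), e.g. from [read_fasta()].
#' @param profiles Optional named list of `ngome_profile` objects.
#' @inheritParams predict_sites
#' @return List with `proteins` (data frame `protein_id`, `n_sites`,
#'   `t50_protein` in days — `NA` marks a protein with no usable internal
#'   Asn — and `provenance`), `sites` (row-bound per-site predictions) and
#'   `failures` (data frame `protein_id`, `message`).
#' @export
batch_predict <- function(sequences, profiles = NULL,
                          weights = ngome_weights(),
                          table = read_halftime_table(), horizon = 2,
                          threshold = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be a named vector", call. = FALSE)
  }
  proteins <- vector("list", length(sequences))
  sites <- vector("list", length(sequences))
  failures <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    res <- tryCatch(
      predict_protein(sequences[[i]],
                      profile = if (!is.null(profiles)) profiles[[id]] else NULL,
                      weights = weights, table = table, horizon = horizon,
                      threshold = threshold, protein_id = id),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(protein_id = id, message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    proteins[[i]] <- data.frame(protein_id = id,
                                n_sites = nrow(res$sites),
                                t50_protein = res$t50_protein,
                                provenance = res$provenance,
                                stringsAsFactors = FALSE)
    sites[[i]] <- res$sites
  }
  list(proteins = do.call(rbind, proteins),
       sites = do.call(rbind, sites),
       failures = if (length(failures)) do.call(rbind, failures)
                  else data.frame(protein_id = character(),
                                  message = character(),
                                  stringsAsFactors = FALSE))
}

#' Correlate predicted deamidation half-times with protein turnover
#'
#' Pearson correlation between the base-10 logarithm of experimental
#' protein half-lives and the base-10 logarithm of predicted whole-protein
#' deamidation half-times. Only records with a positive experimental
#' half-life and a usable prediction enter the statistic; exclusions are
#' counted so that the filtering is auditable. The p-value comes from the
#' t-distribution transform of r; slope and intercept are from the
#' least-squares fit of log10 t50(Protein) on log10 half-life.
#'
#' @param records Data frame with columns `half_life_minutes`
#'   (experimental, any time unit — the correlation is unit-invariant on
#'   the log scale) and `t50_protein_days` (predicted; `NA` marks proteins
#'   without internal Asn).
#' @return List of class `ngome_correlation`: `n`, `r`, `p_value`, `slope`,
#'   `intercept`, `n_excluded_nonpositive`, `n_excluded_nosites`.
#' @export
turnover_correlation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("half_life_minutes", "t50_protein_days") %in% names(records)))
  no_sites <- !is.finite(records$t50_protein_days) |
    (!is.na(records$t50_protein_days) & records$t50_protein_days <= 0)
  nonpos <- !no_sites &
    (!is.finite(records$half_life_minutes) | records$half_life_minutes <= 0)
  keep <- !no_sites & !nonpos
  if (sum(keep) < 3L) {
    stop("fewer than 3 usable records for the correlation", call. = FALSE)
  }
  x <- log10(records$half_life_minutes[keep])
  y <- log10(records$t50_protein_days[keep])
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(
    list(n = sum(keep),
         r = unname(ct$estimate),
         p_value = ct$p.value,
         slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         n_excluded_nonpositive = sum(nonpos),
         n_excluded_nosites = sum(no_sites)),
    class = "ngome_correlation"
  )
}

#' @export
print.ngome_correlation <- function(x, ...) {
  cat(sprintf("log10-log10 Pearson correlation: r = %.3f (n = %d, p = %.3g)\n",
              x$r, x$n, x$p_value))
  cat(sprintf("  fit: log10 t50(Protein) = %.3f + %.3f * log10 half-life\n",
              x$intercept, x$slope))
  cat(sprintf("  excluded: %d non-positive half-life, %d without usable sites\n",
              x$n_excluded_nonpositive, x$n_excluded_nosites))
  invisible(x)
}

#' Bin a scatter for density visualization
#'
#' Optional export of binned counts on the log10 scale (0.1 log-unit bins
#' by default), the data behind a density-colored turnover scatter plot.
#' The statistic itself is always computed on unbinned values.
#'
#' @param records As in [turnover_correlation()].
#' @param bin_width Bin width in log10 units.
#' @return Data frame `log10_half_life_bin`, `log10_t50_bin`, `count`.
#' @export
turnover_bins <- function(records, bin_width = 0.1) {
  keep <- is.finite(records$half_life_minutes) & records$half_life_minutes > 0 &
    is.finite(records$t50_protein_days) & records$t50_protein_days > 0
  x <- floor(log10(records$half_life_minutes[keep]) / bin_width) * bin_width
  y <- floor(log10(records$t50_protein_days[keep]) / bin_width) * bin_width
  agg <- stats::aggregate(list(count = rep(1L, length(x))),
                          by = list(log10_half_life_bin = x, log10_t50_bin = y),
                          FUN = sum)
  agg[order(agg$log10_half_life_bin, agg$log10_t50_bin), , drop = FALSE]
}
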