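# Dataset curation, ROC/AUC machinery, paired AUC comparison, stratified
# splitting and the grid-search training loop for the protection weights.

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_pos_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative' or logical", call. = FALSE)
  }
  labels == "positive"
}

# Mann-Whitney AUC for oriented scores where SMALLER score = more positive;
# ties count one half. Pure-R reference used outside the training hot loop
# (the compiled .cpp_auc_smaller_positive is its exact counterpart).
auc_smaller_positive <- function(scores, pos) {
  m <- sum(pos); n <- sum(!pos)
  r <- rank(-scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' Build a ROC curve
#'
#' Sweeps every distinct score value as a classification threshold. With
#' the default orientation (`direction = "smaller"`, the natural one for
#' half-times: fast deamidators are the positives) a site is called
#' positive when its score is at or below the threshold. Tied scores are
#' grouped at a single threshold, so the curve moves diagonally through
#' ties and its trapezoidal area equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg` with ties counted one half.
#'
#' @param scores Finite numeric scores (e.g. predicted half-times in days).
#' @param labels `"positive"`/`"negative"` per score, or a logical vector
#'   (`TRUE` = positive). Both classes must be present.
#' @param direction `"smaller"` if small scores indicate positives
#'   (half-times), `"larger"` for the opposite orientation.
#' @return An object of class `ngome_roc`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, anchored at (0,0) and ending at (1,1)),
#'   `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
build_roc <- function(scores, labels, direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  pos <- as_pos_logical(labels)
  if (length(scores) != length(pos)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!any(pos) || all(pos)) {
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  }
  s <- if (direction == "smaller") scores else -scores
  thr <- sort(unique(s))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- vapply(thr, function(t) sum(s[pos] <= t), numeric(1L))
  fp <- vapply(thr, function(t) sum(s[!pos] <= t), numeric(1L))
  pts <- data.frame(
    threshold = c(-Inf, if (direction == "smaller") thr else -thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "ngome_roc")
}

#' @export
print.ngome_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f (%s-is-positive)\n",
              x$n_pos, x$n_neg, x$auc, x$direction))
  invisible(x)
}

# per-observation placement values for the DeLong variance estimate,
# oriented so that larger oriented score = more positive
delong_placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), theta = mean(cmp))
}

#' Compare two correlated AUCs (paired DeLong test)
#'
#' Two-sided test for the difference between the AUCs of two score vectors
#' evaluated on the same labeled sites, using the DeLong covariance
#' estimate for paired ROC curves. Used to ask whether structure-aware
#' half-time predictions rank experimental positives better than
#' sequence-only (intrinsic) half-times.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared labels, see [build_roc()].
#' @param direction Score orientation, as in [build_roc()].
#' @return List with `auc_a`, `auc_b`, `delta`, `z` and `p_value`. When the
#'   two score vectors induce identical placements the difference is 0 with
#'   zero variance and `p_value` is 1.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  pos <- as_pos_logical(labels)
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (!any(pos) || all(pos)) {
    stop("AUC comparison needs both classes", call. = FALSE)
  }
  sa <- if (direction == "smaller") -scores_a else scores_a
  sb <- if (direction == "smaller") -scores_b else scores_b
  pa <- delong_placements(sa, pos)
  pb <- delong_placements(sb, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$theta - pb$theta
  if (v <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v)
  }
  list(auc_a = pa$theta, auc_b = pb$theta, delta = delta, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Half-time threshold at a target false-positive rate
#'
#' Returns the largest half-time threshold whose false-positive rate does
#' not exceed the target — the conservative choice used to define the
#' positive/negative call (default target 5%). If even the smallest
#' observed score exceeds the target FPR, a threshold just below all
#' observed scores (FPR 0) is returned.
#'
#' @param curve An `ngome_roc` built with `direction = "smaller"`.
#' @param target_fpr Target false-positive rate in \[0, 1\].
#' @return Threshold on the score scale (days for half-time scores).
#' @export
threshold_at_fpr <- function(curve, target_fpr = 0.05) {
  stopifnot(inherits(curve, "ngome_roc"))
  if (curve$direction != "smaller") {
    stop("threshold_at_fpr expects a smaller-is-positive curve", call. = FALSE)
  }
  if (is.na(target_fpr) || target_fpr < 0 || target_fpr > 1) {
    stop("target_fpr must lie in [0, 1]", call. = FALSE)
  }
  pts <- curve$points[is.finite(curve$points$threshold), ]
  if (!nrow(pts)) stop("empty ROC curve", call. = FALSE)
  ok <- pts$threshold[pts$fpr <= target_fpr]
  if (length(ok)) return(max(ok))
  m <- min(pts$threshold)
  m - max(abs(m), 1) * 1e-9
}

# stratified split of label vector using the current RNG; returns logical
# "in test set"
strat_split_idx <- function(pos, test_fraction) {
  in_test <- logical(length(pos))
  for (cls in unique(pos)) {
    idx <- which(pos == cls)
    n_test <- round(length(idx) * test_fraction)
    if (n_test == 0L || n_test == length(idx)) {
      stop("too few members of a class to stratify", call. = FALSE)
    }
    in_test[sample(idx, n_test)] <- TRUE
  }
  in_test
}

#' Stratified train/test split
#'
#' Splits a labeled site table so that both parts keep the class
#' proportions of the full dataset as closely as possible (within one site
#' per class, by rounding). The split is a pure function of the seed.
#'
#' @param dataset Data frame with a `label` column
#'   (`"positive"`/`"negative"`).
#' @param test_fraction Fraction assigned to the test set, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames; their union is the
#'   input and their intersection is empty.
#' @export
stratified_split <- function(dataset, test_fraction = 0.5, seed) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  pos <- as_pos_logical(dataset$label)
  if (!any(pos) || all(pos)) stop("dataset needs both classes", call. = FALSE)
  in_test <- with_seed(seed, strat_split_idx(pos, test_fraction))
  list(train = dataset[!in_test, , drop = FALSE],
       test = dataset[in_test, , drop = FALSE])
}

#' Fit protection weights by repeated stratified grid search
#'
#' Reproduces the training protocol behind the published weights: the
#' labeled dataset is split into train/test halves many times (stratified
#' by label); for each split the training-set AUC of the model score
#' `log t50(sequence) + wH*H + wO*(1-D)` (a monotone transform of the
#' predicted half-time, so AUC-equivalent) is evaluated over an exhaustive
#' weight grid and the maximizing pair is selected, ties resolved to the
#' lexicographically smallest `(wH, wO)`. The reported weights are the
#' arithmetic mean of the per-split selections, and each split also records
#' whether the fitted model beats sequence-only scoring on the held-out
#' test AUC.
#'
#' @param dataset Data frame with columns `label`, `H`, `D` and
#'   `t50_sequence` (feature-complete labeled sites).
#' @param grid_wh,grid_wo Numeric grids of candidate weights (non-negative,
#'   ascending).
#' @param n_splits Number of random stratified splits.
#' @param test_fraction Held-out fraction per split.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return An object of class `ngome_train`: list with `per_split` (data
#'   frame: split, wH, wO, train AUC, test AUCs for the model and for
#'   sequence-only scoring), `weights` (named mean vector), `wins` (splits
#'   where the model's test AUC strictly exceeds sequence-only), and
#'   `n_splits`.
#' @export
grid_train <- function(dataset,
                       grid_wh = seq(0, 6, by = 0.1),
                       grid_wo = seq(0, 6, by = 0.1),
                       n_splits = 100L, test_fraction = 0.5, seed = 1L) {
  stopifnot(is.data.frame(dataset),
            all(c("label", "H", "D", "t50_sequence") %in% names(dataset)))
  if (!length(grid_wh) || !length(grid_wo) ||
      any(grid_wh < 0) || any(grid_wo < 0)) {
    stop("weight grids must be non-empty and non-negative", call. = FALSE)
  }
  if (any(is.na(dataset$t50_sequence)) || any(dataset$t50_sequence <= 0)) {
    stop("t50_sequence features must be positive and complete", call. = FALSE)
  }
  grid_wh <- sort(unique(grid_wh)); grid_wo <- sort(unique(grid_wo))
  pos <- as_pos_logical(dataset$label)
  if (!any(pos) || all(pos)) stop("dataset needs both classes", call. = FALSE)
  logt <- log(dataset$t50_sequence)
  H <- as.numeric(dataset$H)
  od <- 1 - as.numeric(dataset$D)

  per_split <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_splits), function(k) {
      in_test <- strat_split_idx(pos, test_fraction)
      tr <- !in_test
      sel <- .cpp_grid_argmax(logt[tr], H[tr], od[tr], pos[tr],
                              grid_wh, grid_wo)
      te <- in_test
      score_model <- logt[te] + sel[1L] * H[te] + sel[2L] * od[te]
      data.frame(
        split = k, wH = sel[1L], wO = sel[2L], train_auc = sel[3L],
        test_auc_model = .cpp_auc_smaller_positive(score_model, pos[te]),
        test_auc_sequence = .cpp_auc_smaller_positive(logt[te], pos[te])
      )
    }))
  })
  structure(
    list(per_split = per_split,
         weights = c(wH = mean(per_split$wH), wO = mean(per_split$wO)),
         wins = sum(per_split$test_auc_model > per_split$test_auc_sequence),
         n_splits = n_splits,
         grid_wh = grid_wh, grid_wo = grid_wo),
    class = "ngome_train"
  )
}

#' @export
print.ngome_train <- function(x, ...) {
  cat(sprintf("Grid training over %d stratified splits\n", x$n_splits))
  cat(sprintf("  averaged weights: wH = %.3f, wO = %.3f\n",
              x$weights[["wH"]], x$weights[["wO"]]))
  cat(sprintf("  model beat sequence-only on test AUC in %d/%d splits\n",
              x$wins, x$n_splits))
  cat(sprintf("  mean test AUC: model %.4f, sequence-only %.4f\n",
              mean(x$per_split$test_auc_model),
              mean(x$per_split$test_auc_sequence)))
  invisible(x)
}

#' Curate raw deamidation evidence into labeled sites
#'
#' Applies the dataset rules used to assemble the training set. Records are
#' dropped when measured outside near-physiological conditions (pH outside
#' `ph_range`, temperature above `max_temperature` Kelvin) or when the
#' sample age is unknown (natural-source material of indeterminate age
#' cannot anchor kinetics). Of the remainder, a site is labeled positive
#' when deamidation was unequivocally observed and any quantitative data
#' agree (conversion at least `min_conversion` percent, half-time below
#' `halftime_cut` days); negative when deamidation was tested for and
#' absent, or the half-time exceeds `halftime_cut` days. Records meeting
#' both criteria are flagged contradictory and excluded; records meeting
#' neither are dropped as insufficient.
#'
#' @param records Data frame with columns `protein_id`, `position`, `ph`,
#'   `temperature_k`, `conversion_percent`, `half_time_days`,
#'   `deamidation_observed` (logical, `NA` = not directly tested),
#'   `sample_age_known` (logical; `NA` treated as known, i.e. recombinant
#'   material), and optionally `n_plus_1` and `source`.
#' @param ph_range Acceptable pH window (numeric length 2).
#' @param max_temperature Maximum temperature in Kelvin.
#' @param min_conversion Minimum conversion percent for a positive call.
#' @param halftime_cut Half-time cut in days separating positives
#'   (`< halftime_cut`) from negatives (`> halftime_cut`).
#' @return List with `sites` (data frame `protein_id`, `position`,
#'   `n_plus_1`, `label`) and `dispositions` (one row per input record:
#'   `protein_id`, `position`, `disposition`, `reason`). Every input record
#'   appears in exactly one disposition.
#' @export
curate_records <- function(records, ph_range = c(6.5, 8.5),
                           max_temperature = 313, min_conversion = 50,
                           halftime_cut = 100) {
  need <- c("protein_id", "position", "ph", "temperature_k",
            "conversion_percent", "half_time_days", "deamidation_observed",
            "sample_age_known")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  disposition <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (is.na(r$ph) || is.na(r$temperature_k)) {
      disposition[i] <- "dropped"; reason[i] <- "missing-conditions"; next
    }
    if (r$ph < ph_range[1] || r$ph > ph_range[2]) {
      disposition[i] <- "dropped"; reason[i] <- "ph-out-of-range"; next
    }
    if (r$temperature_k > max_temperature) {
      disposition[i] <- "dropped"; reason[i] <- "temperature-above-limit"; next
    }
    if (isFALSE(r$sample_age_known)) {
      disposition[i] <- "dropped"; reason[i] <- "unknown-sample-age"; next
    }
    quant_ok <- (is.na(r$conversion_percent) || r$conversion_percent >= min_conversion) &&
      (is.na(r$half_time_days) || r$half_time_days < halftime_cut)
    is_pos <- isTRUE(r$deamidation_observed) && quant_ok
    is_neg <- isFALSE(r$deamidation_observed) ||
      (!is.na(r$half_time_days) && r$half_time_days > halftime_cut)
    if (is_pos && is_neg) {
      disposition[i] <- "dropped"; reason[i] <- "contradictory-evidence"
    } else if (is_pos) {
      disposition[i] <- "positive"; reason[i] <- "deamidation-observed"
    } else if (is_neg) {
      disposition[i] <- "negative"; reason[i] <- "tested-absent-or-slow"
    } else {
      disposition[i] <- "dropped"; reason[i] <- "insufficient-evidence"
    }
  }
  keep <- disposition %in% c("positive", "negative")
  sites <- data.frame(
    protein_id = records$protein_id[keep],
    position = records$position[keep],
    n_plus_1 = if ("n_plus_1" %in% names(records)) records$n_plus_1[keep]
               else NA_character_,
    label = disposition[keep],
    stringsAsFactors = FALSE
  )
  list(sites = sites,
       dispositions = data.frame(protein_id = records$protein_id,
                                 position = records$position,
                                 disposition = disposition,
                                 reason = reason,
                                 stringsAsFactors = FALSE))
}
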