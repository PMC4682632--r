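test_that("ROC handles perfect and inverted separations", {
  labs <- c("positive", "positive", "negative", "negative")
  expect_equal(build_roc(c(1, 2, 3, 4), labs)$auc, 1.0)
  expect_equal(build_roc(c(4, 3, 2, 1), labs)$auc, 0.0)
  expect_error(build_roc(1:3, rep("positive", 3)), "positive and")
  expect_error(build_roc(c(1, Inf, 2), c("positive", "negative", "negative")),
               "finite")
})

test_that("ROC curves are monotone with anchored endpoints", {
  set.seed(5)
  for (i in 1:20) {
    fx <- random_roc_fixture(sample(4:30, 1))
    curve <- build_roc(fx$scores, fx$labels)
    pts <- curve$points
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  }
})

test_that("AUC equals exhaustive Mann-Whitney pair counting", {
  set.seed(7)
  for (i in 1:60) {
    fx <- random_roc_fixture(sample(4:12, 1))
    expect_equal(build_roc(fx$scores, fx$labels)$auc,
                 pair_count_auc(fx$scores, fx$labels))
  }
})

test_that("compiled AUC agrees with the pure-R rank formula", {
  set.seed(8)
  for (i in 1:40) {
    fx <- random_roc_fixture(sample(5:60, 1))
    pos <- fx$labels == "positive"
    expect_equal(ngome:::.cpp_auc_smaller_positive(fx$scores, pos),
                 ngome:::auc_smaller_positive(fx$scores, pos))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  for (i in 1:10) {
    fx <- random_roc_fixture(20)
    a0 <- build_roc(fx$scores, fx$labels)$auc
    expect_equal(build_roc(log(fx$scores + 0.5), fx$labels)$auc, a0)
    expect_equal(build_roc(rank(fx$scores, ties.method = "average"),
                           fx$labels)$auc, a0)
  }
})

test_that("paired AUC comparison matches the reference DeLong implementation", {
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    labs <- c(rep("positive", 15), rep("negative", 25))
    t50_a <- rexp(n, 1 / 50) * ifelse(labs == "positive", 0.3, 1)
    t50_b <- t50_a * exp(rnorm(n, 0, 0.5))
    ours <- compare_auc(t50_a, t50_b, labs)
    ref <- pROC::roc.test(
      pROC::roc(labs, t50_a, levels = c("negative", "positive"),
                direction = ">", quiet = TRUE),
      pROC::roc(labs, t50_b, levels = c("negative", "positive"),
                direction = ">", quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(ours$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("AUC comparison is two-sided, symmetric and null for identical scores", {
  labs <- c("positive", "positive", "negative", "negative")
  expect_equal(compare_auc(c(1, 2, 3, 4), c(1, 2, 3, 4), labs)$p_value, 1.0)
  set.seed(14)
  s1 <- rexp(30); s2 <- rexp(30)
  labs <- sample(c("positive", "negative"), 30, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(compare_auc(s1, s2, labs)$p_value,
               compare_auc(s2, s1, labs)$p_value)
  # discrimination vs uninformative scores: p shrinks as evidence grows
  p_at_n <- vapply(c(16, 40, 100), function(n) {
    labs <- rep(c("positive", "negative"), n / 2)
    good <- ifelse(labs == "positive", 1, 2) + seq_len(n) * 1e-3
    flat <- rep(1, n) + as.numeric(seq_len(n) %% 7) * 1e-3
    compare_auc(good, flat, labs)$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_n) < 0))
  expect_lt(p_at_n[3], 0.01)
})

test_that("stratified splits preserve class balance and partition the data", {
  set.seed(20)
  dataset <- data.frame(id = 1:281,
                        label = c(rep("positive", 67), rep("negative", 214)))
  sp <- stratified_split(dataset, 0.5, seed = 1)
  expect_true(sum(sp$test$label == "positive") %in% c(33L, 34L))
  expect_true(sum(sp$test$label == "negative") %in% c(107L))
  for (s in c(2, 99, 1234)) {
    sp <- stratified_split(dataset, 0.5, seed = s)
    expect_setequal(c(sp$train$id, sp$test$id), dataset$id)
    expect_length(intersect(sp$train$id, sp$test$id), 0L)
  }
  sp1 <- stratified_split(dataset, 0.3, seed = 7)
  sp2 <- stratified_split(dataset, 0.3, seed = 7)
  expect_identical(sp1, sp2)
  expect_error(stratified_split(data.frame(label = c("positive", "negative")),
                                0.5, seed = 1), "too few")
})

test_that("FPR-targeted thresholds never exceed the target", {
  set.seed(21)
  scores <- c(rexp(10, 1 / 5), rexp(20, 1 / 50) + 5)
  labels <- c(rep("positive", 10), rep("negative", 20))
  curve <- build_roc(scores, labels)
  thr <- threshold_at_fpr(curve, 0.05)
  expect_lte(sum(scores[labels == "negative"] <= thr), 1L)
  thr0 <- threshold_at_fpr(curve, 0)
  expect_equal(sum(scores[labels == "negative"] <= thr0), 0L)
  expect_equal(threshold_at_fpr(curve, 1), max(scores))
  expect_error(threshold_at_fpr(curve, 1.5), "\\[0, 1\\]")
})

test_that("grid training is reproducible and degenerates sensibly", {
  fx <- generate_fixture(n_sequences = 120, seed = 31)
  f1 <- grid_train(fx$sites, grid_wh = seq(0, 2, 0.5), grid_wo = seq(0, 4, 0.5),
                   n_splits = 5, seed = 2)
  f2 <- grid_train(fx$sites, grid_wh = seq(0, 2, 0.5), grid_wo = seq(0, 4, 0.5),
                   n_splits = 5, seed = 2)
  expect_identical(f1, f2)
  # single split: the average IS the argmax of that split
  f3 <- grid_train(fx$sites, grid_wh = seq(0, 2, 0.5), grid_wo = seq(0, 4, 0.5),
                   n_splits = 1, seed = 3)
  expect_equal(unname(f3$weights), unname(unlist(f3$per_split[1, c("wH", "wO")])))
  # zero-weight grid reduces the model to sequence-only scoring
  f0 <- grid_train(fx$sites, grid_wh = 0, grid_wo = 0, n_splits = 10, seed = 4)
  expect_equal(f0$per_split$test_auc_model, f0$per_split$test_auc_sequence)
  expect_equal(f0$wins, 0L)
})

test_that("curation labels follow the evidence rules and partition the input", {
  records <- data.frame(
    protein_id = c("a", "a", "b", "b", "c", "c", "d"),
    position = c(10L, 20L, 5L, 6L, 7L, 8L, 9L),
    ph = c(7.4, 7.0, 4.0, 7.5, 7.4, NA, 7.2),
    temperature_k = c(310, 298, 298, 350, 310, 298, 298),
    conversion_percent = c(80, NA, 90, 90, NA, NA, 20),
    half_time_days = c(20, 400, 10, 10, NA, 5, NA),
    deamidation_observed = c(TRUE, NA, TRUE, TRUE, FALSE, TRUE, TRUE),
    sample_age_known = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  out <- curate_records(records)
  d <- out$dispositions
  expect_equal(d$disposition[1], "positive")      # quantitative positive
  expect_equal(d$disposition[2], "negative")      # half-time > 100 d
  expect_equal(d$reason[3], "ph-out-of-range")    # acidic: dropped
  expect_equal(d$reason[4], "temperature-above-limit")
  expect_equal(d$disposition[5], "negative")      # tested and absent
  expect_equal(d$reason[6], "missing-conditions")
  expect_equal(d$reason[7], "unknown-sample-age")
  # partition: every record has exactly one disposition
  expect_equal(nrow(d), nrow(records))
  expect_true(all(d$disposition %in% c("positive", "negative", "dropped")))
  expect_equal(nrow(out$sites), sum(d$disposition != "dropped"))
})

test_that("slow observed deamidation is a negative; weak evidence is dropped", {
  recs <- data.frame(
    protein_id = c("x", "x"), position = c(1L, 2L), ph = 7.4,
    temperature_k = 310,
    conversion_percent = c(80, 20),
    half_time_days = c(150, NA),
    deamidation_observed = TRUE,
    sample_age_known = TRUE, stringsAsFactors = FALSE
  )
  out <- curate_records(recs)
  # observed but with a half-time beyond the cut: the slow rule wins
  expect_equal(out$dispositions$disposition[1], "negative")
  # observed but conversion below the positive bar and no half-time: neither rule
  expect_equal(out$dispositions$reason[2], "insufficient-evidence")
})
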