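# Shared test helpers: small half-time tables, hand-built profiles and
# random labeled-score fixtures.

toy_table <- function() {
  halftime_table(c(G = 1.0, A = 20.0, L = 100.0), source_label = "toy")
}

# profile with explicit tracks (bypasses parsing)
make_profile <- function(helix, disorder, id = "test") {
  structure(list(sequence_id = id, helix = as.integer(helix),
                 disorder = as.numeric(disorder), provenance = "parsed-external"),
            class = "ngome_profile")
}

uniform_profile <- function(L, H = 0, D = 1, id = "test") {
  make_profile(rep(H, L), rep(D, L), id)
}

# random scores/labels with both classes present, optionally with ties
random_roc_fixture <- function(n, tie_prob = 0.3) {
  scores <- if (runif(1) < tie_prob) {
    sample(seq_len(max(2L, n %/% 2L)), n, replace = TRUE) * 1.0
  } else {
    round(rexp(n, rate = 0.1), 3)
  }
  labels <- sample(c("positive", "negative"), n, replace = TRUE)
  if (all(labels == labels[1L])) labels[1L] <- setdiff(c("positive", "negative"), labels[1L])
  list(scores = scores, labels = labels)
}

# brute-force Mann-Whitney AUC by exhaustive pair counting (ties count 1/2),
# smaller score = more positive
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
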