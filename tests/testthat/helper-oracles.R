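# Independent oracles and small fixture builders. Everything here is
# deliberately naive (brute force / exhaustive) and shares no code with the
# implementation paths it checks.

# Brute-force batch information gain (bits) of the best binary split on one
# column: every midpoint between consecutive sorted distinct values is tried
# against the empirical class counts.
batch_gain_for_column <- function(x, labels) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  tab0 <- table(labels)
  h0 <- ent(tab0)
  v <- sort(unique(x))
  if (length(v) < 2) return(0)
  cuts <- (v[-length(v)] + v[-1]) / 2
  best <- 0
  for (t in cuts) {
    l <- labels[x <= t]; r <- labels[x > t]
    g <- h0 - (length(l) * ent(table(l)) + length(r) * ent(table(r))) /
      length(labels)
    if (g > best) best <- g
  }
  best
}

# argmax attribute by brute-force batch gain; ties -> lowest index
batch_best_attr <- function(features, labels) {
  gains <- apply(features, 2, batch_gain_for_column, labels = labels)
  which.max(gains)
}

# Naive root-to-leaf traversal, re-implemented against the serialized tree
# (plain list), independent of the package's routing code.
naive_route <- function(tree_list, x) {
  nd <- tree_list$root
  while (!isTRUE(nd$is_leaf)) {
    nd <- if (x[[nd$attr]] <= nd$threshold) nd$left else nd$right
  }
  nd$leaf_id
}

# Exhaustive pairwise single-linkage grouping oracle: O(n^2) similarity via
# the exported pairwise function, then BFS over the threshold graph.
oracle_grouping <- function(texts, theta) {
  n <- length(texts)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) sim[i, j] <- text_similarity(texts[i], texts[j])
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[i])) next
      comp[i] <- cid
      queue <- c(queue, which(sim[i, ] >= theta & is.na(comp)))
    }
  }
  comp
}

# Two regimes over four channels whose means differ by `gap_sd` noise
# standard deviations on exactly one channel.
two_class_regimes <- function(gap_sd = 4, sep_channel = 2L, sd = 2) {
  ch <- c("bp", "hr", "eeg", "temp")
  base <- stats::setNames(c(100, 80, 60, 37), ch)
  shifted <- base
  shifted[sep_channel] <- base[sep_channel] + gap_sd * sd
  ph <- function(tag) phrase_dist(paste(tag, c("alpha", "beta")), c(0.7, 0.3))
  list(class_regime("low", base, stats::setNames(rep(sd, 4), ch),
                    treatment = ph("treat low"), diagnosis = ph("diag low"),
                    history = ph("hist low")),
       class_regime("high", shifted, stats::setNames(rep(sd, 4), ch),
                    treatment = ph("treat high"), diagnosis = ph("diag high"),
                    history = ph("hist high")))
}

# Six classes separated along a single channel: many non-tied splits, so a
# small corpus grows a multi-level tree quickly under a short grace period.
six_class_regimes <- function() {
  ch <- c("bp", "hr", "eeg", "temp")
  ph <- function(tag) phrase_dist(paste(tag, c("alpha", "beta")), c(0.7, 0.3))
  lapply(1:6, function(k) {
    means <- stats::setNames(c(60 + 20 * k, 80, 60, 37), ch)
    class_regime(sprintf("class%d", k), means,
                 stats::setNames(c(1.5, 2, 2, 0.2), ch),
                 treatment = ph(sprintf("treat %d", k)),
                 diagnosis = ph(sprintf("diag %d", k)),
                 history = ph(sprintf("hist %d", k)))
  })
}

# A tiny trained engine over a temporary store.
# The mean/min/max features of one separating channel carry tied gains, so
# small-corpus fixtures raise tau: the tie route then splits within tens of
# examples instead of thousands.
tiny_engine <- function(n = 60, seed = 1, regimes = two_class_regimes(),
                        config = cdss_config(
                          vfdt = vfdt_config(grace_period = 20L, tau = 0.5))) {
  eng <- cdss_engine(tempfile("eng"), config)
  run_initial_training(eng, generate_records(regimes, n = n, seed = seed))
  eng
}

# From-scratch recomputation of a leaf's consensus, bypassing the cache:
# the semantic ground truth that cached predictions must match.
recompute_leaf <- function(engine, leaf_id) {
  ptrs <- vfdt_pointer_lists(engine$tree)[[leaf_id]]
  if (is.null(ptrs) || length(ptrs) == 0L) return(NULL)
  recs <- resolve_many(engine$store, ptrs)
  cfg <- engine$config
  rank <- function(field) {
    texts <- vapply(recs, `[[`, character(1), field)
    most_frequent(group_descriptions(texts, cfg$theta, cfg$synonyms),
                  cfg$top_k)
  }
  list(rids = vapply(recs, `[[`, character(1), "rid"),
       treatments = rank("treatment_text"),
       diagnoses = rank("diagnosis_text"),
       prognoses = rank("illness_history_text"))
}

expect_same_prediction <- function(res, oracle) {
  expect_equal(res$rids, oracle$rids)
  for (f in c("treatments", "diagnoses", "prognoses")) {
    expect_equal(res[[f]]$representative, oracle[[f]]$representative)
    expect_equal(res[[f]]$count, oracle[[f]]$count)
  }
}
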