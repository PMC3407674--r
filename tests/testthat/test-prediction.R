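test_that("degenerate groupings behave: identical strings, disjoint vocabularies", {
  g1 <- group_descriptions(rep("give aspirin now", 7), theta = 0.5)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$count, 7L)
  expect_equal(g1$representative, "give aspirin now")

  g2 <- group_descriptions(c("alpha bravo", "charlie delta"), theta = 0.1)
  expect_equal(nrow(g2), 2)
  expect_equal(sort(g2$count), c(1L, 1L))
})

test_that("planted paraphrase clusters are recovered and match the exhaustive oracle", {
  set.seed(10)
  clusters <- list(
    c("administer intravenous fluids and monitor output",
      "administer intravenous fluids and watch output",
      "monitor output and administer intravenous fluids"),
    c("schedule surgical consult for appendix removal",
      "schedule urgent surgical consult for appendix removal"),
    c("prescribe oral antihistamine for rash",
      "prescribe an oral antihistamine for the rash"))
  texts <- unlist(lapply(seq_along(clusters), function(k)
    sample(clusters[[k]], 10 + 3 * k, replace = TRUE)))
  texts <- sample(texts)
  g <- group_descriptions(texts, theta = 0.5)
  expect_equal(nrow(g), 3)
  # sum of group counts equals the number of input texts
  expect_equal(sum(g$count), length(texts))
  # membership matches an exhaustive pairwise single-linkage oracle
  mem <- attr(g, "membership")
  oracle <- oracle_grouping(texts, 0.5)
  expect_equal(length(unique(oracle)), 3)
  expect_identical(outer(mem, mem, "=="), outer(oracle, oracle, "=="))
})

test_that("group representative is the most frequent exact string, ties lexicographic", {
  g <- group_descriptions(c("b b b", "a a a", "b b b", "a a a"), theta = 0.9)
  # two groups of equal count sorted by representative
  expect_equal(g$representative, c("a a a", "b b b"))
  g2 <- group_descriptions(c("take aspirin daily", "take aspirin twice daily",
                             "take aspirin daily"), theta = 0.5)
  expect_equal(g2$representative, "take aspirin daily")
})

test_that("synonym substitution merges otherwise-distinct wording", {
  sy <- data.frame(term = c("mi", "heart"), canonical = c("cardiac", "cardiac"))
  a <- "mi"
  b <- "heart"
  expect_equal(text_similarity(a, b), 0)
  expect_equal(text_similarity(a, b, synonyms = sy), 1)
  g <- group_descriptions(c(a, b), theta = 0.9, synonyms = sy)
  expect_equal(nrow(g), 1)
})

test_that("most_frequent orders by count then representative and prefixes consistently", {
  texts <- c(rep("aaa aaa", 5), rep("bbb bbb", 3), "ccc ccc")
  g <- group_descriptions(texts, theta = 0.5)
  top2 <- most_frequent(g, 2)
  expect_equal(top2$representative, c("aaa aaa", "bbb bbb"))
  expect_equal(top2$count, c(5L, 3L))
  expect_identical(most_frequent(g, 2),
                   utils::head(most_frequent(g, nrow(g)), 2))
  expect_equal(format_ranked(most_frequent(g, 3)),
               "1.aaa aaa 2.bbb bbb 3.ccc ccc")
})

test_that("the metric distance matches its definition", {
  expect_equal(lsml_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(lsml_distance(c(3, 4), c(0, 0)), 25)   # identity P, squared Euclidean
  set.seed(6)
  for (i in 1:10) {
    A <- matrix(rnorm(25), 5)
    P <- crossprod(A)                                  # random PSD
    x <- rnorm(5); y <- rnorm(5)
    # naive double-loop oracle
    d <- x - y
    naive <- 0
    for (a in 1:5) for (b in 1:5) naive <- naive + d[a] * P[a, b] * d[b]
    expect_equal(lsml_distance(x, y, P), naive, tolerance = 1e-10)
    expect_gte(lsml_distance(x, y, P), 0)
  }
  expect_error(lsml_distance(c(1, 0), c(0, 1), matrix(c(1, 0, 0, -2), 2)),
               "not positive semidefinite")
  expect_error(lsml_distance(c(1, 0), c(0, 1), matrix(c(1, 5, -5, 1), 2)),
               "not symmetric")
})

test_that("retrieved same-class records are nearer than other-class records (identity metric)", {
  accs <- vapply(1:5, function(seed) {
    eng <- tiny_engine(n = 150, seed = seed,
                       regimes = two_class_regimes(gap_sd = 6))
    q_recs <- generate_records(two_class_regimes(gap_sd = 6), n = 20,
                               seed = 100 + seed)
    ok <- vapply(q_recs, function(qr) {
      res <- predict(eng, qr$features)
      if (length(res$rids) == 0) return(NA)
      same <- resolve_many(eng$store,
                           match(res$rids, mapping_table(eng$store)$rid))
      all_recs <- resolve_many(eng$store, mapping_table(eng$store)$pointer)
      other <- Filter(function(r) !(r$rid %in% res$rids), all_recs)
      d_same <- mean(vapply(same, function(r)
        lsml_distance(qr$features, r$features), numeric(1)))
      d_other <- mean(vapply(other, function(r)
        lsml_distance(qr$features, r$features), numeric(1)))
      d_same <= d_other
    }, logical(1))
    mean(ok, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("cache entries are version-guarded and invalidation is idempotent", {
  cc <- prediction_cache()
  cache_put <- streamcds:::cache_put
  cache_get <- streamcds:::cache_get
  cache_put(cc, "C1", 3L, list(x = 1))
  expect_equal(cache_get(cc, "C1", 3L), list(x = 1))
  expect_null(cache_get(cc, "C1", 4L))   # stale stamp never served
  invalidate(cc, "C1")
  expect_null(cache_get(cc, "C1", 3L))
  expect_silent(invalidate(cc, "C1"))    # absent entry: no-op
  expect_silent(invalidate(cc, "never-existed"))
})
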