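test_that("normalization canonicalizes text and is idempotent", {
  ev <- feedback_event("  Cardiac ", "  Administer   BETA blocker.  ",
                       "Acute MI", "Prior\tepisodes",
                       features = c(1, 2))
  r1 <- normalize_feedback(ev, 1)
  expect_equal(r1$class_label, "cardiac")
  expect_equal(r1$treatment_text, "administer beta blocker.")
  expect_equal(r1$diagnosis_text, "acute mi")
  expect_equal(r1$illness_history_text, "prior episodes")
  expect_equal(r1$rid, "R1")
  # idempotence: normalizing an already-canonical event changes nothing
  ev2 <- feedback_event(r1$class_label, r1$treatment_text, r1$diagnosis_text,
                        r1$illness_history_text, features = r1$features)
  expect_equal(normalize_feedback(ev2, 1), r1)
})

test_that("an event carrying a raw data unit is featurized like a direct call", {
  unit <- data.frame(timestamp = 1:3, bp = c(100, 104, 108), hr = c(70, 71, 72))
  ev <- feedback_event("cardiac", "t", "d", "h", unit = unit)
  r <- normalize_feedback(ev, 5)
  expect_identical(r$features, unname(featurize(unit)))
  expect_equal(r$rid, "R5")
})

test_that("events without a class label or data are validation errors", {
  expect_error(normalize_feedback(feedback_event("", features = 1:2), 1),
               "validation error")
  expect_error(normalize_feedback(feedback_event("flu"), 1),
               "validation error")
})

test_that("ingest into an empty engine creates record, pointer 1 and a one-leaf tree", {
  eng <- cdss_engine(withr::local_tempdir())
  out <- ingest(eng, feedback_event("flu", "rest", "viral", "none",
                                    features = c(1, 2, 3)))
  expect_equal(out$pointer, 1L)
  expect_equal(store_size(eng$store), 1)
  expect_true(eng$tree$root$is_leaf)
  expect_equal(vfdt_pointer_lists(eng$tree)$C1, 1L)
})

test_that("copy-train-swap: pre-swap queries see the pre-ingest tree; post-swap the pointer sits in exactly one leaf", {
  eng <- tiny_engine(n = 200, seed = 2, regimes = six_class_regimes())
  probes <- do.call(rbind, lapply(generate_records(six_class_regimes(), 30,
                                                   seed = 50),
                                  `[[`, "features"))
  before <- predict(eng$tree, probes, type = "leaf")
  before_cls <- predict(eng$tree, probes, type = "class")
  seen_during <- NULL
  ev <- feedback_event("class3", "treat 3 alpha", "diag 3 alpha",
                       "hist 3 alpha",
                       features = generate_records(six_class_regimes(), 1,
                                                   seed = 51)[[1]]$features)
  out <- ingest(eng, ev, .probe = function(e) {
    seen_during <<- list(leaf = predict(e$tree, probes, type = "leaf"),
                         cls = predict(e$tree, probes, type = "class"))
  })
  # between clone and swap, the serving tree answered from the snapshot
  expect_identical(seen_during$leaf, before)
  expect_identical(seen_during$cls, before_cls)
  # after the swap the new pointer is present in exactly one leaf
  pls <- vfdt_pointer_lists(eng$tree)
  holders <- names(Filter(function(p) out$pointer %in% p, pls))
  expect_length(holders, 1)
  expect_equal(holders, out$leaf_id)
})

test_that("a failed ingest leaves store, tree and cache unchanged", {
  eng <- tiny_engine(n = 80, seed = 3)
  n0 <- store_size(eng$store)
  snap <- vfdt_to_list(eng$tree)
  expect_error(ingest(eng, feedback_event("", features = rnorm(16))),
               "validation error")
  expect_equal(store_size(eng$store), n0)
  expect_identical(vfdt_to_list(eng$tree), snap)
})

test_that("an orphaned store append is reconciled on startup", {
  dir <- withr::local_tempdir()
  eng <- cdss_engine(dir)
  run_initial_training(eng, generate_records(two_class_regimes(), 40, seed = 4))
  # simulate a crash between store append and tree swap
  orphan <- generate_records(two_class_regimes(), 1, seed = 5,
                             rid_start = 1000)[[1]]
  p_orphan <- register_record(eng$store, orphan)
  cdss_save(eng)
  eng2 <- cdss_load(dir)
  expect_equal(attr(eng2, "reconciled"), p_orphan)
  pls <- unlist(vfdt_pointer_lists(eng2$tree), use.names = FALSE)
  expect_setequal(pls, seq_len(store_size(eng2$store)))
})

test_that("eager ingest re-extracts the affected leaf's consensus immediately", {
  eng <- tiny_engine(n = 100, seed = 6)
  feats <- generate_records(two_class_regimes(), 1, seed = 7)[[1]]$features
  out <- ingest(eng, feedback_event("low", "treat low alpha", "d", "h",
                                    features = feats))
  # the fresh extraction is already cached: the next predict is a hit
  res <- cdss_predict_leaf(eng, out$leaf_id)
  expect_true(res$cache_hit)
  oracle <- recompute_leaf(eng, out$leaf_id)
  expect_same_prediction(res, oracle)
})

test_that("feedback events round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(class_label = "flu", treatment_text = "Rest",
                            features = c(1, 2, 3)),
                       p, auto_unbox = TRUE, digits = NA)
  ev <- read_feedback_json(p)
  expect_s3_class(ev, "feedback_event")
  expect_equal(ev$features, c(1, 2, 3))
  expect_equal(ev$class_label, "flu")
})
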