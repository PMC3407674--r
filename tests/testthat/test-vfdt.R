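test_that("Hoeffding bound matches the closed form and is monotone", {
  expect_equal(hoeffding_bound(1, 1, 10), 0)
  expect_equal(hoeffding_bound(1, 0.05, 1000), sqrt(log(20) / 2000),
               tolerance = 1e-12)
  expect_gt(hoeffding_bound(2, 0.01, 100), hoeffding_bound(2, 0.01, 10000))
  expect_gt(hoeffding_bound(2, 0.001, 500), hoeffding_bound(2, 0.1, 500))
  expect_error(hoeffding_bound(1, 0.05, 0), "domain error")
})

test_that("a pure leaf yields zero gain and no split candidate", {
  m <- vfdt(2)
  for (i in 1:50) vfdt_learn_one(m, rnorm(2), "only")
  bs <- best_splits(m$root)
  expect_equal(bs$g1, 0)
  expect_true(is.na(bs$attr))
})

test_that("perfect separation gives the prior entropy as gain, on the right attribute", {
  set.seed(2)
  m <- vfdt(3)
  x1 <- cbind(rnorm(80, 0, 0.5), rnorm(80), rnorm(80))
  x2 <- cbind(rnorm(80, 10, 0.5), rnorm(80), rnorm(80))
  for (i in 1:80) vfdt_learn_one(m, x1[i, ], "a")
  for (i in 1:80) vfdt_learn_one(m, x2[i, ], "b")
  leaf <- m$root
  expect_true(leaf$is_leaf)  # 160 examples < grace period: no attempt yet
  bs <- best_splits(leaf)
  expect_equal(bs$attr, 1)
  # prior is 50/50 -> entropy 1 bit; brute-force empirical gain agrees
  expect_equal(bs$g1, 1, tolerance = 0.02)
  feats <- rbind(x1, x2)
  labs <- rep(c("a", "b"), each = 80)
  expect_equal(batch_gain_for_column(feats[, 1], labs), 1, tolerance = 1e-9)
  expect_equal(batch_best_attr(feats, labs), 1)
})

test_that("first example initializes a single-leaf tree; the Adder stores pointers", {
  m <- vfdt(4)
  res <- vfdt_learn_one(m, c(1, 2, 3, 4), "flu", pointer = 1L)
  expect_true(m$root$is_leaf)
  expect_equal(sum(m$root$class_counts), 1)
  expect_equal(res$leaf_id, "C1")
  expect_equal(res$adder_event, "C1")
  expect_true(1L %in% m$root$pointer_list)
  cl <- vfdt_classify(m, c(1, 2, 3, 4))
  expect_equal(cl$label, "flu")
  expect_equal(cl$leaf_id, "C1")
  expect_equal(cl$pointer_list, 1L)
})

test_that("root split attribute matches the brute-force batch gain argmax", {
  set.seed(31)
  n <- 5000
  sep <- 2L
  means <- c(0, 0, 0, 0)
  x <- matrix(rnorm(n * 4), ncol = 4)
  cls <- sample(c("a", "b"), n, replace = TRUE)
  x[cls == "b", sep] <- x[cls == "b", sep] + 4  # 4 sd on one attribute
  m <- vfdt(4)
  for (i in seq_len(n)) vfdt_learn_one(m, x[i, ], cls[i])
  expect_false(m$root$is_leaf)
  expect_equal(m$root$attr, sep)
  expect_equal(unname(batch_best_attr(x, cls)), sep)
})

test_that("splits happen only when the Hoeffding test licenses them", {
  set.seed(8)
  x <- matrix(rnorm(2000 * 2), ncol = 2)
  cls <- rep(c("a", "b"), 1000)
  x[cls == "b", 1] <- x[cls == "b", 1] + 8
  # delta ~ 0 keeps epsilon above the 1-bit maximum gain for n <= 345;
  # with tau = 0 no split can be licensed on this prefix
  m_strict <- vfdt(2, vfdt_config(delta = 1e-300, tau = 0, grace_period = 50))
  for (i in 1:250) vfdt_learn_one(m_strict, x[i, ], cls[i])
  expect_true(m_strict$root$is_leaf)
  # generous tie threshold licenses the split at the first attempt
  m_loose <- vfdt(2, vfdt_config(delta = 1e-6, tau = 10, grace_period = 50))
  for (i in 1:50) vfdt_learn_one(m_loose, x[i, ], cls[i])
  expect_false(m_loose$root$is_leaf)
})

test_that("classification agrees with a naive traversal of the serialized tree", {
  set.seed(5)
  m <- vfdt(3, vfdt_config(grace_period = 40))
  for (i in 1:600) {
    cls <- sample(c("a", "b", "c"), 1)
    mu <- c(a = -4, b = 0, c = 4)[cls]
    vfdt_learn_one(m, rnorm(3) + c(mu, 0, mu / 2), cls)
  }
  tl <- vfdt_to_list(m)
  probes <- matrix(rnorm(300), ncol = 3) * 4
  for (i in seq_len(nrow(probes))) {
    expect_identical(vfdt_classify(m, probes[i, ])$leaf_id,
                     naive_route(tl, probes[i, ]))
  }
})

test_that("pointer conservation holds through splits", {
  set.seed(12)
  m <- vfdt(2, vfdt_config(grace_period = 25))
  n <- 400
  for (p in seq_len(n)) {
    cls <- sample(c("a", "b", "c"), 1)
    mu <- c(a = -6, b = 0, c = 6)[cls]
    vfdt_learn_one(m, c(rnorm(1) + mu, rnorm(1)), cls, pointer = p)
  }
  expect_gte(m$n_splits, 1)
  all_ptrs <- unlist(vfdt_pointer_lists(m), use.names = FALSE)
  expect_setequal(all_ptrs, seq_len(n))
  expect_false(anyDuplicated(all_ptrs) > 0)
})

test_that("serialization round-trips to identical classifications", {
  set.seed(77)
  m <- vfdt(4, vfdt_config(grace_period = 30))
  for (i in 1:500) {
    cls <- sample(c("x", "y"), 1)
    vfdt_learn_one(m, rnorm(4) + if (cls == "x") 0 else 5, cls,
                   pointer = if (i %% 3 == 0) i else NULL)
  }
  p <- withr::local_tempfile(fileext = ".json")
  vfdt_save(m, p)
  m2 <- vfdt_load(p)
  probes <- matrix(rnorm(200) * 4, ncol = 4)
  expect_identical(predict(m, probes, type = "leaf"),
                   predict(m2, probes, type = "leaf"))
  expect_identical(predict(m, probes, type = "class"),
                   predict(m2, probes, type = "class"))
  expect_equal(vfdt_pointer_lists(m), vfdt_pointer_lists(m2))
})

test_that("clone independence: training the clone never touches the original", {
  set.seed(3)
  m <- vfdt(2)
  for (i in 1:100) {
    vfdt_learn_one(m, rnorm(2) + 3 * (i %% 2), c("e", "o")[1 + i %% 2],
                   pointer = i)
  }
  snap <- vfdt_to_list(m)
  cl <- vfdt_clone(m)
  for (i in 101:300) {
    vfdt_learn_one(cl, rnorm(2) + 3 * (i %% 2), c("e", "o")[1 + i %% 2],
                   pointer = i)
  }
  expect_identical(vfdt_to_list(m), snap)
  expect_equal(sort(unlist(vfdt_pointer_lists(cl))), 1:300,
               ignore_attr = TRUE)
})

test_that("schema violations are rejected; new labels are accepted", {
  m <- vfdt(3)
  vfdt_learn_one(m, 1:3, "a")
  expect_error(vfdt_learn_one(m, 1:4, "a"), "schema error")
  expect_error(vfdt_classify(m, 1:2), "schema error")
  vfdt_learn_one(m, 3:1, "brand-new-label")
  expect_true("brand-new-label" %in% m$classes)
})
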