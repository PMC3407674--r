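#' Incremental Hoeffding-tree (VFDT) classifier with pointer lists
#'
#' A VFDT learns a decision tree from a stream one example at a time, in
#' constant time and memory per example. A leaf converts to a split only
#' when the Hoeffding bound guarantees, with confidence `1 - delta`, that
#' the best candidate attribute truly beats the runner-up (or the two are
#' within the tie threshold `tau`). Each leaf additionally carries a
#' *pointer list*: the pointer values of every historical medical record
#' trained into that leaf, appended by the Adder. The pointer list is what
#' lets a classified stream retrieve similar past cases directly.
#'
#' Numeric attributes are summarized per class by running Gaussian
#' estimators (count, mean, variance via Welford updates) plus observed
#' min/max, keeping per-leaf memory fixed.
#'
#' @name vfdt_core
#' @keywords internal
NULL

#' VFDT hyperparameters
#'
#' @param delta split confidence in (0, 1]: the probability that the chosen
#'   split attribute is not truly the best is at most `delta`.
#' @param tau tie-break threshold (>= 0): when the top two candidate gains
#'   are within `tau` the split proceeds anyway once the bound tightens
#'   below `tau`.
#' @param grace_period number of examples a leaf accumulates between split
#'   attempts (>= 1).
#' @param max_depth optional maximum tree depth (`Inf` = unbounded).
#' @param pointer_cap optional per-leaf cap on the pointer list
#'   (keep-most-recent); `Inf` (default) keeps every pointer.
#' @return a `vfdt_config` list.
#' @export
vfdt_config <- function(delta = 1e-6, tau = 0.05, grace_period = 200L,
                        max_depth = Inf, pointer_cap = Inf) {
  stopifnot(delta > 0, delta <= 1, tau >= 0, grace_period >= 1,
            max_depth >= 1, pointer_cap >= 1)
  structure(list(delta = delta, tau = tau,
                 grace_period = as.integer(grace_period),
                 max_depth = max_depth, pointer_cap = pointer_cap),
            class = "vfdt_config")
}

#' Hoeffding bound
#'
#' After `n` independent observations of a quantity with range `R`, the
#' true mean lies within `epsilon = sqrt(R^2 * ln(1/delta) / (2 n))` of the
#' observed mean with probability `1 - delta`. Applied to information gain
#' (range `log2(n_classes)` bits), it licenses a split as soon as the
#' observed gain advantage exceeds `epsilon`.
#'
#' @param R nonnegative range of the averaged quantity.
#' @param delta confidence parameter in (0, 1].
#' @param n number of observations (>= 1).
#' @return nonnegative `epsilon`, strictly decreasing in `n` and `delta`.
#' @export
hoeffding_bound <- function(R, delta, n) {
  stopifnot(R >= 0, delta > 0, delta <= 1)
  if (any(n < 1)) stop("domain error: n must be >= 1", call. = FALSE)
  sqrt(R^2 * log(1 / delta) / (2 * n))
}

#' Create an empty VFDT model
#'
#' @param n_features length of the feature vectors the tree will consume.
#' @param config a [vfdt_config()].
#' @param feature_names optional character vector naming the features.
#' @return a `vfdt` object (environment with reference semantics; use
#'   [vfdt_clone()] for an independent copy).
#' @export
vfdt <- function(n_features, config = vfdt_config(), feature_names = NULL) {
  stopifnot(n_features >= 1)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(n_features))
  stopifnot(length(feature_names) == n_features)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$n_features <- as.integer(n_features)
  m$feature_names <- feature_names
  m$classes <- character(0)
  m$next_leaf_id <- 2L
  m$n_seen <- 0L
  m$n_splits <- 0L
  m$ptr_features <- new.env(parent = emptyenv())  # pointer -> features+label
  m$root <- new_leaf(m, "C1", depth = 1L, fallback = NA_character_)
  class(m) <- "vfdt"
  m
}

new_leaf <- function(model, leaf_id, depth, fallback) {
  nf <- model$n_features
  lf <- new.env(parent = emptyenv())
  lf$is_leaf <- TRUE
  lf$leaf_id <- leaf_id
  lf$depth <- depth
  lf$class_counts <- numeric(0)          # named by class label
  lf$stats <- list()                     # per class: list(n, mean, M2)
  lf$attr_min <- rep(Inf, nf)
  lf$attr_max <- rep(-Inf, nf)
  lf$pointer_list <- integer(0)
  lf$version <- 1L                       # bumped on every Adder event
  lf$n_since_attempt <- 0L
  lf$fallback_class <- fallback
  lf
}

route_to_leaf <- function(model, x) {
  node <- model$root
  while (!node$is_leaf) {
    node <- if (x[node$attr] <= node$threshold) node$left else node$right
  }
  node
}

update_leaf_stats <- function(leaf, x, label) {
  if (is.na(match(label, names(leaf$class_counts)))) {
    leaf$class_counts[label] <- 0
    leaf$stats[[label]] <- list(n = 0L, mean = numeric(length(x)),
                                M2 = numeric(length(x)))
  }
  leaf$class_counts[label] <- leaf$class_counts[label] + 1
  s <- leaf$stats[[label]]
  s$n <- s$n + 1L
  d <- x - s$mean
  s$mean <- s$mean + d / s$n
  s$M2 <- s$M2 + d * (x - s$mean)
  leaf$stats[[label]] <- s
  leaf$attr_min <- pmin(leaf$attr_min, x)
  leaf$attr_max <- pmax(leaf$attr_max, x)
  invisible(leaf)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Best split candidate on one attribute: thresholds are midpoints between
# class means plus interior deciles of the observed range; per-class mass on
# each side is estimated from the Gaussian summaries.
best_split_for_attr <- function(leaf, j) {
  labs <- names(leaf$class_counts)
  counts <- leaf$class_counts
  mu <- vapply(labs, function(l) leaf$stats[[l]]$mean[j], numeric(1))
  sd_ <- vapply(labs, function(l) {
    s <- leaf$stats[[l]]
    if (s$n >= 2) sqrt(max(s$M2[j] / (s$n - 1), 0)) else 0
  }, numeric(1))
  sd_ <- pmax(sd_, 1e-9)
  lo <- leaf$attr_min[j]; hi <- leaf$attr_max[j]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    return(list(gain = 0, threshold = NA_real_))
  }
  mids <- if (length(mu) >= 2) {
    sm <- sort(unique(mu))
    (sm[-length(sm)] + sm[-1]) / 2
  } else numeric(0)
  dec <- seq(lo, hi, length.out = 11L)[2:10]
  cand <- sort(unique(c(mids, dec)))
  cand <- cand[cand > lo & cand < hi]
  if (length(cand) == 0L) return(list(gain = 0, threshold = NA_real_))
  h0 <- entropy_bits(counts)
  n_tot <- sum(counts)
  # frac[c, t]: estimated fraction of class c at or below threshold t
  frac <- vapply(cand, function(t) stats::pnorm((t - mu) / sd_),
                 numeric(length(labs)))
  frac <- matrix(frac, nrow = length(labs))
  nl <- counts * frac                     # class x threshold
  nr <- counts - nl
  gains <- vapply(seq_along(cand), function(k) {
    l <- nl[, k]; r <- nr[, k]
    wl <- sum(l); wr <- sum(r)
    if (wl <= 0 || wr <= 0) return(0)
    h0 - (wl * entropy_bits(l) + wr * entropy_bits(r)) / n_tot
  }, numeric(1))
  k <- which.max(gains)                   # first max -> lowest threshold
  list(gain = max(gains[k], 0), threshold = cand[k])
}

#' Top two candidate splits at a leaf
#'
#' Evaluates the best threshold per attribute from the per-class Gaussian
#' summaries and returns the two best attributes by information gain
#' (bits). Ties break deterministically toward the lowest attribute index,
#' then the lowest threshold. A single-class leaf yields gain 0 and no
#' split candidate.
#'
#' @param leaf a leaf environment of a [vfdt()] model.
#' @return list with `g1`, `g2` (top two gains; `g2 = 0` when fewer than two
#'   informative attributes exist), `attr`, `threshold` of the best split.
#' @export
best_splits <- function(leaf) {
  labs <- names(leaf$class_counts)
  if (length(labs) < 2L) {
    return(list(g1 = 0, g2 = 0, attr = NA_integer_, threshold = NA_real_))
  }
  nf <- length(leaf$attr_min)
  per_attr <- lapply(seq_len(nf), function(j) best_split_for_attr(leaf, j))
  gains <- vapply(per_attr, `[[`, numeric(1), "gain")
  o <- order(-gains, seq_len(nf))         # ties -> lowest attribute index
  b <- o[1]
  list(g1 = gains[b],
       g2 = if (nf >= 2) gains[o[2]] else 0,
       attr = b,
       threshold = per_attr[[b]]$threshold)
}

attempt_split <- function(model, leaf) {
  cfg <- model$config
  if (leaf$depth >= cfg$max_depth) return(FALSE)
  cand <- best_splits(leaf)
  if (is.na(cand$attr) || cand$g1 <= 1e-12) return(FALSE)
  n <- sum(leaf$class_counts)
  R <- log2(max(length(model$classes), 2))
  eps <- hoeffding_bound(R, cfg$delta, n)
  if (!(cand$g1 - cand$g2 > eps || eps < cfg$tau)) return(FALSE)
  do_split(model, leaf, cand$attr, cand$threshold)
  TRUE
}

do_split <- function(model, leaf, attr, threshold) {
  maj <- leaf_majority(leaf)
  left <- new_leaf(model, sprintf("C%d", model$next_leaf_id), leaf$depth + 1L,
                   fallback = maj)
  right <- new_leaf(model, sprintf("C%d", model$next_leaf_id + 1L),
                    leaf$depth + 1L, fallback = maj)
  model$next_leaf_id <- model$next_leaf_id + 2L
  model$n_splits <- model$n_splits + 1L
  # Re-route every pointed record by its remembered features so the
  # leaf -> similar-records mapping stays correct after growth.
  for (p in leaf$pointer_list) {
    rec <- get(as.character(p), envir = model$ptr_features)
    child <- if (rec$features[attr] <= threshold) left else right
    child$pointer_list <- c(child$pointer_list, p)
    update_leaf_stats(child, rec$features, rec$label)
  }
  # convert the leaf environment, in place, into a split node
  rm(list = intersect(c("class_counts", "stats", "attr_min", "attr_max",
                        "pointer_list", "version", "n_since_attempt",
                        "leaf_id", "fallback_class"),
                      ls(leaf)), envir = leaf)
  leaf$is_leaf <- FALSE
  leaf$attr <- attr
  leaf$threshold <- threshold
  leaf$left <- left
  leaf$right <- right
  invisible(leaf)
}

leaf_majority <- function(leaf) {
  if (length(leaf$class_counts) == 0L) return(leaf$fallback_class)
  cc <- leaf$class_counts[order(names(leaf$class_counts))]  # ties -> lexicographic
  names(cc)[which.max(cc)]
}

#' Train the model on one labeled example
#'
#' Routes the feature vector to a leaf, updates that leaf's class counts
#' and Gaussian attribute summaries, and (when `pointer` is given) has the
#' Adder append the pointer to the leaf's pointer list — bumping the leaf's
#' version stamp, which invalidates any cached prediction for that leaf.
#' Every `grace_period` examples the leaf attempts a split; the split is
#' made iff `G1 - G2 > epsilon` or `epsilon < tau`. On a split, pointers
#' are re-distributed to the children by re-routing each pointed record's
#' remembered features.
#'
#' @param model a [vfdt()] model (modified in place).
#' @param features numeric vector matching the model schema.
#' @param label class label (opaque string; new labels are registered).
#' @param pointer optional positive integer pointer value of the record.
#' @return invisibly, a list with `leaf_id` (leaf the example reached; if a
#'   split occurred this leaf no longer exists), `split` (logical), and
#'   `adder_event` (leaf id whose pointer list grew, or `NA`).
#' @export
vfdt_learn_one <- function(model, features, label, pointer = NULL) {
  features <- as.numeric(features)
  if (length(features) != model$n_features) {
    stop("schema error: feature vector length ", length(features),
         " != model schema ", model$n_features, call. = FALSE)
  }
  label <- as.character(label)
  if (!label %in% model$classes) model$classes <- c(model$classes, label)
  leaf <- route_to_leaf(model, features)
  update_leaf_stats(leaf, features, label)
  model$n_seen <- model$n_seen + 1L
  adder_event <- NA_character_
  if (!is.null(pointer)) {
    pointer <- as.integer(pointer)
    assign(as.character(pointer),
           list(features = features, label = label),
           envir = model$ptr_features)
    leaf$pointer_list <- c(leaf$pointer_list, pointer)
    cap <- model$config$pointer_cap
    if (is.finite(cap) && length(leaf$pointer_list) > cap) {
      dropped <- leaf$pointer_list[seq_len(length(leaf$pointer_list) - cap)]
      leaf$pointer_list <- leaf$pointer_list[
        (length(leaf$pointer_list) - cap + 1L):length(leaf$pointer_list)]
      rm(list = as.character(dropped), envir = model$ptr_features)
    }
    leaf$version <- leaf$version + 1L
    adder_event <- leaf$leaf_id
  }
  leaf$n_since_attempt <- leaf$n_since_attempt + 1L
  leaf_id <- leaf$leaf_id
  split <- FALSE
  if (leaf$n_since_attempt >= model$config$grace_period) {
    leaf$n_since_attempt <- 0L
    split <- attempt_split(model, leaf)
  }
  invisible(list(leaf_id = leaf_id, split = split, adder_event = adder_event))
}

#' Classify a feature vector
#'
#' Deterministically routes to a leaf and reports the leaf id, its majority
#' class, and the Laplace-smoothed class posterior at the leaf. Valid after
#' any prefix of the training stream (an empty leaf answers with its
#' parent's majority at split time).
#'
#' @param model a [vfdt()] model.
#' @param features numeric vector matching the model schema.
#' @return list with `leaf_id`, `label`, `posterior` (named over all
#'   classes the model has seen), `pointer_list`, `leaf_version`.
#' @export
vfdt_classify <- function(model, features) {
  features <- as.numeric(features)
  if (length(features) != model$n_features) {
    stop("schema error: feature vector length ", length(features),
         " != model schema ", model$n_features, call. = FALSE)
  }
  leaf <- route_to_leaf(model, features)
  cls <- sort(model$classes)
  cc <- stats::setNames(numeric(length(cls)), cls)
  if (length(leaf$class_counts)) {
    cc[names(leaf$class_counts)] <- leaf$class_counts
  }
  post <- if (length(cls)) (cc + 1) / (sum(cc) + length(cls)) else cc
  list(leaf_id = leaf$leaf_id,
       label = leaf_majority(leaf),
       posterior = post,
       pointer_list = leaf$pointer_list,
       leaf_version = leaf$version)
}

#' @export
predict.vfdt <- function(object, newdata,
                         type = c("class", "prob", "leaf"), ...) {
  type <- match.arg(type)
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  res <- apply(newdata, 1, function(x) vfdt_classify(object, x),
               simplify = FALSE)
  switch(type,
         class = vapply(res, `[[`, character(1), "label"),
         leaf = vapply(res, `[[`, character(1), "leaf_id"),
         prob = do.call(rbind, lapply(res, `[[`, "posterior")))
}

walk_leaves <- function(node, fn) {
  if (node$is_leaf) fn(node) else {
    walk_leaves(node$left, fn)
    walk_leaves(node$right, fn)
  }
  invisible(NULL)
}

#' Leaf-level summary of a VFDT
#'
#' @param model a [vfdt()] model.
#' @return data frame with one row per leaf: `leaf_id`, `depth`, `n`
#'   (examples incorporated), `majority`, `n_pointers`, `version`.
#' @export
vfdt_leaf_table <- function(model) {
  rows <- list()
  walk_leaves(model$root, function(lf) {
    rows[[length(rows) + 1L]] <<- data.frame(
      leaf_id = lf$leaf_id, depth = lf$depth,
      n = sum(lf$class_counts),
      majority = if (is.null(leaf_majority(lf))) NA_character_ else
        leaf_majority(lf),
      n_pointers = length(lf$pointer_list),
      version = lf$version, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All leaf pointer lists
#'
#' @param model a [vfdt()] model.
#' @return named list, leaf id -> integer vector of pointer values.
#' @export
vfdt_pointer_lists <- function(model) {
  out <- list()
  walk_leaves(model$root, function(lf) out[[lf$leaf_id]] <<- lf$pointer_list)
  out
}

leaf_env_by_id <- function(model, leaf_id) {
  found <- NULL
  walk_leaves(model$root, function(lf) {
    if (identical(lf$leaf_id, leaf_id)) found <<- lf
  })
  found
}

#' Deep-clone a VFDT
#'
#' Produces a fully independent logical copy: training the clone never
#' affects the original. This is the "copy" step of copy-train-swap.
#'
#' @param model a [vfdt()] model.
#' @return an independent `vfdt` object.
#' @export
vfdt_clone <- function(model) {
  m <- new.env(parent = emptyenv())
  for (f in c("config", "n_features", "feature_names", "classes",
              "next_leaf_id", "n_seen", "n_splits")) {
    assign(f, get(f, envir = model), envir = m)
  }
  m$ptr_features <- list2env(as.list(model$ptr_features),
                             envir = new.env(parent = emptyenv()))
  m$root <- clone_node(model$root)
  class(m) <- "vfdt"
  m
}

clone_node <- function(node) {
  nd <- new.env(parent = emptyenv())
  for (f in ls(node)) {
    if (f %in% c("left", "right")) next
    assign(f, get(f, envir = node), envir = nd)
  }
  if (!node$is_leaf) {
    nd$left <- clone_node(node$left)
    nd$right <- clone_node(node$right)
  }
  nd
}

node_to_list <- function(node) {
  if (node$is_leaf) {
    list(is_leaf = TRUE, leaf_id = node$leaf_id, depth = node$depth,
         class_counts = as.list(node$class_counts),
         stats = lapply(node$stats, function(s)
           list(n = s$n, mean = s$mean, M2 = s$M2)),
         attr_min = node$attr_min, attr_max = node$attr_max,
         pointer_list = node$pointer_list, version = node$version,
         n_since_attempt = node$n_since_attempt,
         fallback_class = node$fallback_class)
  } else {
    list(is_leaf = FALSE, attr = node$attr, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(x, depth = 1L) {
  nd <- new.env(parent = emptyenv())
  if (isTRUE(x$is_leaf)) {
    nd$is_leaf <- TRUE
    nd$leaf_id <- x$leaf_id
    nd$depth <- if (!is.null(x$depth)) as.integer(x$depth) else depth
    nd$class_counts <- stats::setNames(as.numeric(unlist(x$class_counts)),
                                       names(x$class_counts))
    if (length(nd$class_counts) == 0L) nd$class_counts <- numeric(0)
    nd$stats <- lapply(x$stats, function(s)
      list(n = as.integer(s$n), mean = as.numeric(s$mean),
           M2 = as.numeric(s$M2)))
    nd$attr_min <- as.numeric(x$attr_min)
    nd$attr_max <- as.numeric(x$attr_max)
    nd$pointer_list <- as.integer(unlist(x$pointer_list))
    if (length(nd$pointer_list) == 0L) nd$pointer_list <- integer(0)
    nd$version <- as.integer(x$version)
    nd$n_since_attempt <- as.integer(x$n_since_attempt)
    nd$fallback_class <- if (is.null(x$fallback_class)) NA_character_ else
      as.character(x$fallback_class)
  } else {
    nd$is_leaf <- FALSE
    nd$attr <- as.integer(x$attr)
    nd$threshold <- as.numeric(x$threshold)
    nd$left <- node_from_list(x$left, depth + 1L)
    nd$right <- node_from_list(x$right, depth + 1L)
  }
  nd
}

#' Serialize a VFDT to a plain list / JSON
#'
#' The list form round-trips through [vfdt_from_list()]; [vfdt_save()] and
#' [vfdt_load()] write and read the JSON document (nodes, split predicates,
#' leaf statistics, pointer lists, config, schema).
#'
#' @param model a [vfdt()] model.
#' @return a plain list (no environments).
#' @export
vfdt_to_list <- function(model) {
  pf <- as.list(model$ptr_features)
  list(config = unclass(model$config),
       n_features = model$n_features,
       feature_names = model$feature_names,
       classes = model$classes,
       next_leaf_id = model$next_leaf_id,
       n_seen = model$n_seen,
       n_splits = model$n_splits,
       ptr_features = pf,
       root = node_to_list(model$root))
}

#' @rdname vfdt_to_list
#' @param x a list produced by [vfdt_to_list()] (or parsed from its JSON).
#' @export
vfdt_from_list <- function(x) {
  cfg <- x$config
  m <- new.env(parent = emptyenv())
  m$config <- vfdt_config(
    delta = cfg$delta, tau = cfg$tau, grace_period = cfg$grace_period,
    max_depth = if (is.null(cfg$max_depth) || !is.finite(cfg$max_depth) ||
                    cfg$max_depth <= 0) Inf else cfg$max_depth,
    pointer_cap = if (is.null(cfg$pointer_cap) || !is.finite(cfg$pointer_cap) ||
                      cfg$pointer_cap <= 0) Inf else cfg$pointer_cap)
  m$n_features <- as.integer(x$n_features)
  m$feature_names <- as.character(unlist(x$feature_names))
  m$classes <- as.character(unlist(x$classes))
  if (length(m$classes) == 0L) m$classes <- character(0)
  m$next_leaf_id <- as.integer(x$next_leaf_id)
  m$n_seen <- as.integer(x$n_seen)
  m$n_splits <- as.integer(x$n_splits)
  m$ptr_features <- new.env(parent = emptyenv())
  for (p in names(x$ptr_features)) {
    rec <- x$ptr_features[[p]]
    assign(p, list(features = as.numeric(unlist(rec$features)),
                   label = as.character(rec$label)),
           envir = m$ptr_features)
  }
  m$root <- node_from_list(x$root)
  class(m) <- "vfdt"
  m
}

#' @rdname vfdt_to_list
#' @param path JSON file path.
#' @export
vfdt_save <- function(model, path) {
  # Inf (unbounded depth/cap) is not representable in JSON; encode as null
  x <- vfdt_to_list(model)
  x$config$max_depth <- if (is.finite(x$config$max_depth))
    x$config$max_depth else NULL
  x$config$pointer_cap <- if (is.finite(x$config$pointer_cap))
    x$config$pointer_cap else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname vfdt_to_list
#' @export
vfdt_load <- function(path) {
  vfdt_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE))
}

#' @export
print.vfdt <- function(x, ...) {
  lt <- vfdt_leaf_table(x)
  cat(sprintf(
    "Hoeffding tree (VFDT): %d leaves, %d splits, depth %d\n",
    nrow(lt), x$n_splits, max(lt$depth)))
  cat(sprintf("  trained on %d examples, %d classes (%s)\n", x$n_seen,
              length(x$classes), paste(sort(x$classes), collapse = ", ")))
  cat(sprintf("  %d record pointers attached across leaves\n",
              sum(lt$n_pointers)))
  invisible(x)
}

#' @export
summary.vfdt <- function(object, ...) {
  out <- list(leaf_table = vfdt_leaf_table(object),
              n_seen = object$n_seen, n_splits = object$n_splits,
              classes = sort(object$classes), config = object$config)
  class(out) <- "summary.vfdt"
  out
}

#' @export
print.summary.vfdt <- function(x, ...) {
  cat(sprintf("VFDT: %d examples, %d splits, classes: %s\n", x$n_seen,
              x$n_splits, paste(x$classes, collapse = ", ")))
  cat(sprintf("  delta=%g tau=%g grace_period=%d\n", x$config$delta,
              x$config$tau, x$config$grace_period))
  print(x$leaf_table, row.names = FALSE)
  invisible(x)
}
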