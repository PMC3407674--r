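#' The clinical decision-support engine
#'
#' Wires the pipeline together: vital-sign stream -> data units -> feature
#' vectors -> VFDT leaf -> pointer list -> record retrieval -> consensus
#' extraction, with a per-leaf prediction cache in the middle and the
#' copy-train-swap feedback loop closing it. One engine owns one live
#' tree, one record store, and one cache.
#'
#' @name engine
#' @keywords internal
NULL

#' Engine configuration
#'
#' @param unit_size time points per data unit.
#' @param scheme feature scheme (see [featurize()]).
#' @param theta text-similarity threshold for description grouping.
#' @param top_k number of ranked consensus texts per field.
#' @param eager recompute a leaf's consensus immediately after feedback
#'   lands on it (`TRUE`, the default) or lazily on next query.
#' @param vfdt a [vfdt_config()].
#' @param synonyms optional synonym table (see [read_synonyms()]).
#' @return a `cdss_config` list.
#' @export
cdss_config <- function(unit_size = 3L, scheme = "mslmm", theta = 0.5,
                        top_k = 3L, eager = TRUE, vfdt = vfdt_config(),
                        synonyms = NULL) {
  stopifnot(unit_size >= 1L, theta >= 0, theta <= 1, top_k >= 1L)
  structure(list(unit_size = as.integer(unit_size), scheme = scheme,
                 theta = theta, top_k = as.integer(top_k),
                 eager = isTRUE(eager), vfdt = vfdt, synonyms = synonyms),
            class = "cdss_config")
}

#' Create a decision-support engine
#'
#' @param store_dir directory for the record store (created if absent).
#' @param config a [cdss_config()].
#' @return a `cdss_engine` (environment: `$tree`, `$store`, `$cache`,
#'   `$config`).
#' @export
cdss_engine <- function(store_dir = tempfile("cdss"), config = cdss_config()) {
  eng <- new.env(parent = emptyenv())
  eng$config <- config
  eng$store <- record_store(store_dir)
  eng$cache <- prediction_cache()
  eng$tree <- NULL          # created on first training record (fixes schema)
  eng$log <- list()
  class(eng) <- "cdss_engine"
  eng
}

ensure_tree <- function(engine, n_features, feature_names = NULL) {
  if (is.null(engine$tree)) {
    engine$tree <- vfdt(n_features, engine$config$vfdt, feature_names)
  } else if (engine$tree$n_features != n_features) {
    stop("schema error: feature length ", n_features,
         " != engine schema ", engine$tree$n_features, call. = FALSE)
  }
  engine$tree
}

log_event <- function(engine, type, ...) {
  engine$log[[length(engine$log) + 1L]] <- c(list(type = type), list(...))
  invisible(NULL)
}

#' Train a record into the engine
#'
#' Registers the record (minting its pointer and mapping row) and trains
#' the live tree on it; the Adder attaches the pointer to the reached leaf
#' and the leaf's cached prediction, if any, is invalidated.
#'
#' @param engine a [cdss_engine()].
#' @param record a [medical_record()].
#' @return the pointer value, invisibly.
#' @export
train_record <- function(engine, record) {
  ensure_tree(engine, length(record$features), names(record$features))
  pointer <- register_record(engine$store, record)
  res <- vfdt_learn_one(engine$tree, record$features, record$class_label,
                        pointer)
  if (!is.na(res$adder_event)) {
    invalidate(engine$cache, res$adder_event)
    log_event(engine, "adder", leaf = res$adder_event, pointer = pointer)
  }
  if (res$split) log_event(engine, "split", leaf = res$leaf_id)
  invisible(pointer)
}

#' Initial training from a record source
#'
#' Registers and trains every historical record in order, each with its
#' pointer, so that after incubation every leaf indexes the records of its
#' class directly.
#'
#' @param engine a [cdss_engine()].
#' @param records list of [medical_record()]s, or the path of a JSON-lines
#'   record file.
#' @return the engine, invisibly.
#' @export
run_initial_training <- function(engine, records) {
  if (is.character(records)) records <- read_records_jsonl(records)
  for (r in records) train_record(engine, r)
  invisible(engine)
}

#' Extract the consensus prediction for a leaf
#'
#' If the cache holds an entry whose version stamp matches the leaf's
#' current pointer-list version, it is returned directly (`cache_hit =
#' TRUE`). Otherwise the leaf's pointers are resolved through the mapping
#' table, the treatment / diagnosis / illness-history texts are grouped and
#' ranked independently, and the result is cached under the current
#' version.
#'
#' @param engine a [cdss_engine()].
#' @param leaf_id id of an existing leaf of the live tree.
#' @return a `prediction_result`: `leaf_id`, `class_label`, `rids`,
#'   ranked `treatments` / `diagnoses` / `prognoses` data frames,
#'   `cache_hit`, `empty_leaf` warning flag.
#' @export
cdss_predict_leaf <- function(engine, leaf_id) {
  leaf <- leaf_env_by_id(engine$tree, leaf_id)
  if (is.null(leaf)) {
    stop("lookup error: no leaf '", leaf_id, "' in the live tree",
         call. = FALSE)
  }
  hit <- cache_get(engine$cache, leaf_id, leaf$version)
  if (!is.null(hit)) {
    hit$cache_hit <- TRUE
    return(hit)
  }
  cfg <- engine$config
  label <- leaf_majority(leaf)
  ptrs <- leaf$pointer_list
  empty_rank <- data.frame(representative = character(0), count = integer(0),
                           group_id = integer(0), stringsAsFactors = FALSE)
  if (length(ptrs) == 0L) {
    res <- new_prediction_result(leaf_id, label, character(0), empty_rank,
                                 empty_rank, empty_rank, cache_hit = FALSE,
                                 empty_leaf = TRUE)
  } else {
    recs <- resolve_many(engine$store, ptrs)
    rank_field <- function(field) {
      texts <- vapply(recs, `[[`, character(1), field)
      most_frequent(group_descriptions(texts, cfg$theta, cfg$synonyms),
                    cfg$top_k)
    }
    res <- new_prediction_result(
      leaf_id, label,
      rids = vapply(recs, `[[`, character(1), "rid"),
      treatments = rank_field("treatment_text"),
      diagnoses = rank_field("diagnosis_text"),
      prognoses = rank_field("illness_history_text"),
      cache_hit = FALSE, empty_leaf = FALSE)
  }
  cache_put(engine$cache, leaf_id, leaf$version, res)
  res
}

new_prediction_result <- function(leaf_id, class_label, rids, treatments,
                                  diagnoses, prognoses, cache_hit,
                                  empty_leaf) {
  structure(list(leaf_id = leaf_id, class_label = class_label, rids = rids,
                 treatments = treatments, diagnoses = diagnoses,
                 prognoses = prognoses, cache_hit = cache_hit,
                 empty_leaf = empty_leaf),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Prediction at leaf %s: class '%s'%s\n", x$leaf_id,
              if (is.na(x$class_label)) "?" else x$class_label,
              if (x$cache_hit) " [cached]" else ""))
  if (x$empty_leaf) {
    cat("  (leaf has no pointed records yet; no consensus available)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d similar records: %s\n", length(x$rids),
              paste(utils::head(x$rids, 8), collapse = ", ")))
  cat("  treatment: ", format_ranked(x$treatments), "\n", sep = "")
  cat("  diagnosis: ", format_ranked(x$diagnoses), "\n", sep = "")
  cat("  prognosis: ", format_ranked(x$prognoses), "\n", sep = "")
  invisible(x)
}

#' Serialize a prediction result to JSON
#'
#' @param result a `prediction_result`.
#' @return a JSON string.
#' @export
prediction_to_json <- function(result) {
  as.character(jsonlite::toJSON(unclass(result), auto_unbox = TRUE,
                                digits = NA, dataframe = "rows"))
}

#' Classify features and predict
#'
#' Full query path for one feature vector: route through the live tree,
#' then extract (or serve from cache) the leaf's consensus.
#'
#' @param object a [cdss_engine()].
#' @param newdata a numeric feature vector, a feature matrix (one row per
#'   unit), or a `data_unit`.
#' @param ... unused.
#' @return one `prediction_result`, or a list of them for a matrix.
#' @export
predict.cdss_engine <- function(object, newdata, ...) {
  if (is.null(object$tree)) {
    stop("engine has no trained tree yet", call. = FALSE)
  }
  if (inherits(newdata, "data_unit")) {
    newdata <- featurize(newdata, object$config$scheme)
  }
  if (is.null(dim(newdata))) {
    cl <- vfdt_classify(object$tree, newdata)
    res <- cdss_predict_leaf(object, cl$leaf_id)
    res$class_label <- cl$label
    return(res)
  }
  apply(as.matrix(newdata), 1, function(x) predict(object, x),
        simplify = FALSE)
}

#' Run a vital-sign stream through the engine
#'
#' Segments the stream into data units, featurizes, classifies and
#' predicts each complete unit. Rows with missing channel values or
#' non-increasing timestamps are logged and skipped. When a `label` column
#' is present, prequential (test-then-train) accuracy is accumulated:
#' each unit is predicted first, then used to update the tree (no pointer
#' is attached, so stream updates never touch pointer lists or the cache).
#'
#' @param engine a [cdss_engine()] with a trained tree.
#' @param samples a data frame (stream CSV schema, optional `label`
#'   column) or a path to a stream CSV.
#' @param update train on labeled units after predicting (default `TRUE`).
#' @param results keep the per-unit `prediction_result`s (default `TRUE`;
#'   turn off for long streams).
#' @return list with `results` (list of `prediction_result`), `labels`,
#'   `predicted`, `correct` (logical per labeled unit), and `summary`
#'   (rows in/skipped, units, prequential accuracy, cache-hit rate).
#' @export
run_stream <- function(engine, samples, update = TRUE, results = TRUE) {
  if (is.character(samples)) {
    samples <- utils::read.csv(samples, check.names = FALSE)
  }
  samples <- as.data.frame(samples)
  n_in <- nrow(samples)
  has_label <- "label" %in% names(samples)
  ch <- setdiff(names(samples), c("timestamp", "label"))
  ok <- !Reduce(`|`, lapply(samples[ch], is.na), rep(FALSE, n_in))
  if ("timestamp" %in% names(samples)) {
    ts <- as.numeric(samples$timestamp)
    keep_increasing <- !is.na(ts)
    last <- -Inf
    for (i in seq_len(n_in)) {
      if (keep_increasing[i] && ok[i] && ts[i] > last) last <- ts[i]
      else keep_increasing[i] <- FALSE
    }
    ok <- ok & keep_increasing
  }
  n_skipped <- sum(!ok)
  samples <- samples[ok, , drop = FALSE]
  fs <- featurize_stream(samples, engine$config$unit_size,
                         engine$config$scheme,
                         label_col = if (has_label) "label" else NULL)
  out <- list()
  predicted <- character(0)
  correct <- logical(0)
  if (!is.null(fs$features)) {
    ensure_tree(engine, ncol(fs$features), colnames(fs$features))
    for (i in seq_len(nrow(fs$features))) {
      x <- fs$features[i, ]
      res <- predict(engine, x)
      if (results) out[[length(out) + 1L]] <- res
      if (has_label) {
        predicted <- c(predicted, res$class_label)
        correct <- c(correct, identical(res$class_label, fs$labels[i]))
        if (update) vfdt_learn_one(engine$tree, x, fs$labels[i])
      }
    }
  }
  cache <- engine$cache
  qs <- cache$hits + cache$misses
  list(results = out,
       labels = fs$labels,
       predicted = predicted,
       correct = correct,
       summary = list(
         rows_in = n_in, rows_skipped = n_skipped,
         n_units = if (is.null(fs$features)) 0L else nrow(fs$features),
         prequential_accuracy = if (length(correct)) mean(correct) else NA_real_,
         cache_hit_rate = if (qs > 0) cache$hits / qs else NA_real_))
}

#' Leaf purity of the trained engine
#'
#' For every leaf with pointers, the fraction of pointed records whose
#' stored class equals the leaf's majority class; returns the
#' pointer-weighted mean over leaves. After initial training on separable
#' data this is the degree to which "one leaf node represents one illness
#' class".
#'
#' @param engine a [cdss_engine()].
#' @return purity in \[0, 1\] (`NaN` when no leaf holds pointers).
#' @export
leaf_purity <- function(engine) {
  pls <- vfdt_pointer_lists(engine$tree)
  agree <- 0L; total <- 0L
  for (leaf_id in names(pls)) {
    ptrs <- pls[[leaf_id]]
    if (length(ptrs) == 0L) next
    leaf <- leaf_env_by_id(engine$tree, leaf_id)
    maj <- leaf_majority(leaf)
    recs <- resolve_many(engine$store, ptrs)
    agree <- agree + sum(vapply(recs, `[[`, character(1), "class_label") == maj)
    total <- total + length(ptrs)
  }
  agree / total
}

#' Save / load an engine
#'
#' The store is already on disk; this writes the tree JSON and the engine
#' config beside it. [cdss_load()] reopens the store, reloads the tree,
#' and reconciles: any record present in the mapping table whose pointer
#' is missing from the tree (e.g. a crash between store append and tree
#' swap) is re-trained so no doctor's record is ever lost.
#'
#' @param engine a [cdss_engine()].
#' @return `cdss_save`: the directory, invisibly. `cdss_load`: the engine,
#'   with attribute `reconciled` (integer vector of re-trained pointers).
#' @export
cdss_save <- function(engine) {
  dir <- engine$store$dir
  if (!is.null(engine$tree)) {
    vfdt_save(engine$tree, file.path(dir, "tree.json"))
  }
  cfg <- engine$config
  jsonlite::write_json(
    list(unit_size = cfg$unit_size, scheme = cfg$scheme, theta = cfg$theta,
         top_k = cfg$top_k, eager = cfg$eager,
         vfdt = list(delta = cfg$vfdt$delta, tau = cfg$vfdt$tau,
                     grace_period = cfg$vfdt$grace_period)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname cdss_save
#' @param store_dir directory of a saved engine.
#' @export
cdss_load <- function(store_dir) {
  cfg_path <- file.path(store_dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    x <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cdss_config(unit_size = x$unit_size, scheme = x$scheme, theta = x$theta,
                top_k = x$top_k, eager = x$eager,
                vfdt = vfdt_config(delta = x$vfdt$delta, tau = x$vfdt$tau,
                                   grace_period = x$vfdt$grace_period))
  } else cdss_config()
  eng <- cdss_engine(store_dir, config)
  tree_path <- file.path(store_dir, "tree.json")
  if (file.exists(tree_path)) eng$tree <- vfdt_load(tree_path)
  reconciled <- integer(0)
  if (!is.null(eng$tree)) {
    known <- unlist(vfdt_pointer_lists(eng$tree), use.names = FALSE)
    orphans <- setdiff(mapping_table(eng$store)$pointer, known)
    for (p in sort(orphans)) {
      rec <- resolve(eng$store, p)
      vfdt_learn_one(eng$tree, rec$features, rec$class_label, p)
      reconciled <- c(reconciled, p)
    }
  }
  attr(eng, "reconciled") <- reconciled
  eng
}

#' @export
print.cdss_engine <- function(x, ...) {
  cat("Clinical decision-support engine\n")
  cat(sprintf("  store: %d records at %s\n", store_size(x$store),
              x$store$dir))
  if (is.null(x$tree)) cat("  tree: <untrained>\n") else {
    lt <- vfdt_leaf_table(x$tree)
    cat(sprintf("  tree: %d leaves, %d classes, %d examples\n", nrow(lt),
                length(x$tree$classes), x$tree$n_seen))
  }
  cat(sprintf("  cache: %d entries (%d hits / %d misses)\n",
              length(cache_keys(x$cache)), x$cache$hits, x$cache$misses))
  invisible(x)
}

#' @export
summary.cdss_engine <- function(object, ...) {
  out <- list(store_size = store_size(object$store),
              tree = if (is.null(object$tree)) NULL else summary(object$tree),
              cache_entries = length(cache_keys(object$cache)),
              cache_hits = object$cache$hits,
              cache_misses = object$cache$misses)
  class(out) <- "summary.cdss_engine"
  out
}

#' @export
print.summary.cdss_engine <- function(x, ...) {
  cat(sprintf("Engine: %d records, cache %d entries (%d/%d hit/miss)\n",
              x$store_size, x$cache_entries, x$cache_hits, x$cache_misses))
  if (!is.null(x$tree)) print(x$tree)
  invisible(x)
}
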