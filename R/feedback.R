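#' Doctor feedback: normalize, store, copy-train-swap
#'
#' A confirmed diagnosis arrives as a feedback event (free-text fields plus
#' either a feature vector or a raw data unit, with the doctor-assigned
#' class). It is rewritten into the uniform record format, appended to the
#' store and mapping table, and folded into the model by copy-train-swap:
#' the live tree is cloned, the clone is trained with the new record's
#' pointer, and the clone atomically replaces the live tree — queries are
#' never served by a half-trained model.
#'
#' @name feedback
#' @keywords internal
NULL

#' Construct a feedback event
#'
#' @param class_label doctor-assigned illness class (required, non-empty).
#' @param treatment_text,diagnosis_text,illness_history_text free text.
#' @param features numeric feature vector (classifier schema), or `NULL`
#'   when `unit` is given.
#' @param unit a raw `data_unit` (or samples data frame) to featurize
#'   instead of `features`.
#' @return a `feedback_event` list.
#' @export
feedback_event <- function(class_label, treatment_text = "",
                           diagnosis_text = "", illness_history_text = "",
                           features = NULL, unit = NULL) {
  structure(list(class_label = class_label,
                 treatment_text = treatment_text,
                 diagnosis_text = diagnosis_text,
                 illness_history_text = illness_history_text,
                 features = features, unit = unit),
            class = "feedback_event")
}

#' Read a feedback event from JSON
#'
#' @param path JSON file with the `feedback_event` fields.
#' @return a [feedback_event()].
#' @export
read_feedback_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feedback_event(class_label = x$class_label,
                 treatment_text = x$treatment_text %||% "",
                 diagnosis_text = x$diagnosis_text %||% "",
                 illness_history_text = x$illness_history_text %||% "",
                 features = if (!is.null(x$features)) as.numeric(x$features),
                 unit = if (!is.null(x$unit)) as.data.frame(x$unit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

canonical_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize a feedback event into a medical record
#'
#' Rewrites the free-text fields into the uniform format (lower case,
#' collapsed whitespace, trimmed — idempotent), computes features from the
#' raw unit when no feature vector was supplied, and mints the next
#' sequential record ID.
#'
#' @param event a [feedback_event()].
#' @param next_rid_number ordinal for the minted rid (`R<n>`); usually
#'   `store_size(engine$store) + 1`.
#' @param scheme feature scheme used when `event$unit` must be featurized.
#' @return a [medical_record()].
#' @export
normalize_feedback <- function(event, next_rid_number, scheme = "mslmm") {
  lab <- event$class_label
  if (is.null(lab) || !nzchar(trimws(as.character(lab)))) {
    stop("validation error: feedback event has no class label",
         call. = FALSE)
  }
  features <- event$features
  if (is.null(features)) {
    if (is.null(event$unit)) {
      stop("validation error: feedback event has neither features nor a ",
           "raw data unit", call. = FALSE)
    }
    features <- featurize(event$unit, scheme)
  }
  medical_record(
    rid = sprintf("R%d", as.integer(next_rid_number)),
    features = as.numeric(features),
    class_label = canonical_text(lab),
    treatment_text = canonical_text(event$treatment_text),
    diagnosis_text = canonical_text(event$diagnosis_text),
    illness_history_text = canonical_text(event$illness_history_text))
}

#' Ingest doctor feedback (copy-train-swap)
#'
#' Normalizes and registers the record (store append and mapping row
#' first, so the record is never lost), clones the live tree, trains the
#' clone with the new pointer, and swaps the clone in atomically. The
#' affected leaf's cache entry is invalidated and — in eager mode — its
#' consensus is re-extracted immediately. Any classification issued before
#' the swap (see `.probe`) is served by the pre-ingest tree.
#'
#' @param engine a [cdss_engine()].
#' @param event a [feedback_event()].
#' @param .probe optional function called as `.probe(engine)` after the
#'   clone is trained but before the swap; used to audit the non-blocking
#'   contract in deterministic replays (the engine still serves the old
#'   tree at that instant).
#' @return invisibly, a list with `pointer` (new pointer value), `rid`,
#'   and `leaf_id` (leaf of the live tree now holding the pointer).
#' @export
ingest <- function(engine, event, .probe = NULL) {
  rec <- normalize_feedback(event, store_size(engine$store) + 1L,
                            engine$config$scheme)
  if (is.null(engine$tree)) {
    ensure_tree(engine, length(rec$features), names(rec$features))
  } else if (length(rec$features) != engine$tree$n_features) {
    stop("schema error: feedback features length ", length(rec$features),
         " != engine schema ", engine$tree$n_features, call. = FALSE)
  }
  # store append happens before the tree swap: a crash in between leaves an
  # orphaned record that cdss_load() reconciles by re-training it
  pointer <- register_record(engine$store, rec)
  clone <- vfdt_clone(engine$tree)
  vfdt_learn_one(clone, rec$features, rec$class_label, pointer)
  if (!is.null(.probe)) .probe(engine)
  engine$tree <- clone                       # atomic swap
  leaf_id <- vfdt_classify(engine$tree, rec$features)$leaf_id
  invalidate(engine$cache, leaf_id)
  log_event(engine, "ingest", pointer = pointer, leaf = leaf_id)
  if (engine$config$eager) cdss_predict_leaf(engine, leaf_id)
  invisible(list(pointer = pointer, rid = rec$rid, leaf_id = leaf_id))
}
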