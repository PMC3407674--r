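#' Historical medical-record store and mapping table
#'
#' Records (feature vector, illness class, free-text treatment / diagnosis /
#' illness-history fields) are persisted append-only to a JSON-lines file.
#' Each registration mints the next sequential *pointer value* (the first
#' record R1 gets pointer P1 with value 1) and appends one row to the
#' mapping table: pointer value, record ID, and the physical address the
#' record can be read from directly. The physical address is the store file
#' plus a byte offset, printed as a 16-hex-digit offset.
#'
#' @name record_store
#' @keywords internal
NULL

#' Construct a medical record
#'
#' @param rid unique record ID (e.g. `"R1"`).
#' @param features numeric feature vector (classifier schema).
#' @param class_label illness class label (non-empty string).
#' @param treatment_text,diagnosis_text,illness_history_text free text.
#' @return a `medical_record` list.
#' @export
medical_record <- function(rid, features, class_label,
                           treatment_text = "", diagnosis_text = "",
                           illness_history_text = "") {
  stopifnot(is.character(rid), length(rid) == 1L, nzchar(rid),
            is.numeric(features), length(features) >= 1L,
            is.character(class_label), length(class_label) == 1L,
            nzchar(class_label))
  structure(list(rid = rid,
                 features = as.numeric(features),
                 class_label = class_label,
                 treatment_text = as.character(treatment_text),
                 diagnosis_text = as.character(diagnosis_text),
                 illness_history_text = as.character(illness_history_text)),
            class = "medical_record")
}

#' @export
print.medical_record <- function(x, ...) {
  cat(sprintf("<medical_record %s: class '%s', %d features>\n", x$rid,
              x$class_label, length(x$features)))
  invisible(x)
}

#' Open (or create) a record store
#'
#' @param dir directory holding `records.jsonl` (append-only records) and
#'   `mapping.tsv` (the mapping table). Created if absent; reopening a
#'   populated directory reloads the mapping table.
#' @return a `record_store` object (environment).
#' @export
record_store <- function(dir = tempfile("store")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  st$dir <- dir
  st$records_path <- file.path(dir, "records.jsonl")
  st$mapping_path <- file.path(dir, "mapping.tsv")
  if (file.exists(st$mapping_path)) {
    mp <- utils::read.delim(st$mapping_path, stringsAsFactors = FALSE,
                            colClasses = c("integer", "character", "character"))
    st$pointers <- mp$pointer
    st$rids <- mp$rid
    st$addresses <- mp$address
  } else {
    st$pointers <- integer(0)
    st$rids <- character(0)
    st$addresses <- character(0)
    writeLines("pointer\trid\taddress", st$mapping_path)
  }
  st$rid_set <- new.env(parent = emptyenv())
  for (r in st$rids) assign(r, TRUE, envir = st$rid_set)
  if (!file.exists(st$records_path)) file.create(st$records_path)
  st$schema_len <- NULL
  class(st) <- "record_store"
  if (length(st$pointers) > 0L) {
    st$schema_len <- length(resolve(st, st$pointers[1])$features)
  }
  st
}

format_address <- function(path, offset) {
  sprintf("%s:%016X", basename(path), offset)
}

parse_address <- function(store, address) {
  parts <- strsplit(address, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("storage-corruption error: bad address '", address, "'",
         call. = FALSE)
  }
  list(path = file.path(store$dir, parts[1]),
       offset = strtoi(parts[2], base = 16L))
}

#' Register a record and mint its pointer
#'
#' Appends the record to the store file, assigns the next sequential
#' pointer value (1 for the first record), and adds the (pointer, rid,
#' physical address) row to the mapping table.
#'
#' @param store a [record_store()].
#' @param record a [medical_record()]; its `rid` must be new.
#' @return the pointer value (integer).
#' @export
register_record <- function(store, record) {
  stopifnot(inherits(record, "medical_record"))
  if (!is.null(get0(record$rid, envir = store$rid_set))) {
    stop("uniqueness error: rid '", record$rid, "' already registered",
         call. = FALSE)
  }
  if (is.null(store$schema_len)) {
    store$schema_len <- length(record$features)
  } else if (length(record$features) != store$schema_len) {
    stop("schema error: feature length ", length(record$features),
         " != store schema ", store$schema_len, call. = FALSE)
  }
  offset <- file.size(store$records_path)
  line <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA)
  con <- file(store$records_path, open = "ab")
  on.exit(close(con))
  writeLines(line, con)
  pointer <- length(store$pointers) + 1L
  address <- format_address(store$records_path, offset)
  store$pointers[pointer] <- pointer
  store$rids[pointer] <- record$rid
  store$addresses[pointer] <- address
  assign(record$rid, TRUE, envir = store$rid_set)
  cat(sprintf("%d\t%s\t%s\n", pointer, record$rid, address),
      file = store$mapping_path, append = TRUE)
  pointer
}

#' Resolve a pointer to its record
#'
#' Looks the pointer up in the mapping table and reads the record directly
#' from its physical address (file + byte offset).
#'
#' @param store a [record_store()].
#' @param pointer a pointer value present in the mapping table.
#' @return the [medical_record()].
#' @export
resolve <- function(store, pointer) {
  i <- match(as.integer(pointer), store$pointers)
  if (is.na(i)) {
    stop("lookup error: unknown pointer ", pointer, call. = FALSE)
  }
  addr <- parse_address(store, store$addresses[i])
  con <- file(addr$path, open = "rb")
  on.exit(close(con))
  seek(con, where = addr$offset, origin = "start")
  line <- readLines(con, n = 1L, warn = FALSE)
  if (length(line) == 0L || !nzchar(line)) {
    stop("storage-corruption error: empty record at ",
         store$addresses[i], call. = FALSE)
  }
  x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  medical_record(x$rid, as.numeric(x$features), x$class_label,
                 x$treatment_text, x$diagnosis_text, x$illness_history_text)
}

#' Resolve several pointers, preserving order
#'
#' Atomic: one unknown pointer fails the whole batch before any I/O.
#'
#' @param store a [record_store()].
#' @param pointers integer vector of pointer values.
#' @return list of [medical_record()]s in input order.
#' @export
resolve_many <- function(store, pointers) {
  pointers <- as.integer(pointers)
  if (length(pointers) == 0L) return(list())
  idx <- match(pointers, store$pointers)
  if (anyNA(idx)) {
    stop("lookup error: unknown pointer(s) ",
         paste(pointers[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  # one connection per distinct file, seeking record by record
  addrs <- lapply(store$addresses[idx], function(a) parse_address(store, a))
  paths <- vapply(addrs, `[[`, character(1), "path")
  cons <- lapply(unique(paths), function(p) file(p, open = "rb"))
  names(cons) <- unique(paths)
  on.exit(lapply(cons, close))
  lapply(seq_along(pointers), function(k) {
    con <- cons[[paths[k]]]
    seek(con, where = addrs[[k]]$offset, origin = "start")
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || !nzchar(line)) {
      stop("storage-corruption error: empty record at ",
           store$addresses[idx[k]], call. = FALSE)
    }
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    medical_record(x$rid, as.numeric(x$features), x$class_label,
                   x$treatment_text, x$diagnosis_text,
                   x$illness_history_text)
  })
}

#' The mapping table
#'
#' @param store a [record_store()].
#' @return data frame with columns `pointer`, `rid`, `address`.
#' @export
mapping_table <- function(store) {
  data.frame(pointer = store$pointers, rid = store$rids,
             address = store$addresses, stringsAsFactors = FALSE)
}

#' Number of registered records
#' @param store a [record_store()].
#' @export
store_size <- function(store) length(store$pointers)

#' @export
print.record_store <- function(x, ...) {
  cat(sprintf("<record_store at %s: %d records>\n", x$dir, store_size(x)))
  invisible(x)
}
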