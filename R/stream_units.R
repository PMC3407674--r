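#' Vital-sign stream segmentation and featurization
#'
#' A vital-sign stream is a sequence of timestamped multichannel readings
#' (one numeric value per bedside monitor: blood pressure, ECG-derived rate,
#' EEG index, body temperature, ...). The classifier does not consume raw
#' time points; consecutive points are grouped into fixed-size *data units*
#' (e.g. `U1 = {T1,T2,T3}`), each summarizing the short-term trend of the
#' patient's state, and every unit is reduced to one feature vector.
#'
#' @name stream_units
#' @keywords internal
NULL

#' Construct a vital-sign sample table
#'
#' Validates a data frame of readings: a strictly increasing `timestamp`
#' column followed by one numeric column per channel. This is the in-memory
#' form of the stream CSV (`timestamp,ch1,...,chk`).
#'
#' @param df data frame with a `timestamp` column and >= 1 numeric channel
#'   columns.
#' @return the validated data frame with class `vital_samples`.
#' @export
vital_samples <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"timestamp" %in% names(df)) {
    stop("malformed stream: no 'timestamp' column", call. = FALSE)
  }
  ch <- setdiff(names(df), "timestamp")
  if (length(ch) < 1L) {
    stop("malformed stream: no channel columns", call. = FALSE)
  }
  for (c in ch) {
    if (!is.numeric(df[[c]])) {
      stop(sprintf("malformed stream: channel '%s' is not numeric", c),
           call. = FALSE)
    }
  }
  if (anyNA(df[ch])) {
    stop("malformed stream: missing channel readings are rejected, not imputed",
         call. = FALSE)
  }
  ts <- df$timestamp
  if (nrow(df) > 1L && any(diff(as.numeric(ts)) <= 0)) {
    stop("stream ordering error: timestamps must strictly increase",
         call. = FALSE)
  }
  structure(df, class = c("vital_samples", "data.frame"))
}

#' Read a vital-sign stream from CSV
#'
#' @param path CSV file with header `timestamp,ch1,...,chk`.
#' @return a `vital_samples` data frame.
#' @export
read_stream_csv <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  vital_samples(utils::read.csv(path, check.names = FALSE))
}

#' Write a vital-sign stream to CSV
#'
#' @param samples a `vital_samples` data frame.
#' @param path output file.
#' @export
write_stream_csv <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Segment a stream into fixed-size data units
#'
#' Splits consecutive samples into complete windows of `unit_size` time
#' points. Only complete units are emitted; a trailing partial window is
#' returned as a carry buffer so streaming ingestion can resume when more
#' rows arrive. Concatenating the emitted units and the carry buffer
#' reproduces the input exactly.
#'
#' @param samples a `vital_samples` data frame (or coercible data frame).
#' @param unit_size number of consecutive time points per unit (>= 1).
#' @param carry optional carry buffer from a previous call (a
#'   `vital_samples` data frame or `NULL`); its rows are prepended.
#' @param first_unit_id unit id assigned to the first emitted unit.
#' @return a list with `units` (list of `data_unit`), `carry` (data frame of
#'   leftover samples, possibly 0-row) and `next_unit_id`.
#' @export
segment <- function(samples, unit_size = 3L, carry = NULL, first_unit_id = 1L) {
  stopifnot(unit_size >= 1L)
  samples <- as.data.frame(samples)
  if (!is.null(carry) && nrow(carry) > 0L) {
    if (!identical(names(carry), names(samples))) {
      stop("malformed stream: carry buffer schema differs from samples",
           call. = FALSE)
    }
    samples <- rbind(as.data.frame(carry), samples)
  }
  samples <- vital_samples(samples)
  n <- nrow(samples)
  n_units <- n %/% unit_size
  units <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    rows <- samples[((i - 1L) * unit_size + 1L):(i * unit_size), , drop = FALSE]
    units[[i]] <- new_data_unit(first_unit_id + i - 1L, rows)
  }
  rest <- samples[seq_len(n) > n_units * unit_size, , drop = FALSE]
  list(units = units,
       carry = as.data.frame(rest),
       next_unit_id = first_unit_id + n_units)
}

new_data_unit <- function(unit_id, rows) {
  structure(list(unit_id = as.integer(unit_id),
                 samples = as.data.frame(rows)),
            class = "data_unit")
}

#' @export
print.data_unit <- function(x, ...) {
  cat(sprintf("<data_unit %d: %d samples x %d channels>\n", x$unit_id,
              nrow(x$samples), ncol(x$samples) - 1L))
  invisible(x)
}

#' Featurize a data unit
#'
#' Reduces one data unit to the numeric vector the classifier consumes.
#' The default `"mslmm"` scheme emits, per channel, the tuple
#' (mean, least-squares slope, min, max): level plus direction of the
#' short-term trend. Time points are treated as equispaced within the unit,
#' so with a single sample the slope is 0 and the mean is the raw reading.
#' The output is channel-major and deterministically named
#' `<channel>.<stat>`.
#'
#' @param unit a `data_unit` (or a `vital_samples` data frame treated as one
#'   unit).
#' @param scheme feature scheme name; `"mslmm"` (mean/slope/min/max) is the
#'   only built-in scheme.
#' @return named numeric vector of length `n_channels * 4`.
#' @export
featurize <- function(unit, scheme = "mslmm") {
  if (!identical(scheme, "mslmm")) {
    stop(sprintf("configuration error: unknown feature scheme '%s'", scheme),
         call. = FALSE)
  }
  rows <- if (inherits(unit, "data_unit")) unit$samples else as.data.frame(unit)
  stopifnot(nrow(rows) >= 1L)
  ch <- setdiff(names(rows), "timestamp")
  n <- nrow(rows)
  # equispaced time index centred at 0 gives the closed-form OLS slope
  t0 <- seq_len(n) - (n + 1) / 2
  stt <- sum(t0 * t0)
  out <- numeric(0)
  for (c in ch) {
    x <- rows[[c]]
    slope <- if (n == 1L) 0 else sum(t0 * x) / stt
    v <- c(mean(x), slope, min(x), max(x))
    names(v) <- paste(c, c("mean", "slope", "min", "max"), sep = ".")
    out <- c(out, v)
  }
  out
}

#' Featurize a whole stream
#'
#' Convenience wrapper: segment then featurize every complete unit.
#'
#' @inheritParams segment
#' @inheritParams featurize
#' @param label_col optional name of a per-sample label column; when
#'   present, each unit's label is the label of its first sample and labels
#'   are excluded from the features.
#' @return list with `features` (matrix, one row per unit), `unit_ids`,
#'   `labels` (or `NULL`) and `carry`.
#' @export
featurize_stream <- function(samples, unit_size = 3L, scheme = "mslmm",
                             label_col = NULL) {
  samples <- as.data.frame(samples)
  labels_all <- NULL
  if (!is.null(label_col) && label_col %in% names(samples)) {
    labels_all <- as.character(samples[[label_col]])
    samples <- samples[setdiff(names(samples), label_col)]
  }
  seg <- segment(samples, unit_size)
  if (length(seg$units) == 0L) {
    return(list(features = NULL, unit_ids = integer(0), labels = NULL,
                carry = seg$carry))
  }
  feats <- t(vapply(seg$units, featurize, scheme = scheme,
                    FUN.VALUE = featurize(seg$units[[1]], scheme)))
  labels <- NULL
  if (!is.null(labels_all)) {
    labels <- labels_all[(seq_along(seg$units) - 1L) * unit_size + 1L]
  }
  list(features = feats,
       unit_ids = vapply(seg$units, `[[`, integer(1), "unit_id"),
       labels = labels,
       carry = seg$carry)
}

#' Serialize / restore a carry buffer
#'
#' The trailing partial window survives process restarts as a small JSON
#' document, making streaming ingestion resumable.
#'
#' @param carry data frame of leftover samples (possibly 0-row).
#' @param path JSON file path.
#' @export
save_carry <- function(carry, path) {
  jsonlite::write_json(as.data.frame(carry), path, digits = NA)
  invisible(path)
}

#' @rdname save_carry
#' @export
load_carry <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
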