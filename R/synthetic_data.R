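#' Synthetic vital-sign streams and record corpora
#'
#' Every stage of the engine is testable without real patient data: a
#' *class regime* describes one illness class as per-channel Gaussian
#' levels (mean, noise sd, within-unit drift slope) plus categorical
#' phrase distributions for the treatment / diagnosis / illness-history
#' fields, each with a designated modal phrase. Streams draw one regime
#' uniformly per data unit; records draw a regime, synthesize one unit for
#' the features, and sample the three text fields. Ground truth (regime
#' parameters, planted modal phrases, a Bayes-error bound) is reported in a
#' manifest.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Define a phrase distribution with a planted mode
#'
#' @param phrases character vector of distinct phrases.
#' @param probs matching probabilities (sum to 1); the first phrase must
#'   carry strictly the highest probability and is the planted mode.
#' @return data frame `phrase`, `prob` with attribute `modal`.
#' @export
phrase_dist <- function(phrases, probs) {
  stopifnot(length(phrases) == length(probs), all(probs > 0),
            abs(sum(probs) - 1) < 1e-9,
            probs[1] > max(probs[-1][is.finite(probs[-1])], 0))
  out <- data.frame(phrase = phrases, prob = probs, stringsAsFactors = FALSE)
  attr(out, "modal") <- phrases[1]
  out
}

#' Define a class regime
#'
#' @param label class label.
#' @param means per-channel mean vector (named by channel).
#' @param sds per-channel noise standard deviations (>= 0).
#' @param drifts per-channel within-unit drift slopes (units per time
#'   point).
#' @param treatment,diagnosis,history [phrase_dist()]s for the three text
#'   fields.
#' @return a `class_regime` list.
#' @export
class_regime <- function(label, means, sds, drifts = 0 * means,
                         treatment, diagnosis, history) {
  stopifnot(length(means) == length(sds), length(means) == length(drifts),
            all(sds >= 0))
  structure(list(label = label, means = means, sds = sds, drifts = drifts,
                 treatment = treatment, diagnosis = diagnosis,
                 history = history),
            class = "class_regime")
}

#' Default three-regime study conditions
#'
#' Three well-separated illness classes over the four canonical monitor
#' channels (systolic blood pressure in mmHg, ECG-derived heart rate in
#' bpm, an EEG burden index in arbitrary units, body temperature in
#' degrees C). Class means differ by at least 5 noise standard deviations
#' on at least one channel, so the regime mixture's Bayes-error bound is
#' far below 1%. Each text field has a modal phrase at probability 0.45, a
#' distinct runner-up at 0.25, a third phrase at 0.15, and a paraphrase of
#' the mode (sharing >= 80% of its tokens) at 0.15, exercising the
#' description-grouping step.
#'
#' @return list of three [class_regime()]s.
#' @export
default_regimes <- function() {
  ch <- c("bp", "hr", "eeg", "temp")
  mk_phrases <- function(mode, variant, runner, third) {
    phrase_dist(c(mode, runner, third, variant), c(0.45, 0.25, 0.15, 0.15))
  }
  list(
    class_regime(
      "stable",
      means = stats::setNames(c(120, 75, 50, 36.8), ch),
      sds = stats::setNames(c(5, 4, 4, 0.3), ch),
      treatment = mk_phrases(
        "continue current medication and routine observation",
        "continue current medication with routine observation",
        "no intervention required schedule follow up visit",
        "discharge planning with outpatient review"),
      diagnosis = mk_phrases(
        "patient condition stable no acute findings",
        "patient condition is stable no acute findings",
        "vital signs within normal limits",
        "no abnormality detected on monitoring"),
      history = mk_phrases(
        "previously stable course without complications",
        "previously stable course with no complications",
        "intermittent mild symptoms resolved spontaneously",
        "unremarkable clinical history to date")),
    class_regime(
      "cardiac",
      means = stats::setNames(c(95, 130, 55, 37.0), ch),
      sds = stats::setNames(c(5, 4, 4, 0.3), ch),
      drifts = stats::setNames(c(-1.5, 2, 0, 0), ch),
      treatment = mk_phrases(
        "administer beta blocker and monitor blood pressure closely",
        "administer beta blocker and watch blood pressure closely",
        "start intravenous fluids and continuous ecg monitoring",
        "prepare catheterization lab and notify cardiology"),
      diagnosis = mk_phrases(
        "acute cardiac decompensation with tachycardia",
        "acute cardiac decompensation and tachycardia",
        "hypotension with compensatory tachycardia",
        "suspected myocardial ischemia on telemetry"),
      history = mk_phrases(
        "prior episodes of tachycardia responding to beta blockade",
        "prior episodes of tachycardia that responded to beta blockade",
        "known coronary artery disease on medication",
        "recurrent palpitations over recent months")),
    class_regime(
      "neuro",
      means = stats::setNames(c(125, 80, 80, 38.5), ch),
      sds = stats::setNames(c(5, 4, 4, 0.3), ch),
      drifts = stats::setNames(c(0, 0, 1.5, 0.05), ch),
      treatment = mk_phrases(
        "load anticonvulsant and obtain urgent neurology consult",
        "load anticonvulsant and request urgent neurology consult",
        "administer antipyretics and order head imaging",
        "initiate seizure precautions and continuous eeg"),
      diagnosis = mk_phrases(
        "encephalopathy with elevated eeg burden and fever",
        "encephalopathy with raised eeg burden and fever",
        "febrile state with abnormal cortical activity",
        "possible central nervous system infection"),
      history = mk_phrases(
        "prior seizure activity controlled with anticonvulsants",
        "prior seizure activity well controlled with anticonvulsants",
        "recent febrile illness with confusion",
        "longstanding epilepsy with good control")))
}

sample_phrase <- function(dist) {
  sample(dist$phrase, 1L, prob = dist$prob)
}

#' Generate a labeled vital-sign stream
#'
#' Emits `n_units * unit_size` samples. Each data unit is drawn wholly
#' from one regime chosen uniformly; within a unit, channel values are
#' `mean + drift * s + N(0, sd)` where `s = 0 .. unit_size-1` is the
#' within-unit time index, so the drift slope is the unit's short-term
#' trend. Fully reproducible from `seed`.
#'
#' @param regimes list of [class_regime()]s.
#' @param n_units number of complete data units (>= 1).
#' @param unit_size samples per unit.
#' @param seed integer seed.
#' @return data frame: `timestamp`, one column per channel, and `label`
#'   (the generating regime, constant within each unit).
#' @export
generate_stream <- function(regimes = default_regimes(), n_units = 100L,
                            unit_size = 3L, seed = 1L) {
  stopifnot(length(regimes) >= 1L, n_units >= 1L, unit_size >= 1L)
  set.seed(seed)
  ch <- names(regimes[[1]]$means)
  k <- length(ch)
  ridx <- sample.int(length(regimes), n_units, replace = TRUE)
  n <- n_units * unit_size
  vals <- matrix(NA_real_, nrow = n, ncol = k, dimnames = list(NULL, ch))
  lab <- character(n)
  s <- 0:(unit_size - 1)
  for (u in seq_len(n_units)) {
    rg <- regimes[[ridx[u]]]
    rows <- ((u - 1L) * unit_size + 1L):(u * unit_size)
    for (j in seq_len(k)) {
      vals[rows, j] <- rg$means[j] + rg$drifts[j] * s +
        stats::rnorm(unit_size, 0, rg$sds[j])
    }
    lab[rows] <- rg$label
  }
  out <- data.frame(timestamp = seq_len(n), vals, label = lab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}

#' Generate a synthetic medical-record corpus
#'
#' Each record draws a regime uniformly, takes its features from one
#' synthesized data unit (via [featurize()]), and samples its three text
#' fields from the regime's phrase distributions. The attached manifest
#' records the ground truth.
#'
#' @param regimes list of [class_regime()]s.
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @param unit_size samples per synthesized unit.
#' @param rid_start first record number (rids are `R<rid_start>` onward).
#' @return list of [medical_record()]s with attribute `manifest` (see
#'   [regime_manifest()]).
#' @export
generate_records <- function(regimes = default_regimes(), n = 100L,
                             seed = 1L, unit_size = 3L, rid_start = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  ch <- names(regimes[[1]]$means)
  s <- 0:(unit_size - 1)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    rg <- regimes[[sample.int(length(regimes), 1L)]]
    vals <- vapply(seq_along(ch), function(j)
      rg$means[j] + rg$drifts[j] * s + stats::rnorm(unit_size, 0, rg$sds[j]),
      numeric(unit_size))
    unit <- data.frame(timestamp = s + 1, matrix(vals, nrow = unit_size,
                                                 dimnames = list(NULL, ch)),
                       check.names = FALSE)
    recs[[i]] <- medical_record(
      rid = sprintf("R%d", rid_start + i - 1L),
      features = featurize(unit),
      class_label = rg$label,
      treatment_text = sample_phrase(rg$treatment),
      diagnosis_text = sample_phrase(rg$diagnosis),
      illness_history_text = sample_phrase(rg$history))
  }
  attr(recs, "manifest") <- regime_manifest(regimes)
  recs
}

#' Ground-truth manifest for a regime set
#'
#' Collects regime parameters, the planted modal phrase of every text
#' field, and a Bayes-error bound for the per-sample channel mixture: with
#' equal priors and shared diagonal covariance the two-class Bayes error is
#' exactly `pnorm(-Delta/2)` where `Delta` is the Mahalanobis separation of
#' the class means; for more than two classes the pairwise union bound
#' `(1/K) * sum_{i != j} pnorm(-Delta_ij/2)` is reported (an upper bound;
#' unit-level features separate at least this well).
#'
#' @param regimes list of [class_regime()]s.
#' @return list with `regimes` (parameters), `modal_phrases`,
#'   `bayes_error_bound`.
#' @export
regime_manifest <- function(regimes) {
  K <- length(regimes)
  err <- 0
  if (K >= 2) {
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (i == j) next
        sd2 <- (regimes[[i]]$sds^2 + regimes[[j]]$sds^2) / 2
        delta <- sqrt(sum((regimes[[i]]$means - regimes[[j]]$means)^2 / sd2))
        err <- err + stats::pnorm(-delta / 2) / K
      }
    }
  }
  list(
    regimes = lapply(regimes, function(rg)
      list(label = rg$label, means = rg$means, sds = rg$sds,
           drifts = rg$drifts)),
    modal_phrases = lapply(regimes, function(rg)
      list(label = rg$label,
           treatment = attr(rg$treatment, "modal"),
           diagnosis = attr(rg$diagnosis, "modal"),
           history = attr(rg$history, "modal"))),
    bayes_error_bound = err)
}

#' Write a record corpus as JSON-lines (plus manifest)
#'
#' @param records output of [generate_records()].
#' @param path JSON-lines output file; the manifest (when attached) is
#'   written beside it as `<path>.manifest.json`.
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  mf <- attr(records, "manifest")
  if (!is.null(mf)) {
    jsonlite::write_json(mf, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a record corpus from JSON-lines
#'
#' @param path JSON-lines file, one record per line.
#' @return list of [medical_record()]s.
#' @export
read_records_jsonl <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    medical_record(x$rid, as.numeric(x$features), x$class_label,
                   x$treatment_text, x$diagnosis_text,
                   x$illness_history_text)
  })
}
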