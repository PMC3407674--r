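#' Consensus extraction from retrieved records
#'
#' The free-text treatment / diagnosis / illness-history fields of similar
#' records are written by different doctors, so the same advice appears
#' under varying wording. Before counting, texts are grouped as
#' "same meaning, different expression": single-linkage clustering under a
#' token-set cosine similarity (after lowercasing, punctuation stripping
#' and optional synonym substitution). The most frequent group then gives
#' the consensus, formatted as the numbered list `1.… 2.… 3.…`.
#'
#' @name prediction
#' @keywords internal
NULL

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

tokenize <- function(x, synonyms = NULL) {
  toks <- strsplit(normalize_text(x), " ", fixed = TRUE)
  lapply(toks, function(t) {
    t <- t[nzchar(t)]
    if (!is.null(synonyms)) {
      i <- match(t, synonyms$term)
      t[!is.na(i)] <- synonyms$canonical[i[!is.na(i)]]
    }
    unique(t)
  })
}

#' Token-set cosine similarity between two texts
#'
#' `|A ∩ B| / sqrt(|A| |B|)` over the (deduplicated, normalized) token sets
#' A and B; two empty texts have similarity 1, one empty text similarity 0.
#'
#' @param a,b character strings.
#' @param synonyms optional synonym table (see [read_synonyms()]).
#' @return similarity in \[0, 1\].
#' @export
text_similarity <- function(a, b, synonyms = NULL) {
  ts <- tokenize(c(a, b), synonyms)
  ta <- ts[[1]]; tb <- ts[[2]]
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  length(intersect(ta, tb)) / sqrt(length(ta) * length(tb))
}

#' Read a synonym table
#'
#' Two-column TSV (`term`, `canonical`); each occurrence of `term` is
#' replaced by `canonical` before similarity is computed.
#'
#' @param path TSV file path.
#' @return data frame with columns `term` and `canonical`.
#' @export
read_synonyms <- function(path) {
  sy <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "canonical") %in% names(sy)))
  sy
}

#' Group equivalent free-text descriptions
#'
#' Single-linkage grouping: two texts join the same group whenever a chain
#' of pairs with token-set cosine similarity >= `theta` connects them.
#' Each input text lands in exactly one group; the group representative is
#' the most frequent exact string in the group (ties broken
#' lexicographically).
#'
#' @param texts non-empty character vector.
#' @param theta similarity threshold in \[0, 1\].
#' @param synonyms optional synonym table.
#' @return data frame with one row per group: `representative`, `count`,
#'   `group_id`, ordered by count (desc) then representative; plus
#'   attribute `membership`, an integer vector assigning each input text
#'   its group_id.
#' @export
group_descriptions <- function(texts, theta = 0.5, synonyms = NULL) {
  stopifnot(length(texts) >= 1L, theta >= 0, theta <= 1)
  texts <- as.character(texts)
  # work on distinct strings; identical strings are always one group member
  uniq <- unique(texts)
  tok <- tokenize(uniq, synonyms)
  vocab <- unique(unlist(tok))
  m <- length(uniq)
  if (length(vocab) == 0L || m == 1L) {
    comp <- rep(1L, m)
  } else {
    # binary term-document matrix -> cosine similarity by crossprod
    td <- matrix(0, nrow = length(vocab), ncol = m)
    for (i in seq_len(m)) td[match(tok[[i]], vocab), i] <- 1
    sizes <- colSums(td)
    sim <- crossprod(td)
    denom <- sqrt(outer(sizes, sizes))
    sim <- ifelse(denom > 0, sim / denom, 0)
    # empty-text convention: empty~empty similar, empty~nonempty not
    empty <- sizes == 0
    if (any(empty)) sim[empty, empty] <- 1
    adj <- sim >= theta
    diag(adj) <- TRUE
    comp <- connected_components(adj)
  }
  membership <- comp[match(texts, uniq)]
  groups <- lapply(sort(unique(comp)), function(g) {
    members <- texts[membership == g]
    tab <- table(members)
    reps <- names(tab)[tab == max(tab)]
    list(representative = sort(reps)[1], count = length(members))
  })
  out <- data.frame(
    representative = vapply(groups, `[[`, character(1), "representative"),
    count = vapply(groups, `[[`, integer(1), "count"),
    stringsAsFactors = FALSE)
  ord <- order(-out$count, out$representative)
  relabel <- match(seq_len(nrow(out)), ord)
  out <- out[ord, , drop = FALSE]
  out$group_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "membership") <- relabel[membership]
  out
}

# union-find over a symmetric logical adjacency matrix
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Top-k most frequent description groups
#'
#' @param groups output of [group_descriptions()].
#' @param k number of groups to keep (>= 1).
#' @return the first `min(k, nrow)` rows: count-descending, ties by
#'   representative.
#' @export
most_frequent <- function(groups, k = 3L) {
  stopifnot(k >= 1)
  utils::head(groups, k)
}

#' Format ranked groups as a numbered list
#'
#' @param groups output of [group_descriptions()] or [most_frequent()].
#' @return single string `"1.<top> 2.<second> ..."`.
#' @export
format_ranked <- function(groups) {
  if (nrow(groups) == 0L) return("")
  paste(sprintf("%d.%s", seq_len(nrow(groups)), groups$representative),
        collapse = " ")
}

#' Quadratic-form metric distance
#'
#' The retrieval-baseline distance `d(x_i, x_j) = (x_i - x_j)' P (x_i - x_j)`
#' with a positive semidefinite metric matrix `P`. With `P = I` this is the
#' squared Euclidean distance.
#'
#' @param x_i,x_j numeric feature vectors of equal length.
#' @param P square symmetric PSD matrix matching the vectors; default
#'   identity.
#' @param tol eigenvalue tolerance for the PSD check.
#' @return nonnegative scalar; 0 when `x_i == x_j`.
#' @export
lsml_distance <- function(x_i, x_j, P = NULL, tol = 1e-8) {
  x_i <- as.numeric(x_i); x_j <- as.numeric(x_j)
  stopifnot(length(x_i) == length(x_j))
  if (is.null(P)) P <- diag(length(x_i))
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(x_i), ncol(P) == length(x_i))
  check_psd(P, tol)
  d <- x_i - x_j
  max(drop(crossprod(d, P %*% d)), 0)
}

check_psd <- function(P, tol = 1e-8) {
  if (max(abs(P - t(P))) > tol) {
    stop("validity error: metric matrix is not symmetric", call. = FALSE)
  }
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop("validity error: metric matrix is not positive semidefinite",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-leaf prediction cache
#'
#' Maps a leaf id to its extracted [PredictionResult] together with the
#' leaf's pointer-list version stamp at extraction time. An entry is served
#' only while its stamp equals the leaf's current version; the Adder bumps
#' the version whenever a new pointer lands on the leaf, so stale advice is
#' never returned.
#'
#' @return a `prediction_cache` environment.
#' @export
prediction_cache <- function() {
  cc <- new.env(parent = emptyenv())
  cc$entries <- new.env(parent = emptyenv())
  cc$hits <- 0L
  cc$misses <- 0L
  class(cc) <- "prediction_cache"
  cc
}

cache_get <- function(cache, leaf_id, version) {
  e <- get0(leaf_id, envir = cache$entries)
  if (!is.null(e) && identical(e$version, version)) {
    cache$hits <- cache$hits + 1L
    return(e$result)
  }
  cache$misses <- cache$misses + 1L
  NULL
}

cache_put <- function(cache, leaf_id, version, result) {
  assign(leaf_id, list(version = version, result = result),
         envir = cache$entries)
  invisible(cache)
}

#' Drop a leaf's cached prediction
#'
#' Idempotent; dropping an absent entry is a no-op.
#'
#' @param cache a [prediction_cache()].
#' @param leaf_id leaf whose entry to drop.
#' @export
invalidate <- function(cache, leaf_id) {
  if (exists(leaf_id, envir = cache$entries)) {
    rm(list = leaf_id, envir = cache$entries)
  }
  invisible(cache)
}

cache_keys <- function(cache) ls(cache$entries)

#' @export
print.prediction_cache <- function(x, ...) {
  cat(sprintf("<prediction_cache: %d entries, %d hits, %d misses>\n",
              length(cache_keys(x)), x$hits, x$misses))
  invisible(x)
}
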