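#' Tokenize an attribute phrase
#'
#' Lowercases the text, strips every character that is not a letter or a
#' digit, and splits on whitespace. This is the tokenizer used for all six
#' CDE attributes before word-level similarity is computed.
#'
#' @param text A character string (length one). Empty text is allowed.
#' @return A character vector of lowercase tokens; `character(0)` for empty
#'   or punctuation-only input.
#' @examples
#' tokenize("What was the classification of the acute myelogenous leukemia?")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- paste(text, collapse = " ")
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Levenshtein edit distance between two words
#'
#' Unit-cost insertion, deletion and substitution distance, computed with
#' [utils::adist()].
#'
#' @param a,b Character strings.
#' @return A non-negative integer.
#' @examples
#' edit_distance("what", "was") # 2
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Word similarity 1 - d/l
#'
#' Similarity between two words: one minus the edit distance divided by the
#' length of the longer word. Lies in \[0, 1\] and equals 1 exactly when the
#' words are identical.
#'
#' @param a,b Character strings; at least one must be non-empty.
#' @return A number in \[0, 1\].
#' @examples
#' word_similarity("what", "was") # 0.5
#' @export
word_similarity <- function(a, b) {
  l <- max(nchar(a), nchar(b))
  if (l == 0L) stop_cde("word_similarity is undefined for two empty words")
  1 - edit_distance(a, b) / l
}

# |a| x |b| matrix of word similarities for two token vectors
word_similarity_matrix <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    return(matrix(numeric(0), nrow = length(a), ncol = length(b)))
  d <- utils::adist(a, b)
  l <- outer(nchar(a), nchar(b), pmax)
  1 - d / l
}

#' Greedy reduction of a word-similarity matrix
#'
#' Repeatedly extracts the current global maximum of the matrix, appends it
#' to the output, and deletes the row and column it occupies, until one
#' dimension is exhausted. Ties are broken towards the smallest row index,
#' then the smallest column index. The returned values are non-increasing
#' and there are `min(nrow, ncol)` of them.
#'
#' @param m A numeric matrix of similarities.
#' @return A non-increasing numeric vector of length `min(dim(m))`.
#' @examples
#' greedy_max_reduce(matrix(c(0.9, 0.8, 0.4, 0.7), 2)) # 0.9 0.7
#' @export
greedy_max_reduce <- function(m) {
  k <- min(dim(m))
  if (k == 0L) return(numeric(0))
  # scanning cells in (-value, row, col) order and keeping each cell whose
  # row and column are still free is equivalent to repeated global-max
  # extraction with the same tie-break
  v <- as.vector(m)
  ord <- order(-v, as.vector(row(m)), as.vector(col(m)))
  row_used <- logical(nrow(m))
  col_used <- logical(ncol(m))
  out <- numeric(k)
  got <- 0L
  for (idx in ord) {
    i <- (idx - 1L) %% nrow(m) + 1L
    j <- (idx - 1L) %/% nrow(m) + 1L
    if (row_used[i] || col_used[j]) next
    row_used[i] <- TRUE
    col_used[j] <- TRUE
    got <- got + 1L
    out[got] <- v[idx]
    if (got == k) break
  }
  out
}

#' Greedy word-similarity list for two token sequences
#'
#' Builds the full word-similarity matrix between the two token sequences
#' and reduces it greedily (see [greedy_max_reduce()]). This is the list of
#' per-word similarities from which an attribute similarity is computed.
#'
#' @param a,b Character vectors of tokens (see [tokenize()]).
#' @return A non-increasing numeric vector of length `min(length(a),
#'   length(b))`; empty if either input is empty.
#' @export
greedy_similarity_list <- function(a, b) {
  greedy_max_reduce(word_similarity_matrix(a, b))
}

#' Similarity of one attribute between two CDEs
#'
#' Tokenizes both phrases, computes the greedy word-similarity list, and
#' returns the fraction of list entries at or above the word-similarity
#' threshold. If either phrase tokenizes to nothing the similarity is 0:
#' absent text carries no evidence of a match.
#'
#' @param a,b Character strings (attribute phrases).
#' @param threshold Word-similarity threshold in (0, 1\]; two words match
#'   when their similarity is greater than or equal to it.
#' @return A number in \[0, 1\].
#' @examples
#' attribute_similarity("What was the classification of the acute myelogenous leukemia?",
#'                      "What was the classification of the chronic myelogenous leukemia?",
#'                      threshold = 0.9) # 8/9
#' @export
attribute_similarity <- function(a, b, threshold = 0.8) {
  check_threshold(threshold)
  attr_sim_tokens(tokenize(a), tokenize(b), threshold)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_cde("word similarity threshold must lie in (0, 1], got %s",
             format(threshold))
}

attr_sim_tokens <- function(ta, tb, threshold) {
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  vals <- greedy_max_reduce(word_similarity_matrix(ta, tb))
  sum(vals >= threshold) / length(vals)
}

#' Six-attribute similarity vector between two CDE records
#'
#' Computes [attribute_similarity()] for each of the six attributes, in the
#' fixed order long name, object class, property, value domain long name,
#' representation term, question text.
#'
#' @param a,b CDE records: named lists or one-row data frames carrying the
#'   six attribute columns.
#' @param threshold Word-similarity threshold.
#' @return A named numeric vector of length 6, each entry in \[0, 1\].
#' @export
attribute_vector <- function(a, b, threshold = 0.8) {
  attrs <- cde_attributes()
  vapply(attrs, function(at) {
    attribute_similarity(as.character(a[[at]]), as.character(b[[at]]), threshold)
  }, numeric(1))
}

#' Attribute weights on the probability simplex
#'
#' Constructs and validates the vector of six attribute weights: all
#' non-negative and summing to one (tolerance 1e-9). The network is
#' initialized with uniform weights 1/6.
#'
#' @param w Numeric vector of length 6.
#' @return A named numeric vector of class `similarity_weights`.
#' @examples
#' uniform_weights()
#' @export
similarity_weights <- function(w = rep(1 / 6, 6)) {
  w <- as.numeric(w)
  if (length(w) != 6L) stop_cde("expected 6 weights, got %d", length(w))
  if (any(w < 0)) stop_cde("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop_cde("weights must sum to 1 (got %.12f)", sum(w))
  names(w) <- cde_attributes()
  class(w) <- "similarity_weights"
  w
}

#' @rdname similarity_weights
#' @export
uniform_weights <- function() similarity_weights()

#' Weighted overall similarity between two CDEs
#'
#' The single-layer network's output: the dot product of the six attribute
#' similarities with the six weights, `s = sum(w_i * s_i)`.
#'
#' @param v Attribute similarity vector (length 6, entries in \[0, 1\]).
#' @param w Weights from [similarity_weights()].
#' @return A number in \[0, 1\].
#' @export
overall_similarity <- function(v, w) {
  w <- similarity_weights(w)
  v <- as.numeric(v)
  if (length(v) != 6L) stop_cde("expected a length-6 attribute vector")
  sum(v * w)
}

# ---- cached pairwise machinery ------------------------------------------
#
# Attribute similarities do not depend on the weights, so all record-pair
# similarity vectors are computed once (with text-level deduplication) and
# training / scoring reduce to dot products.

# matrix of attribute similarities between two text vectors, deduplicated
# over unique texts; symmetric fast path when both vectors are identical
attr_sim_matrix_cached <- function(texts_a, texts_b, threshold) {
  ua <- unique(texts_a)
  symmetric <- identical(texts_a, texts_b)
  ub <- if (symmetric) ua else unique(texts_b)
  toks_a <- lapply(ua, tokenize)
  toks_b <- if (symmetric) toks_a else lapply(ub, tokenize)
  m <- matrix(0, length(ua), length(ub))
  for (i in seq_along(ua)) {
    j0 <- if (symmetric) i else 1L
    for (j in j0:length(ub)) {
      s <- if (ua[i] == ub[j] && length(toks_a[[i]]) > 0L) 1
           else attr_sim_tokens(toks_a[[i]], toks_b[[j]], threshold)
      m[i, j] <- s
      if (symmetric) m[j, i] <- s
    }
  }
  m[match(texts_a, ua), match(texts_b, ub), drop = FALSE]
}

# list of six |a| x |b| matrices, one per attribute, for two record sets
cross_attribute_arrays <- function(records_a, records_b, threshold) {
  attrs <- cde_attributes()
  out <- lapply(attrs, function(at) {
    attr_sim_matrix_cached(as.character(records_a[[at]]),
                           as.character(records_b[[at]]), threshold)
  })
  names(out) <- attrs
  out
}

# collapse the six matrices into one overall-similarity matrix under w
weighted_similarity_matrix <- function(arrays, w) {
  s <- arrays[[1L]] * w[[1L]]
  for (i in 2:6) s <- s + arrays[[i]] * w[[i]]
  s
}
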