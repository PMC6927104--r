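# Independent oracles and fixture builders used across the suite.

# brute-force recursive Levenshtein distance (memoized), independent of the
# package's adist-based implementation
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    val <- min(rec(i - 1L, j) + 1L,
               rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- val
    val
  }
  rec(nchar(a), nchar(b))
}

# brute-force greedy reduction: literally re-scan the whole remaining matrix
# for its maximum at every step, deleting the row and column of the pick;
# ties resolved to the smallest row index, then the smallest column index
oracle_greedy <- function(m) {
  out <- numeric(0)
  while (nrow(m) > 0L && ncol(m) > 0L) {
    best <- max(m)
    hits <- which(m == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    out <- c(out, m[i, j])
    m <- m[-i, -j, drop = FALSE]
  }
  out
}

# random pronounceable-ish words for property tests
random_words <- function(n, min_len = 1L, max_len = 6L) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters[1:10], sample(min_len:max_len, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# one-row CDE record
make_record <- function(id, long_name = "", object_class = "", property = "",
                        value_domain_long_name = "", representation_term = "",
                        question_text = "", mapped_class = NA_character_,
                        dec_concepts = character(0)) {
  df <- data.frame(public_id = id, long_name = long_name,
                   object_class = object_class, property = property,
                   value_domain_long_name = value_domain_long_name,
                   representation_term = representation_term,
                   question_text = question_text,
                   mapped_class = mapped_class, stringsAsFactors = FALSE)
  df$dec_concepts <- list(dec_concepts)
  df
}

# corpus in which each record's whole identity lives in its long_name
# (all other attributes empty), so similarities are hand-computable
make_longname_corpus <- function(long_names, classes,
                                 dec_concepts = NULL) {
  rows <- lapply(seq_along(long_names), function(i) {
    make_record(sprintf("ID%03d", i), long_name = long_names[i],
                mapped_class = classes[i],
                dec_concepts = if (is.null(dec_concepts)) character(0)
                               else dec_concepts[[i]])
  })
  cde_corpus(do.call(rbind, rows))
}

# the worked question-text pair used throughout
acute_question <- "What was the classification of the acute myelogenous leukemia?"
chronic_question <- "What was the classification of the chronic myelogenous leukemia?"

# small fully separable class-structured corpus for end-to-end tests
tiny_separable_corpus <- function(n_classes = 3L, members = 4L, seed = 11L) {
  generate_corpus(synthetic_config(n_classes = n_classes,
                                   members_per_class = members,
                                   seed = seed))
}
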