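#' Configuration for the synthetic corpus generator
#'
#' Parameters controlling a generated class-structured CDE corpus. The
#' defaults emulate a corpus at the scale of the real training material
#' (19 BRIDG classes) with fully separable class vocabularies and no typo
#' noise; `overlap_fraction` and `typo_rate` are the difficulty dials.
#'
#' @param n_classes Number of classes.
#' @param members_per_class Members per class: a scalar or a vector of
#'   length `n_classes`; every class needs at least 2 members.
#' @param vocab_size_per_class Content words per class vocabulary (at
#'   least 4: two object-class words plus a property/representation pool).
#' @param overlap_fraction Fraction of each class vocabulary drawn from a
#'   pool shared by all classes, in \[0, 1\].
#' @param typo_rate Probability that each content word of a record
#'   receives one random single-character edit, in \[0, 1\].
#' @param informative_attribute Optional index 1-6: only this attribute is
#'   built from class-specific words, all others draw from a shared
#'   background pool (parameter-recovery scenarios). `NULL` means all
#'   attributes carry class structure.
#' @param seed Integer seed; identical configurations generate identical
#'   corpora.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 19L, members_per_class = 12L,
                             vocab_size_per_class = 8L,
                             overlap_fraction = 0, typo_rate = 0,
                             informative_attribute = NULL, seed = 1L) {
  if (!is.numeric(n_classes) || n_classes < 1) stop_cde("n_classes must be >= 1")
  members <- as.integer(members_per_class)
  if (length(members) == 1L) members <- rep(members, n_classes)
  if (length(members) != n_classes)
    stop_cde("members_per_class must be scalar or length n_classes")
  if (any(members < 2L))
    stop_cde("members_per_class must be >= 2 (classes must support within-class averages)")
  if (vocab_size_per_class < 4) stop_cde("vocab_size_per_class must be >= 4")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_cde("overlap_fraction must lie in [0, 1]")
  if (typo_rate < 0 || typo_rate > 1) stop_cde("typo_rate must lie in [0, 1]")
  if (!is.null(informative_attribute)) {
    if (!informative_attribute %in% 1:6)
      stop_cde("informative_attribute must be an index 1-6")
    informative_attribute <- as.integer(informative_attribute)
  }
  structure(list(n_classes = as.integer(n_classes),
                 members_per_class = members,
                 vocab_size_per_class = as.integer(vocab_size_per_class),
                 overlap_fraction = overlap_fraction,
                 typo_rate = typo_rate,
                 informative_attribute = informative_attribute,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# pronounceable CV-syllable words, rejection-sampled so every pair of
# lexicon words has word similarity < 0.7: cross-class edit-distance
# matches are then designed, never accidental
make_lexicon <- function(n_words, max_sim = 0.7) {
  consonants <- strsplit("bcdfghjklmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  words <- character(0)
  attempts <- 0L
  while (length(words) < n_words) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_words)
      stop_cde("lexicon rejection sampling failed; lower the vocabulary demand")
    n_syl <- sample(2:5, 1L)
    w <- paste(vapply(seq_len(n_syl), function(i) {
      paste0(sample(consonants, 1L), sample(vowels, 1L))
    }, character(1)), collapse = "")
    if (length(words) > 0L) {
      d <- utils::adist(w, words)[1L, ]
      l <- pmax(nchar(w), nchar(words))
      if (any(1 - d / l >= max_sim)) next
    }
    words <- c(words, w)
  }
  words
}

#' Apply random single-character edits to a word
#'
#' Perturbs a word with `n_edits` random edits (insertion, deletion or
#' substitution of a lowercase letter), guaranteeing the result is
#' non-empty and at edit distance at most `n_edits` from the input. Uses
#' R's global random number stream.
#'
#' @param word Non-empty character string.
#' @param n_edits Number of edits (0 returns the word unchanged).
#' @return The perturbed word.
#' @export
perturb_word <- function(word, n_edits = 1L) {
  if (!nzchar(word)) stop_cde("cannot perturb an empty word")
  if (n_edits < 0) stop_cde("n_edits must be >= 0")
  letters_pool <- letters
  for (e in seq_len(n_edits)) {
    chars <- strsplit(word, "")[[1]]
    nc <- length(chars)
    op <- sample(if (nc > 1L) c("ins", "del", "sub") else c("ins", "sub"), 1L)
    if (op == "ins") {
      pos <- sample.int(nc + 1L, 1L)
      chars <- append(chars, sample(letters_pool, 1L), after = pos - 1L)
    } else if (op == "del") {
      chars <- chars[-sample.int(nc, 1L)]
    } else {
      pos <- sample.int(nc, 1L)
      chars[pos] <- sample(setdiff(letters_pool, chars[pos]), 1L)
    }
    word <- paste(chars, collapse = "")
  }
  word
}

#' Generate a class-structured synthetic CDE corpus
#'
#' Builds a corpus that emulates class-grouped caDSR CDEs. Each class has
#' a fixed two-word object-class phrase (CDEs mapped to one BRIDG class
#' typically share their object class) and a class pool of
#' property/representation words. Per record: the property and
#' representation term are drawn from the class pool, the long name is the
#' concatenation of object class, property and representation term, the
#' value domain long name is templated from the representation term
#' (`"<term> value domain"`), and the question text is a sentence template
#' (`"what was the <property> of the <object class>"`). `dec_concepts`
#' carries the record's canonical (pre-typo) content words, giving exact
#' expected values for [dec_concept_overlap()].
#'
#' With `overlap_fraction > 0` that fraction of each class vocabulary is
#' drawn from a pool shared across classes; with `typo_rate > 0` each
#' content word of a record is independently perturbed by one random edit
#' with that probability. With `informative_attribute = i` only attribute
#' `i` is built from class vocabulary and every other attribute draws its
#' content words from a small background pool shared by all classes, so
#' attribute `i` is the only class signal amid confusable noise.
#'
#' @param config A [synthetic_config()].
#' @return A [cde_corpus()]; identical configs yield identical corpora.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    stop_cde("config must be a synthetic_config")
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  k <- config$n_classes
  vs <- config$vocab_size_per_class
  n_shared <- round(config$overlap_fraction * vs)
  shared_pool_size <- max(vs, n_shared)
  info <- config$informative_attribute
  # one lexicon for everything: shared pool, class-specific words, and (for
  # informative-attribute mode) a small, confusable background pool: the
  # non-informative attributes must carry enough cross-class resemblance
  # that the uniform-weight network actually errs and learning engages
  bg_size <- if (is.null(info)) 0L else vs
  lex <- make_lexicon(shared_pool_size + k * vs + bg_size)
  shared_pool <- lex[seq_len(shared_pool_size)]
  bg_pool <- if (bg_size > 0L) lex[shared_pool_size + seq_len(bg_size)] else character(0)
  fresh <- lex[(shared_pool_size + bg_size + 1L):length(lex)]
  class_vocab <- vector("list", k)
  for (c_i in seq_len(k)) {
    own <- fresh[((c_i - 1L) * vs + 1L):(c_i * vs)]
    vocab <- own
    if (n_shared > 0L) {
      # the shared words replace random positions of the class vocabulary
      pos <- sample.int(vs, n_shared)
      vocab[pos] <- sample(shared_pool, n_shared,
                           replace = n_shared > length(shared_pool))
    }
    class_vocab[[c_i]] <- vocab
  }
  typo <- function(w) {
    if (config$typo_rate > 0 && stats::runif(1) < config$typo_rate)
      perturb_word(w, 1L) else w
  }
  rows <- list()
  rid <- 0L
  for (c_i in seq_len(k)) {
    vocab <- class_vocab[[c_i]]
    obj_words <- vocab[1:2]          # fixed per class
    pool <- vocab[3:length(vocab)]   # property / representation words
    for (m in seq_len(config$members_per_class[c_i])) {
      rid <- rid + 1L
      prop <- sample(pool, 1L)
      rep_term <- sample(pool, 1L)
      if (is.null(info)) {
        content <- list(obj = obj_words, prop = prop, rep = rep_term)
        fields <- build_fields(obj_words, prop, rep_term, typo)
      } else {
        # background draws carry no class signal
        bg_obj <- sample(bg_pool, 2L)
        bg_prop <- sample(bg_pool, 1L)
        bg_rep <- sample(bg_pool, 1L)
        noise <- build_fields(bg_obj, bg_prop, bg_rep, typo)
        signal <- build_fields(obj_words, prop, rep_term, typo)
        fields <- noise
        fields[[info]] <- signal[[info]]
        content <- list(obj = obj_words, prop = prop, rep = rep_term)
      }
      rows[[rid]] <- list(
        public_id = sprintf("CDE%05d", rid),
        long_name = fields[[1L]],
        object_class = fields[[2L]],
        property = fields[[3L]],
        value_domain_long_name = fields[[4L]],
        representation_term = fields[[5L]],
        question_text = fields[[6L]],
        dec_concepts = unique(c(content$obj, content$prop, content$rep)),
        mapped_class = sprintf("SynClass%02d", c_i))
    }
  }
  df <- data.frame(
    public_id = vapply(rows, `[[`, character(1), "public_id"),
    long_name = vapply(rows, `[[`, character(1), "long_name"),
    object_class = vapply(rows, `[[`, character(1), "object_class"),
    property = vapply(rows, `[[`, character(1), "property"),
    value_domain_long_name = vapply(rows, `[[`, character(1),
                                    "value_domain_long_name"),
    representation_term = vapply(rows, `[[`, character(1),
                                 "representation_term"),
    question_text = vapply(rows, `[[`, character(1), "question_text"),
    mapped_class = vapply(rows, `[[`, character(1), "mapped_class"),
    stringsAsFactors = FALSE)
  df$dec_concepts <- lapply(rows, `[[`, "dec_concepts")
  cde_corpus(df)
}

# the six attribute texts, in fixed order, from the content words; each
# content word is perturbed at most once per call, so derived fields stay
# internally consistent (long name really is the concatenation)
build_fields <- function(obj_words, prop, rep_term, typo) {
  t_obj <- vapply(obj_words, typo, character(1), USE.NAMES = FALSE)
  t_prop <- typo(prop)
  t_rep <- typo(rep_term)
  object_class <- paste(t_obj, collapse = " ")
  list(long_name = paste(object_class, t_prop, t_rep),
       object_class = object_class,
       property = t_prop,
       value_domain_long_name = paste(t_rep, "value domain"),
       representation_term = t_rep,
       question_text = sprintf("what was the %s of the %s", t_prop,
                               object_class))
}
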