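#' Similarity between a query CDE and one class
#'
#' Mean overall similarity between the query and the stored members of the
#' class, mirroring the within-class average used in training; if the
#' query itself is among the members it is excluded. A `score_mode` of
#' `"max"` (maximum similarity over members) is available for sensitivity
#' analysis.
#'
#' @param query A CDE record.
#' @param members Data frame of the class's stored records.
#' @param w [similarity_weights()].
#' @param threshold Word-similarity threshold.
#' @param score_mode `"mean"` (default) or `"max"`.
#' @return A number in \[0, 1\].
#' @export
class_similarity <- function(query, members, w, threshold = 0.8,
                             score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  members <- members[members$public_id != as.character(query$public_id), ,
                     drop = FALSE]
  if (nrow(members) == 0L)
    stop_cde("degenerate class: no members to compare the query against")
  sims <- vapply(seq_len(nrow(members)), function(i) {
    overall_similarity(attribute_vector(query, members[i, ], threshold), w)
  }, numeric(1))
  if (score_mode == "mean") mean(sims) else max(sims)
}

# score every class of a model for a block of queries at once, using the
# cached cross-attribute machinery; returns queries x classes score matrix
score_classes <- function(queries, model, score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  members_all <- do.call(rbind, model$class_members)
  rownames(members_all) <- NULL
  cls_of <- rep(names(model$class_members),
                vapply(model$class_members, nrow, integer(1)))
  arrays <- cross_attribute_arrays(queries, members_all, model$threshold)
  s <- weighted_similarity_matrix(arrays, as.numeric(model$weights))
  # a query present among the stored members never scores against itself
  self <- outer(as.character(queries$public_id),
                as.character(members_all$public_id), "==")
  s[self] <- NA_real_
  classes <- names(model$class_members)
  scores <- vapply(classes, function(cl) {
    block <- s[, cls_of == cl, drop = FALSE]
    if (score_mode == "mean") rowMeans(block, na.rm = TRUE)
    else apply(block, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  }, numeric(nrow(queries)))
  scores <- matrix(scores, nrow = nrow(queries),
                   dimnames = list(queries$public_id, classes))
  scores[is.na(scores) | is.infinite(scores)] <- 0  # class emptied by self-exclusion
  scores
}

#' Recommend candidate BRIDG classes for a query CDE
#'
#' Scores every class of the model against the query ([class_similarity()]
#' with the model's learned weights and threshold) and returns the top `k`
#' classes by descending score, ties broken by class name.
#'
#' @param query A CDE record (one-row data frame or named list with the six
#'   attribute fields and a `public_id`).
#' @param model A `cde_model` from [train()] or [load_model()].
#' @param k Number of candidates to return (default 10).
#' @param score_mode `"mean"` or `"max"` member aggregation.
#' @return A `cde_recommendation`: list with `query_id` and `candidates`,
#'   a data frame of `class` and `score` in non-increasing score order.
#' @export
recommend <- function(query, model, k = 10L, score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  if (!is.numeric(k) || k < 1) stop_cde("k must be a positive integer")
  if (length(model$class_members) < 1L) stop_cde("model has no classes")
  qdf <- as.data.frame(as.list(unlist(query[c("public_id", cde_attributes())])),
                       stringsAsFactors = FALSE)
  scores <- score_classes(qdf, model, score_mode)[1L, ]
  ord <- order(-scores, names(scores))
  top <- utils::head(ord, k)
  structure(list(query_id = as.character(qdf$public_id),
                 candidates = data.frame(class = names(scores)[top],
                                         score = unname(scores[top]),
                                         stringsAsFactors = FALSE)),
            class = "cde_recommendation")
}

#' @export
print.cde_recommendation <- function(x, ...) {
  cat(sprintf("<cde_recommendation> query %s\n", x$query_id))
  print(transform(x$candidates, score = round(score, 4)))
  invisible(x)
}

#' Top-n match rate of a model on labeled queries
#'
#' For each query, ranks all classes of the model and records the rank of
#' the query's true class; the match rate is the percentage of queries
#' whose true class appears among the top `n` candidates. A query whose
#' true class is not in the model at all counts as unmatched (rank `NA`).
#'
#' @param queries A [cde_corpus()] in which every record carries a
#'   `mapped_class`.
#' @param model A `cde_model`.
#' @param n Positive integer: list length against which a match is judged.
#' @param score_mode `"mean"` or `"max"` member aggregation.
#' @return A `cde_evaluation`: list with `n`, `match_rate` (percent), and
#'   `per_query`, a data frame of `query_id`, `true_class`, `rank`,
#'   `matched`.
#' @export
match_rate <- function(queries, model, n = 10L,
                       score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  if (!is.numeric(n) || n < 1) stop_cde("n must be a positive integer")
  validate_corpus(queries)
  if (any(is.na(queries$records$mapped_class)))
    stop_cde("every query must carry a mapped_class")
  ranks <- true_class_ranks(queries, model, score_mode)
  matched <- !is.na(ranks$rank) & ranks$rank <= n
  structure(list(n = as.integer(n),
                 match_rate = 100 * mean(matched),
                 per_query = cbind(ranks, matched = matched)),
            class = "cde_evaluation")
}

# data frame of query_id, true_class, rank (NA when the class is absent)
true_class_ranks <- function(queries, model, score_mode = "mean") {
  scores <- score_classes(queries$records, model, score_mode)
  classes <- colnames(scores)
  rank <- vapply(seq_len(nrow(scores)), function(i) {
    truth <- queries$records$mapped_class[i]
    if (!truth %in% classes) return(NA_integer_)
    ord <- order(-scores[i, ], classes)
    which(classes[ord] == truth)
  }, integer(1))
  data.frame(query_id = queries$records$public_id,
             true_class = queries$records$mapped_class,
             rank = rank, stringsAsFactors = FALSE)
}

#' @export
print.cde_evaluation <- function(x, ...) {
  cat(sprintf("<cde_evaluation> top-%d match rate: %.2f%% (%d queries)\n",
              x$n, x$match_rate, nrow(x$per_query)))
  invisible(x)
}

#' Restrict queries to classes with sufficient training data
#'
#' Keeps only the queries whose true class is stored in the model with at
#' least `min_members` members, changing the match-rate denominator to the
#' qualifying queries only.
#'
#' @param queries A labeled [cde_corpus()].
#' @param model A `cde_model`.
#' @param min_members Minimum stored members for a class to qualify.
#' @return A filtered [cde_corpus()].
#' @export
restrict_to_trained <- function(queries, model, min_members = 1L) {
  validate_corpus(queries)
  sizes <- vapply(model$class_members, nrow, integer(1))
  ok <- names(sizes)[sizes >= min_members]
  keep <- which(queries$records$mapped_class %in% ok)
  cde_corpus(queries$records[keep, , drop = FALSE])
}

#' Sweep the evaluation parameter grid
#'
#' For every combination of training ratio, word-similarity threshold and
#' per-class training cap: filter the corpus by minimum class size, split
#' it, cap the training members per class, train, and evaluate the top-n
#' match rate on the verification part for each requested `n`. The whole
#' sweep is deterministic under a fixed seed.
#'
#' @param corpus A labeled [cde_corpus()].
#' @param ratios Training fractions to test (paper grid: 0.75 and 0.9).
#' @param thresholds Word-similarity thresholds to test (paper grid:
#'   0.6 to 1.0).
#' @param per_class_caps Caps on training CDEs per class (paper grid:
#'   4 to 10); `Inf` disables the cap.
#' @param n_values Candidate-list lengths to evaluate (default 1 to 10).
#' @param config Base [training_config()]; its threshold is overridden by
#'   `thresholds` at each grid point.
#' @param seed Integer seed for splitting and capping.
#' @param score_mode `"mean"` or `"max"` member aggregation.
#' @return A data frame with columns `ratio`, `threshold`, `per_class_cap`,
#'   `n`, `match_rate_percent`, `n_queries`.
#' @export
sweep_parameters <- function(corpus, ratios = c(0.75, 0.9),
                             thresholds = c(0.6, 0.7, 0.8, 0.9, 1.0),
                             per_class_caps = Inf, n_values = 1:10,
                             config = training_config(), seed = config$seed,
                             score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  if (length(ratios) == 0L || length(thresholds) == 0L ||
      length(per_class_caps) == 0L || length(n_values) == 0L)
    stop_cde("sweep grid must be non-empty")
  filtered <- filter_by_class_size(corpus, config$min_class_size)
  grid <- expand.grid(ratio = ratios, threshold = thresholds,
                      per_class_cap = per_class_caps,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ratio <- grid$ratio[g]
    thr <- grid$threshold[g]
    cap <- grid$per_class_cap[g]
    parts <- split_train_verify(filtered, ratio, seed = seed)
    train_set <- cap_class_members(parts$train, cap, seed = seed)
    cfg <- config
    cfg$word_similarity_threshold <- thr
    model <- train(train_set, cfg)
    ranks <- true_class_ranks(parts$verify, model, score_mode)
    data.frame(ratio = ratio, threshold = thr, per_class_cap = cap,
               n = as.integer(n_values),
               match_rate_percent = vapply(n_values, function(nv) {
                 100 * mean(!is.na(ranks$rank) & ranks$rank <= nv)
               }, numeric(1)),
               n_queries = nrow(ranks))
  })
  do.call(rbind, rows)
}

#' DEC concept overlap between a testing and a training corpus
#'
#' The percentage of distinct NCI Thesaurus concept identifiers occurring
#' in the DECs of the testing set that also occur in the DECs of the
#' training set — the semantic-similarity statistic used to grade how far
#' a testing set strays from the training vocabulary.
#'
#' @param test,train [cde_corpus()] objects whose records carry
#'   `dec_concepts`.
#' @return A percentage in \[0, 100\].
#' @export
dec_concept_overlap <- function(test, train) {
  test_concepts <- unique(unlist(test$records$dec_concepts))
  train_concepts <- unique(unlist(train$records$dec_concepts))
  if (length(test_concepts) == 0L)
    stop_cde("testing corpus carries no DEC concepts; overlap is undefined")
  100 * length(intersect(test_concepts, train_concepts)) / length(test_concepts)
}
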