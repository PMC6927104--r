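#' Training configuration
#'
#' Hyperparameters of the weight-learning loop. The learning rate defaults
#' to 0.05 and the iteration cap to 50, the values at which the training
#' error was observed to fluctuate by no more than about 1%; the
#' word-similarity threshold is fixed for the life of a model.
#'
#' @param eta Positive learning rate.
#' @param max_iterations Positive integer cap on training passes.
#' @param word_similarity_threshold Threshold in (0, 1\] for word matches.
#' @param min_class_size Minimum class size used by upstream filtering.
#' @param anchor_mode `"all"` (every class member serves as anchor once per
#'   pass) or `"first"` (only the first stored member of each class).
#' @param seed Integer seed (used by operations that subsample, e.g. the
#'   per-class training cap).
#' @return A list of class `training_config`.
#' @export
training_config <- function(eta = 0.05, max_iterations = 50L,
                            word_similarity_threshold = 0.8,
                            min_class_size = 10L,
                            anchor_mode = c("all", "first"), seed = 1L) {
  anchor_mode <- match.arg(anchor_mode)
  if (!is.numeric(eta) || eta <= 0) stop_cde("eta must be positive")
  if (!is.numeric(max_iterations) || max_iterations < 1)
    stop_cde("max_iterations must be >= 1")
  check_threshold(word_similarity_threshold)
  if (!is.numeric(min_class_size) || min_class_size < 1)
    stop_cde("min_class_size must be >= 1")
  structure(list(eta = eta,
                 max_iterations = as.integer(max_iterations),
                 word_similarity_threshold = word_similarity_threshold,
                 min_class_size = as.integer(min_class_size),
                 anchor_mode = anchor_mode,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Within-class average similarity of an anchor CDE
#'
#' Mean overall similarity between the anchor and the *other* members of
#' its class; the anchor never contributes to its own average.
#'
#' @param anchor A CDE record (one-row data frame or named list).
#' @param members Data frame of the class's records, including the anchor.
#' @param w [similarity_weights()].
#' @param threshold Word-similarity threshold.
#' @return A number in \[0, 1\].
#' @export
within_class_avg <- function(anchor, members, w, threshold = 0.8) {
  others <- members[members$public_id != as.character(anchor$public_id), ,
                    drop = FALSE]
  if (nrow(others) == 0L)
    stop_cde("degenerate class: an anchor needs at least one other member")
  sims <- vapply(seq_len(nrow(others)), function(i) {
    overall_similarity(attribute_vector(anchor, others[i, ], threshold), w)
  }, numeric(1))
  mean(sims)
}

#' Between-class average similarity of an anchor CDE
#'
#' Mean overall similarity between the anchor and every record mapped to a
#' class other than the anchor's own.
#'
#' @param anchor A CDE record.
#' @param corpus A [cde_corpus()].
#' @param own_class Class name of the anchor.
#' @param w [similarity_weights()].
#' @param threshold Word-similarity threshold.
#' @return A number in \[0, 1\].
#' @export
other_class_avg <- function(anchor, corpus, own_class, w, threshold = 0.8) {
  recs <- corpus$records
  outside <- recs[!is.na(recs$mapped_class) & recs$mapped_class != own_class, ,
                  drop = FALSE]
  if (nrow(outside) == 0L)
    stop_cde("degenerate corpus: no records outside class '%s'", own_class)
  sims <- vapply(seq_len(nrow(outside)), function(i) {
    overall_similarity(attribute_vector(anchor, outside[i, ], threshold), w)
  }, numeric(1))
  mean(sims)
}

#' Training error for one anchor
#'
#' Squared-error loss `E = (1/2) (s_max - s_avg)^2` where `s_max` is the
#' larger of the within-class average `s_avg` and the between-class average
#' `s_other`: the target output is the larger value, the network's output
#' is `s_avg`, and the error is zero exactly when the anchor is already
#' more similar to its own class than to the rest of the corpus.
#'
#' @param s_avg Within-class average similarity, in \[0, 1\].
#' @param s_other Between-class average similarity, in \[0, 1\].
#' @return A non-negative number.
#' @export
training_error <- function(s_avg, s_other) {
  0.5 * (max(s_avg, s_other) - s_avg)^2
}

#' Delta-rule weight update
#'
#' When the anchor's within-class average falls below its between-class
#' average, each weight is incremented by `eta * (s_max - s_avg) *
#' mean_attr_i`, where `mean_attr` is the mean attribute-similarity vector
#' over the anchor's within-class pairs, and the weights are renormalized
#' to the probability simplex. When the error is zero the weights are
#' returned unchanged.
#'
#' @param w [similarity_weights()].
#' @param s_avg,s_other Within- and between-class average similarities.
#' @param mean_attr Mean attribute vector over the within-class pairs.
#' @param eta Positive learning rate.
#' @return Updated [similarity_weights()].
#' @export
update_weights <- function(w, s_avg, s_other, mean_attr, eta = 0.05) {
  w <- similarity_weights(w)
  if (s_avg >= s_other) return(w)
  delta <- eta * (s_other - s_avg) * as.numeric(mean_attr)
  raw <- as.numeric(w) + delta
  similarity_weights(raw / sum(raw))
}

#' Train the attribute weights on a labeled corpus
#'
#' Learns the six attribute weights by gradient descent. Weights start
#' uniform at 1/6. Classes are traversed from smallest to largest (ties
#' broken by class name); for each anchor CDE the within-class average
#' similarity `s_avg` and the between-class average `s_avg_other_cls` are
#' computed under the current weights, and when `s_avg` falls short the
#' weights are nudged towards the attributes that are similar within the
#' class ([update_weights()]). Passes repeat up to `max_iterations`, with
#' early stopping when the total error changes by less than 1% relative
#' between successive passes.
#'
#' All record-pair attribute similarities are precomputed once (they do not
#' depend on the weights), so each pass reduces to dot products.
#'
#' @param corpus A [cde_corpus()] in which every record carries a
#'   `mapped_class`, with at least 2 classes and at least 2 members per
#'   class (apply [filter_by_class_size()] first).
#' @param config A [training_config()].
#' @return A `cde_model`: list with `weights`, `threshold`,
#'   `class_members` (named list of record data frames), `config` and
#'   `training_log` (per-pass total error).
#' @export
train <- function(corpus, config = training_config()) {
  validate_corpus(corpus)
  if (!inherits(config, "training_config")) stop_cde("config must be a training_config")
  recs <- corpus$records
  if (any(is.na(recs$mapped_class)))
    stop_cde("training corpus contains %d unmapped record(s)",
             sum(is.na(recs$mapped_class)))
  sizes <- lengths(corpus$class_index)
  if (length(sizes) < 2L) stop_cde("training needs at least 2 classes")
  if (any(sizes < 2L))
    stop_cde("every class needs >= 2 members for within-class averages; too small: %s",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
  threshold <- config$word_similarity_threshold
  n <- nrow(recs)
  arrays <- cross_attribute_arrays(recs, recs, threshold)
  # smallest classes first; lexicographic tie-break for determinism
  class_order <- names(sizes)[order(sizes, names(sizes))]
  class_rows <- lapply(class_order,
                       function(cl) which(recs$mapped_class == cl))
  names(class_rows) <- class_order
  w <- as.numeric(uniform_weights())
  err_trace <- numeric(0)
  for (iter in seq_len(config$max_iterations)) {
    total_err <- 0
    for (cl in class_order) {
      rows <- class_rows[[cl]]
      anchors <- if (config$anchor_mode == "first") rows[1L] else rows
      outside <- setdiff(seq_len(n), rows)
      for (a in anchors) {
        within <- setdiff(rows, a)
        va <- vapply(arrays, function(m) m[a, ], numeric(n))  # n x 6
        s <- as.vector(va %*% w)
        s_avg <- mean(s[within])
        s_other <- mean(s[outside])
        total_err <- total_err + training_error(s_avg, s_other)
        if (s_avg < s_other) {
          mean_attr <- colMeans(va[within, , drop = FALSE])
          raw <- w + config$eta * (s_other - s_avg) * mean_attr
          w <- raw / sum(raw)
        }
      }
    }
    err_trace <- c(err_trace, total_err)
    if (iter >= 2L) {
      prev <- err_trace[iter - 1L]
      if (prev == 0 && total_err == 0) break
      if (prev > 0 && abs(total_err - prev) / prev < 0.01) break
    }
  }
  members <- lapply(corpus$class_index, function(ids) {
    recs[match(ids, recs$public_id), , drop = FALSE]
  })
  structure(list(weights = similarity_weights(w),
                 threshold = threshold,
                 class_members = members,
                 config = config,
                 training_log = err_trace),
            class = "cde_model")
}

#' @export
print.cde_model <- function(x, ...) {
  cat(sprintf("<cde_model> %d classes, threshold %.2f, %d training pass(es)\n",
              length(x$class_members), x$threshold, length(x$training_log)))
  cat("weights:\n")
  print(round(unclass(x$weights), 6))
  invisible(x)
}

#' Persist a trained model as JSON
#'
#' The JSON document carries the six named weights, the word-similarity
#' threshold, an echo of the training configuration, the error trace, and
#' the stored class members (public ids plus the six attribute texts, so
#' the model is self-contained for recommendation).
#'
#' @param model A `cde_model` from [train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "cde_model")) stop_cde("not a cde_model")
  classes <- lapply(model$class_members, function(df) {
    list(public_ids = as.list(df$public_id),
         records = lapply(seq_len(nrow(df)), function(i) {
           as.list(df[i, c("public_id", cde_attributes())])
         }))
  })
  doc <- list(weights = as.list(unclass(model$weights)),
              threshold = model$threshold,
              config = unclass(model$config),
              training_log = model$training_log,
              classes = classes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trained model from JSON
#'
#' Re-validates the simplex invariant on the weights; a model whose weights
#' are negative or do not sum to one is refused.
#'
#' @param path Path to a file written by [save_model()].
#' @return A `cde_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_cde("model file does not exist: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  w <- similarity_weights(unlist(doc$weights[cde_attributes()]))
  cfg <- doc$config
  config <- training_config(eta = cfg$eta,
                            max_iterations = cfg$max_iterations,
                            word_similarity_threshold = cfg$word_similarity_threshold,
                            min_class_size = cfg$min_class_size,
                            anchor_mode = cfg$anchor_mode,
                            seed = cfg$seed)
  members <- lapply(doc$classes, function(cl) {
    df <- data.frame(lapply(c("public_id", cde_attributes()), function(col) {
      vapply(cl$records, function(r) as.character(r[[col]]), character(1))
    }), stringsAsFactors = FALSE)
    names(df) <- c("public_id", cde_attributes())
    df
  })
  structure(list(weights = w,
                 threshold = doc$threshold,
                 class_members = members,
                 config = config,
                 training_log = as.numeric(unlist(doc$training_log))),
            class = "cde_model")
}

#' Cap the number of stored training CDEs per class
#'
#' Subsamples each class of a corpus down to at most `cap` members, using
#' the given seed; used to realize the "training CDEs per class" parameter
#' of the evaluation grid.
#'
#' @param corpus A [cde_corpus()].
#' @param cap Positive integer, or `Inf` for no cap.
#' @param seed Integer seed.
#' @return A [cde_corpus()]; record order is preserved.
#' @export
cap_class_members <- function(corpus, cap, seed = 1L) {
  validate_corpus(corpus)
  if (is.infinite(cap)) return(corpus)
  if (!is.numeric(cap) || cap < 1) stop_cde("cap must be >= 1 or Inf")
  keep <- with_seed(seed, {
    unlist(lapply(corpus$class_index, function(ids) {
      rows <- match(ids, corpus$records$public_id)
      if (length(rows) <= cap) rows else rows[sample.int(length(rows), cap)]
    }), use.names = FALSE)
  })
  keep <- c(keep, which(is.na(corpus$records$mapped_class)))
  corpus_subset(corpus, keep)
}
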