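#' CDE corpora
#'
#' A `cde_corpus` holds an ordered collection of CDE records — one ISO 11179
#' data element per row, described by its six semantic attributes — plus an
#' index from BRIDG class name to the public ids of the records mapped to
#' that class. Records without a `mapped_class` are allowed (they are
#' recommendation queries) and appear in no class group.
#'
#' @param records A data frame with character columns `public_id`,
#'   `long_name`, `object_class`, `property`, `value_domain_long_name`,
#'   `representation_term`, `question_text`, `mapped_class` (NA or ""
#'   meaning unmapped) and a list column `dec_concepts` of character
#'   vectors (optional; defaults to empty sets).
#' @return An object of class `cde_corpus`: a list with elements `records`
#'   (the data frame) and `class_index` (named list of public-id vectors).
#' @export
cde_corpus <- function(records) {
  required <- c("public_id", cde_attributes())
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop_cde("corpus is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  for (col in required) records[[col]] <- trimws(as.character(records[[col]]))
  if (!"mapped_class" %in% names(records)) records$mapped_class <- NA_character_
  records$mapped_class <- trimws(as.character(records$mapped_class))
  records$mapped_class[!nzchar(records$mapped_class) |
                         is.na(records$mapped_class)] <- NA_character_
  if (!"dec_concepts" %in% names(records)) {
    records$dec_concepts <- replicate(nrow(records), character(0),
                                      simplify = FALSE)
  } else if (!is.list(records$dec_concepts)) {
    records$dec_concepts <- lapply(as.character(records$dec_concepts),
                                   parse_concepts)
  }
  dup <- records$public_id[duplicated(records$public_id)]
  if (length(dup) > 0L)
    stop_cde("duplicate public_id in corpus: %s",
             paste(unique(dup), collapse = ", "))
  records <- records[, corpus_columns(), drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, class_index = build_class_index(records)),
            class = "cde_corpus")
}

parse_concepts <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

build_class_index <- function(records) {
  mapped <- !is.na(records$mapped_class)
  if (!any(mapped)) return(structure(list(), names = character(0)))
  idx <- split(records$public_id[mapped], records$mapped_class[mapped])
  idx[order(names(idx))]
}

#' @export
print.cde_corpus <- function(x, ...) {
  n_cls <- length(x$class_index)
  n_unmapped <- sum(is.na(x$records$mapped_class))
  cat(sprintf("<cde_corpus> %d records, %d classes, %d unmapped\n",
              nrow(x$records), n_cls, n_unmapped))
  if (n_cls > 0L) {
    sizes <- lengths(x$class_index)
    cat("class sizes: ", paste(sprintf("%s=%d", names(sizes), sizes),
                               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.cde_corpus <- function(x) nrow(x$records)

# subset a corpus by row index, preserving record order
corpus_subset <- function(corpus, idx) {
  cde_corpus(corpus$records[sort(idx), , drop = FALSE])
}

#' Validate a corpus against its invariants
#'
#' Checks that the class index is exactly derivable from the records and
#' that public ids are unique. Called by readers and model training.
#'
#' @param corpus A `cde_corpus`.
#' @return The corpus, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  if (!inherits(corpus, "cde_corpus")) stop_cde("not a cde_corpus")
  rebuilt <- build_class_index(corpus$records)
  if (!identical(rebuilt, corpus$class_index))
    stop_cde("class_index is not derivable from records")
  invisible(corpus)
}

#' Read a CDE corpus
#'
#' Reads the canonical flat interchange format (CSV or JSON) or, as a
#' best effort, a caDSR CDE Browser XML export. The canonical CSV has a
#' header row with columns `public_id`, `long_name`, `object_class`,
#' `property`, `value_domain_long_name`, `representation_term`,
#' `question_text`, `dec_concepts` (semicolon-joined, may be empty) and
#' `mapped_class` (may be empty). The canonical JSON is an array of objects
#' with the same keys, `dec_concepts` as an array.
#'
#' For XML, element names are matched case-insensitively against a set of
#' caDSR-style names; records from which no public id or no attribute text
#' can be extracted are skipped with a warning giving the count.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"json"`, `"xml"`; by default inferred
#'   from the file extension.
#' @return A [cde_corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "csv", "json", "xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cde("file does not exist: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json", xml = "xml",
                     stop_cde("cannot infer corpus format from '%s'", path))
  }
  switch(format,
         csv = read_corpus_csv(path),
         json = read_corpus_json(path),
         xml = read_corpus_xml(path))
}

corpus_columns <- function() {
  c("public_id", cde_attributes(), "dec_concepts", "mapped_class")
}

read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  missing_cols <- setdiff(corpus_columns(), names(df))
  if (length(missing_cols) > 0L)
    stop_cde("CSV is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  df <- df[, corpus_columns(), drop = FALSE]
  df$dec_concepts <- lapply(df$dec_concepts, parse_concepts)
  cde_corpus(df)
}

read_corpus_json <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cols <- corpus_columns()
  rows <- lapply(objs, function(o) {
    missing_keys <- setdiff(setdiff(cols, "dec_concepts"), names(o))
    if (length(missing_keys) > 0L)
      stop_cde("JSON record is missing key(s): %s",
               paste(missing_keys, collapse = ", "))
    o
  })
  df <- data.frame(lapply(setdiff(cols, "dec_concepts"), function(col) {
    vapply(rows, function(o) {
      v <- o[[col]]
      if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v)
    }, character(1))
  }), stringsAsFactors = FALSE)
  names(df) <- setdiff(cols, "dec_concepts")
  df$dec_concepts <- lapply(rows, function(o) {
    as.character(unlist(o$dec_concepts))
  })
  cde_corpus(df)
}

read_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  lower <- "translate(local-name(), 'ABCDEFGHIJKLMNOPQRSTUVWXYZ', 'abcdefghijklmnopqrstuvwxyz')"
  nodes <- xml2::xml_find_all(doc, sprintf("//*[%s='dataelement']", lower))
  if (length(nodes) == 0L)
    stop_cde("no DataElement records found in %s", path)
  field_names <- list(
    public_id = c("publicid", "public_id", "cdeid", "id"),
    long_name = c("longname", "long_name", "preferredname"),
    object_class = c("objectclass", "object_class", "objectclassname"),
    property = c("property", "propertyname", "property_name"),
    value_domain_long_name = c("valuedomainlongname", "value_domain_long_name",
                               "vdlongname"),
    representation_term = c("representationterm", "representation_term",
                            "repterm"),
    question_text = c("questiontext", "question_text",
                      "preferredquestiontext"),
    mapped_class = c("mappedclass", "mapped_class", "bridgclass"),
    dec_concepts = c("decconcepts", "dec_concepts", "conceptcodes"))
  rows <- lapply(nodes, function(node) {
    vals <- lapply(field_names, function(cands) xml_field(node, cands, lower))
    if (is.na(vals$public_id)) return(NULL)
    attr_vals <- unlist(vals[cde_attributes()])
    if (all(is.na(attr_vals) | !nzchar(attr_vals))) return(NULL)
    vals
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  rows <- Filter(Negate(is.null), rows)
  if (skipped > 0L)
    warning(sprintf("skipped %d unparseable DataElement record(s) in %s",
                    skipped, path), call. = FALSE)
  if (length(rows) == 0L) stop_cde("no parseable DataElement records in %s", path)
  df <- data.frame(lapply(setdiff(corpus_columns(), "dec_concepts"),
                          function(col) {
    vapply(rows, function(r) {
      v <- r[[col]]
      if (is.na(v)) "" else v
    }, character(1))
  }), stringsAsFactors = FALSE)
  names(df) <- setdiff(corpus_columns(), "dec_concepts")
  df$dec_concepts <- lapply(rows, function(r) parse_concepts(r$dec_concepts))
  cde_corpus(df)
}

xml_field <- function(node, candidates, lower) {
  for (cand in candidates) {
    hit <- xml2::xml_find_first(node, sprintf(".//*[%s='%s']", lower, cand))
    if (!inherits(hit, "xml_missing")) return(trimws(xml2::xml_text(hit)))
  }
  NA_character_
}

#' Write a CDE corpus
#'
#' Serializes a corpus to the canonical CSV or JSON schema described in
#' [read_corpus()]; the written file reads back as an equal corpus, and
#' re-serialization is byte-identical.
#'
#' @param corpus A [cde_corpus()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json",
                     stop_cde("cannot infer corpus format from '%s'", path))
  }
  df <- corpus$records
  if (format == "csv") {
    flat <- df
    flat$dec_concepts <- vapply(df$dec_concepts, paste, character(1),
                                collapse = ";")
    flat$mapped_class[is.na(flat$mapped_class)] <- ""
    flat <- flat[, corpus_columns(), drop = FALSE]
    utils::write.csv(flat, path, row.names = FALSE, na = "")
  } else {
    objs <- lapply(seq_len(nrow(df)), function(i) {
      o <- as.list(df[i, setdiff(corpus_columns(), "dec_concepts")])
      o$mapped_class <- if (is.na(o$mapped_class)) "" else o$mapped_class
      o$dec_concepts <- as.list(df$dec_concepts[[i]])
      o[corpus_columns()]
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Drop classes with too few training examples
#'
#' Removes every record mapped to a class with fewer than `min_size`
#' members, and all unmapped records. Classes with too few examples do not
#' provide enough training signal and interfere with weight learning; the
#' default of 10 is the refinement used to reduce 1232 gold-standard CDEs
#' over 57 classes to 1134 CDEs over 19 classes.
#'
#' @param corpus A [cde_corpus()].
#' @param min_size Positive integer, minimum surviving class size.
#' @return A filtered [cde_corpus()] (possibly empty); record order is
#'   preserved.
#' @export
filter_by_class_size <- function(corpus, min_size = 10L) {
  validate_corpus(corpus)
  if (!is.numeric(min_size) || min_size < 1) stop_cde("min_size must be >= 1")
  sizes <- lengths(corpus$class_index)
  keep_classes <- names(sizes)[sizes >= min_size]
  keep <- which(corpus$records$mapped_class %in% keep_classes)
  cde_corpus(corpus$records[keep, , drop = FALSE])
}

#' Split a corpus into training and verification sets
#'
#' Randomly partitions the records into a training part and a verification
#' part. With `stratified = TRUE` (the default) each class contributes
#' approximately `train_fraction` of its members to training, with at least
#' one member on each side, so small classes never vanish from training.
#' Records are selected randomly, not alphabetically, to avoid ordering
#' bias; the same seed always produces the same split.
#'
#' @param corpus A [cde_corpus()].
#' @param train_fraction Number strictly between 0 and 1.
#' @param seed Integer seed controlling the random selection.
#' @param stratified Stratify the split per class (each mapped class then
#'   needs at least 2 members). Unmapped records are split as a single
#'   extra stratum.
#' @return A list with elements `train` and `verify`, both [cde_corpus()]
#'   objects; together they cover the input exactly.
#' @export
split_train_verify <- function(corpus, train_fraction = 0.75, seed = 1L,
                               stratified = TRUE) {
  validate_corpus(corpus)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_cde("train_fraction must lie strictly between 0 and 1")
  n <- nrow(corpus$records)
  if (n < 2L) stop_cde("corpus must have at least 2 records to split")
  train_idx <- with_seed(seed, {
    if (stratified) {
      cls <- corpus$records$mapped_class
      strata <- split(seq_len(n), ifelse(is.na(cls), "", cls))
      one_member <- names(strata)[nzchar(names(strata)) & lengths(strata) < 2L]
      if (length(one_member) > 0L)
        stop_cde("stratified split requires >= 2 members per class; too small: %s",
                 paste(one_member, collapse = ", "))
      unlist(lapply(names(strata), function(s) {
        idx <- strata[[s]]
        m <- length(idx)
        k <- round(train_fraction * m)
        if (nzchar(s)) k <- min(max(k, 1L), m - 1L) else k <- min(max(k, 0L), m)
        if (k == 0L) return(integer(0))
        idx[sample.int(m, k)]
      }), use.names = FALSE)
    } else {
      k <- min(max(round(train_fraction * n), 1L), n - 1L)
      sample.int(n, k)
    }
  })
  list(train = corpus_subset(corpus, train_idx),
       verify = corpus_subset(corpus, setdiff(seq_len(n), train_idx)))
}
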