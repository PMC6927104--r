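test_that("corpus construction builds the class index and trims fields", {
  corpus <- cde_corpus(rbind(
    make_record("P1", long_name = " Alpha Beta ", mapped_class = "PerformedDiagnosis"),
    make_record("P2", long_name = "Gamma", mapped_class = "PerformedDiagnosis"),
    make_record("P3", long_name = "Delta")))
  expect_length(corpus$class_index, 1L)
  expect_identical(corpus$class_index$PerformedDiagnosis, c("P1", "P2"))
  expect_identical(corpus$records$long_name[1], "Alpha Beta")
  expect_true(is.na(corpus$records$mapped_class[3]))
  expect_silent(validate_corpus(corpus))
})

test_that("duplicate public ids and missing columns are rejected by name", {
  expect_error(cde_corpus(rbind(make_record("X"), make_record("X"))),
               "duplicate public_id.*X")
  bad <- make_record("A")
  bad$question_text <- NULL
  expect_error(cde_corpus(bad), "question_text")
})

test_that("class index membership equals the multiset of mapped_class values", {
  corpus <- tiny_separable_corpus(4, 5)
  tab <- table(corpus$records$mapped_class)
  expect_identical(lengths(corpus$class_index)[names(tab)], c(tab))
})

test_that("CSV and JSON round trips are the identity on valid corpora", {
  corpus <- generate_corpus(synthetic_config(n_classes = 4, members_per_class = 5,
                                             typo_rate = 0.2, seed = 3))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_corpus(corpus, path)
    back <- read_corpus(path)
    expect_identical(back$records, corpus$records)
    expect_identical(back$class_index, corpus$class_index)
  }
})

test_that("a CSV with unmapped records and concepts survives the round trip", {
  corpus <- cde_corpus(rbind(
    make_record("Q1", long_name = "Alpha, \"quoted\"", question_text = "what was alpha?",
                mapped_class = "C1", dec_concepts = c("C1234", "C99")),
    make_record("Q2", long_name = "Beta", mapped_class = "C1"),
    make_record("Q3", long_name = "Unmapped query")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_identical(back$records$dec_concepts[[1]], c("C1234", "C99"))
  expect_identical(back$records$dec_concepts[[2]], character(0))
  expect_true(is.na(back$records$mapped_class[3]))
  expect_identical(back$records$long_name[1], "Alpha, \"quoted\"")
})

test_that("re-serialization of a 100-record corpus is byte-identical", {
  corpus <- generate_corpus(synthetic_config(n_classes = 10, members_per_class = 10,
                                             overlap_fraction = 0.3, seed = 9))
  expect_identical(nrow(corpus$records), 100L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, p1)
  write_corpus(read_corpus(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("CSV reader names the missing column in its schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("public_id,long_name", "A,Alpha"), path)
  expect_error(read_corpus(path), "object_class")
})

test_that("empty and single-record corpora serialize sensibly", {
  empty <- cde_corpus(make_record("Z")[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(empty, path)
  expect_length(readLines(path), 1L)  # header only
  one <- cde_corpus(make_record("Z", long_name = "Solo"))
  write_corpus(one, path)
  expect_length(readLines(path), 2L)
})

test_that("the caDSR-style XML reader extracts records case-insensitively", {
  xml <- c(
    '<?xml version="1.0"?>',
    "<DataElementsList>",
    "  <DataElement>",
    "    <PUBLICID>2518</PUBLICID>",
    "    <LONGNAME>Acute Myeloid Leukemia Classification Type</LONGNAME>",
    "    <ObjectClass>Acute Myeloid Leukemia</ObjectClass>",
    "    <Property>Classification</Property>",
    "    <ValueDomainLongName>Acute Myeloid Leukemia Type</ValueDomainLongName>",
    "    <RepresentationTerm>Type</RepresentationTerm>",
    "    <QuestionText>What was the classification of the acute myelogenous leukemia?</QuestionText>",
    "    <MappedClass>PerformedDiagnosis</MappedClass>",
    "  </DataElement>",
    "  <dataElement>",
    "    <publicId>2519</publicId>",
    "    <longName>Chronic Myelogenous Leukemia Classification Type</longName>",
    "    <objectClass>Chronic Myelogenous Leukemia</objectClass>",
    "  </dataElement>",
    "  <DataElement><Junk>nothing usable</Junk></DataElement>",
    "</DataElementsList>")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_warning(corpus <- read_corpus(path), "skipped 1")
  expect_identical(nrow(corpus$records), 2L)
  expect_identical(corpus$records$public_id, c("2518", "2519"))
  expect_identical(corpus$records$mapped_class[1], "PerformedDiagnosis")
  expect_identical(corpus$records$object_class[2], "Chronic Myelogenous Leukemia")
  expect_identical(corpus$records$question_text[2], "")
})

test_that("class-size filtering drops small classes and unmapped records", {
  classes <- c(rep("A", 12), rep("B", 9), rep("C", 10), NA)
  corpus <- make_longname_corpus(sprintf("name %d", seq_along(classes)), classes)
  kept <- filter_by_class_size(corpus, 10)
  expect_identical(nrow(kept$records), 22L)  # 12 + 10 survive
  expect_identical(sort(names(kept$class_index)), c("A", "C"))
  # min_size 1 keeps all mapped records
  all_mapped <- filter_by_class_size(corpus, 1)
  expect_identical(nrow(all_mapped$records), 31L)
  # every class too small -> empty corpus
  expect_identical(nrow(filter_by_class_size(corpus, 13)$records), 0L)
  # idempotence
  expect_identical(filter_by_class_size(kept, 10)$records, kept$records)
  # record order preserved
  expect_identical(kept$records$public_id, sort(kept$records$public_id))
})

test_that("stratified splitting is exact, seeded and conservative", {
  corpus <- make_longname_corpus(sprintf("w%d", 1:20), rep("A", 20))
  parts <- split_train_verify(corpus, 0.75, seed = 5)
  expect_identical(nrow(parts$train$records), 15L)
  expect_identical(nrow(parts$verify$records), 5L)
  # identical seed, identical split
  parts2 <- split_train_verify(corpus, 0.75, seed = 5)
  expect_identical(parts$train$records, parts2$train$records)
  # different seed, different membership (overwhelmingly likely)
  parts3 <- split_train_verify(corpus, 0.75, seed = 6)
  expect_false(identical(parts$train$records$public_id,
                         parts3$train$records$public_id))
  # conservation: disjoint partition covering the corpus
  ids <- c(parts$train$records$public_id, parts$verify$records$public_id)
  expect_identical(sort(ids), sort(corpus$records$public_id))
  expect_length(intersect(parts$train$records$public_id,
                          parts$verify$records$public_id), 0L)
})

test_that("splits conserve records for many classes and reject tiny strata", {
  corpus <- generate_corpus(synthetic_config(n_classes = 19,
                                             members_per_class = 6, seed = 2))
  parts <- split_train_verify(corpus, 0.9, seed = 1)
  expect_identical(nrow(parts$train$records) + nrow(parts$verify$records), 114L)
  # each class contributes to both sides
  expect_length(parts$train$class_index, 19L)
  expect_length(parts$verify$class_index, 19L)
  single <- make_longname_corpus(c("a", "b", "c"), c("A", "A", "B"))
  expect_error(split_train_verify(single, 0.5, seed = 1), "B")
  expect_error(split_train_verify(corpus, 1.0, seed = 1), "strictly between")
})

test_that("non-stratified splitting still partitions the corpus", {
  corpus <- tiny_separable_corpus(3, 6)
  parts <- split_train_verify(corpus, 0.6, seed = 3, stratified = FALSE)
  ids <- c(parts$train$records$public_id, parts$verify$records$public_id)
  expect_identical(sort(ids), sort(corpus$records$public_id))
  expect_identical(nrow(parts$train$records), 11L)  # round(0.6 * 18)
})
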