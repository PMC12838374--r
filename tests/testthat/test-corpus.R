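test_that("JSONL serialization round-trips byte-identically", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  reports <- list(tiny_report(),
                  report("rpt2", "Pièce d'exérèse de thyroïde analysée.",
                         language = "fr", sentences = list(c(0L, 37L)),
                         entities = list(entity_mention(0, 27, "SAMPLE_TYPE",
                                                        "Pièce d'exérèse de thyroïde"))))
  write_reports(reports, path)
  back <- read_reports(path)
  expect_identical(back, reports)
  # empty file -> empty sequence
  writeLines(character(0), path)
  expect_identical(read_reports(path), list())
})

test_that("invalid spans and overlapping entities are rejected with context", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"report_id":"bad1","text":"short","language":"en",',
                    '"sentences":[[0,5]],"entities":[{"start":0,"end":99,"type":"FINDING"}]}'),
             path)
  expect_error(read_reports(path), "bad1")
  writeLines("{not json", path)
  expect_error(read_reports(path), "line 1")
  expect_error(
    report("r", "abcdef", sentences = list(c(0L, 6L)),
           entities = list(entity_mention(0, 4, "FINDING", "abcd"),
                           entity_mention(2, 6, "FINDING", "cdef"))),
    "overlapping")
  expect_error(entity_mention(5, 3, "FINDING", "x"), "invalid span")
  expect_error(entity_mention(0, 3, "DRUG", "abc"), "unknown entity type")
})

test_that("spans_to_bio projects entities onto BIO word tags", {
  r <- tiny_report()
  ts <- spans_to_bio(r, 1)
  expect_identical(ts$tokens, c("Biopsy", "of", "thyroid", "received", "."))
  expect_identical(ts$tags, c("B-SAMPLE_TYPE", "I-SAMPLE_TYPE", "I-SAMPLE_TYPE",
                              "O", "O"))
  # sentence with no entities -> all O
  r2 <- report("r2", "No entity here.", sentences = list(c(0L, 15L)))
  expect_true(all(spans_to_bio(r2, 1)$tags == "O"))
  # adjacent entities of different types: the second starts with its own B-
  r3 <- report("r3", "thyroid osteosarcoma", sentences = list(c(0L, 20L)),
               entities = list(entity_mention(0, 7, "SAMPLE_TYPE", "thyroid"),
                               entity_mention(8, 20, "FINDING", "osteosarcoma")))
  expect_identical(spans_to_bio(r3, 1)$tags, c("B-SAMPLE_TYPE", "B-FINDING"))
  # a word partially overlapped by the entity is included
  r4 <- report("r4", "abcdef ghi", sentences = list(c(0L, 10L)),
               entities = list(entity_mention(2, 8, "FINDING", "cdef g")))
  expect_identical(spans_to_bio(r4, 1)$tags, c("B-FINDING", "I-FINDING"))
})

test_that("bio_to_spans inverts spans_to_bio and repairs illegal transitions", {
  r <- tiny_report()
  for (si in seq_along(r$sentences)) {
    ts <- spans_to_bio(r, si)
    got <- bio_to_spans(ts, text = r$text)
    s <- r$sentences[[si]]
    gold <- Filter(function(e) e$start >= s[1] && e$end <= s[2], r$entities)
    expect_equal(length(got), length(gold))
    for (i in seq_along(gold)) {
      expect_identical(got[[i]]$start, gold[[i]]$start)
      expect_identical(got[[i]]$end, gold[[i]]$end)
      expect_identical(got[[i]]$surface, gold[[i]]$surface)
      expect_identical(got[[i]]$entity_type, gold[[i]]$entity_type)
    }
  }
  # orphan I- is repaired as B-
  off <- data.frame(start = c(0L, 4L), end = c(3L, 8L))
  ts2 <- tagged_sequence(c("abc", "defg"), c("O", "I-FINDING"), off)
  got2 <- bio_to_spans(ts2, text = "abc defg")
  expect_equal(length(got2), 1L)
  expect_identical(got2[[1]]$entity_type, "FINDING")
  expect_identical(got2[[1]]$start, 4L)
  expect_error(bio_to_spans(list(tokens = "a", tags = "O", offsets = NULL)),
               "offsets")
})

test_that("BIO repair matches a brute-force oracle over all tag bigrams", {
  labs <- bio_labels()
  # oracle: an I-t is legal only right after B-t or I-t
  oracle <- function(tags) {
    out <- tags
    for (i in seq_along(tags)) {
      t <- tags[i]
      if (startsWith(t, "I-")) {
        prev <- if (i == 1L) "O" else out[i - 1L]
        ty <- substring(t, 3)
        legal <- prev %in% paste0(c("B-", "I-"), ty)
        if (!legal) out[i] <- paste0("B-", ty)
      }
    }
    out
  }
  for (a in labs) for (b in labs) {
    expect_identical(pathocode:::repair_bio(c(a, b)), oracle(c(a, b)),
                     info = paste(a, b))
  }
})

test_that("round-trip holds on generated reports", {
  corp <- small_corpus(15, noise = zero_noise, seed = 3)
  for (r in corp$reports[1:10]) {
    got <- list()
    for (si in seq_along(r$sentences))
      got <- c(got, bio_to_spans(spans_to_bio(r, si), text = r$text))
    expect_equal(length(got), length(r$entities))
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$start, r$entities[[i]]$start)
      expect_identical(got[[i]]$end, r$entities[[i]]$end)
    }
  }
})

test_that("align_labels follows the first-subword strategy with -100 masking", {
  ts <- tagged_sequence(c("lipoma", "found"), c("B-FINDING", "O"))
  # word 1 split into two subwords, specials at both ends
  al <- align_labels(ts, c(NA, 1L, 1L, 2L, NA),
                     subwords = c("[CLS]", "lip", "##oma", "found", "[SEP]"))
  expect_identical(al$label_ids,
                   c(-100L, bio_label_id("B-FINDING"), -100L,
                     bio_label_id("O"), -100L))
  # no word split -> ids equal word label ids, specials -100
  al2 <- align_labels(ts, c(NA, 1L, 2L))
  expect_identical(al2$label_ids, c(-100L, bio_label_id(ts$tags)))
  # all-special -> all -100
  expect_true(all(align_labels(ts, c(NA, NA))$label_ids == -100L))
  # all-subwords strategy labels continuations too
  al3 <- align_labels(ts, c(1L, 1L, 2L), strategy = "all")
  expect_identical(al3$label_ids,
                   c(rep(bio_label_id("B-FINDING"), 2L), bio_label_id("O")))
  expect_error(align_labels(ts, c(1L, 7L)), "out of range")
  # property: no real label where word_index is NA
  for (i in 1:20) {
    m <- sample(c(NA, 1L, 2L), 6, replace = TRUE)
    al <- align_labels(ts, m)
    expect_true(all(al$label_ids[is.na(al$word_index)] == -100L))
  }
})

test_that("CoNLL export writes token/tag lines with sentence breaks", {
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(list(tiny_report()), path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_true("Biopsy\tB-SAMPLE_TYPE" %in% lines)
  expect_true(any(lines == ""))
})

test_that("collect_mentions flattens entities with per-terminology codes", {
  m <- collect_mentions(list(tiny_report()))
  expect_equal(nrow(m), 3L)
  expect_identical(m$SNOMEDCT, c("111009", NA, "222009"))
  expect_identical(m$LOINC[2], "12345-6")
  expect_identical(m$ICD11[3], "2B51.0")
  expect_equal(nrow(collect_mentions(list())), 0L)
})
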