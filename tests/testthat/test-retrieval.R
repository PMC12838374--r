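test_that("dense index stores one unit-norm row per entry, deterministically", {
  tab <- tiny_concepts()
  enc <- hash_encoder(dim = 64, seed = 3)
  idx <- build_dense_index(tab, enc)
  expect_equal(nrow(idx$matrix), nrow(text_entries(tab)))
  expect_equal(unname(sqrt(rowSums(idx$matrix^2))),
               rep(1, nrow(idx$matrix)), tolerance = 1e-6)
  idx2 <- build_dense_index(tab, hash_encoder(dim = 64, seed = 3))
  expect_identical(idx$matrix, idx2$matrix)
  # row i equals the encoder output for that entry text
  expect_equal(idx$matrix[1, ], encode(enc, idx$texts[1])[1, ])
})

test_that("dense_search is exact: a verbatim entry ranks first at cosine 1", {
  idx <- build_dense_index(tiny_concepts(), hash_encoder(dim = 64, seed = 3))
  cs <- dense_search(idx, "thyroid biopsy", k = 2)
  expect_identical(cs$code[1], "111009")
  expect_equal(cs$score[1], 1, tolerance = 1e-6)
  # k >= number of codes returns all codes
  expect_equal(nrow(dense_search(idx, "anything", k = 99)), 3L)
  expect_error(dense_search(structure(list(codes = character(0)),
                                      class = "dense_index"), "x", 1),
               "empty")
})

test_that("dense ranking agrees with an exhaustive cosine oracle", {
  cfg <- generator_config(n_reports = 1, n_concepts = c(sample_type = 10,
                                                        test_performed = 5,
                                                        finding = 10),
                          distractor_concepts = c(sample_type = 0,
                                                  test_performed = 0,
                                                  finding = 0),
                          seed = 21)
  tab <- generate_terminology(cfg, "SNOMEDCT")
  enc <- hash_encoder(dim = 64, seed = 5)
  idx <- build_dense_index(tab, enc)
  entries <- text_entries(tab)
  set.seed(9)
  queries <- c(sample(entries$text, 10),
               paste(sample(letters, 10, TRUE), collapse = ""))
  for (q in queries) {
    got <- dense_search(idx, q, k = 5)
    qv <- encode(enc, q)[1, ]
    per_code <- tapply(vapply(seq_len(nrow(entries)), function(i)
      cosine_similarity(qv, idx$matrix[i, ]), numeric(1)),
      entries$code, max)
    want <- names(sort(per_code, decreasing = TRUE))
    # compare scores (ranking may permute within exact ties)
    expect_equal(got$score, as.numeric(sort(per_code, decreasing = TRUE))[1:5],
                 tolerance = 1e-9)
    expect_identical(got$code[1], want[1])
  }
})

test_that("bm25_score matches the Okapi formula evaluated by hand", {
  tab <- concept_table(data.frame(
    terminology = "LOINC", code = c("1-1", "2-2", "3-3"),
    label = c("thyroid biopsy", "thyroid stain", "bone biopsy"),
    synonyms = "", group = "g", parent = "", stringsAsFactors = FALSE))
  idx <- build_sparse_index(tab)          # k1 = 1.5, b = 0.75
  # N = 3, every doc has 2 tokens, avg_len = 2, length norm = k1
  # df(thyroid) = df(biopsy) = 2, idf = ln((3 - 2 + 0.5)/(2 + 0.5) + 1) = ln(1.6)
  # per matched term: idf * 1 * 2.5 / (1 + 1.5) = idf
  idf <- log(1.6)
  expect_equal(bm25_score(idx, c("thyroid", "biopsy"), 1), 2 * idf)
  expect_equal(bm25_score(idx, c("thyroid", "biopsy"), 2), idf)
  expect_equal(bm25_score(idx, c("thyroid", "biopsy"), 3), idf)
  # no query term present -> 0
  expect_equal(bm25_score(idx, c("zebra"), 1), 0)
  # duplicate entries receive identical scores
  tab2 <- concept_table(data.frame(
    terminology = "LOINC", code = c("1-1", "2-2"),
    label = c("giemsa stain", "giemsa stain x"), synonyms = c("", "giemsa stain"),
    group = "g", parent = "", stringsAsFactors = FALSE))
  idx2 <- build_sparse_index(tab2)
  expect_equal(bm25_score(idx2, c("giemsa"), 1), bm25_score(idx2, c("giemsa"), 3))
})

test_that("sparse_search ranks by best BM25 per code with lexicographic ties", {
  tab <- tiny_concepts()
  idx <- build_sparse_index(tab)
  cs <- sparse_search(idx, "biopsy of thyroid", k = 3)
  expect_identical(cs$code[1], "111009")
  # empty query after tokenization
  expect_equal(nrow(sparse_search(idx, "   ", k = 3)), 0L)
  # ranking matches brute-force scoring of every entry
  entries <- text_entries(tab)
  q <- "osteosarcoma of bone"
  qt <- pathocode:::bm25_tokens(q)
  brute <- tapply(vapply(seq_len(nrow(entries)), function(i)
    bm25_score(idx, qt, i), numeric(1)), entries$code, max)
  got <- sparse_search(idx, q, k = 3)
  expect_equal(got$score, as.numeric(sort(brute, decreasing = TRUE)),
               tolerance = 1e-12)
  # exact ties break to the lexicographically smaller code
  tie_tab <- concept_table(data.frame(
    terminology = "LOINC", code = c("9-9", "1-1"), label = c("x y", "x z"),
    synonyms = "", group = "g", parent = "", stringsAsFactors = FALSE))
  tie <- sparse_search(build_sparse_index(tie_tab), "x", k = 2)
  expect_identical(tie$code, c("1-1", "9-9"))
})

test_that("candidate sets keep the best score per code, non-increasing", {
  cs <- candidate_set(c("b", "a", "b"), c(0.2, 0.5, 0.9), "dense", "q")
  expect_identical(cs$code, c("b", "a"))
  expect_equal(cs$score, c(0.9, 0.5))
  expect_true(all(diff(cs$score) <= 0))
  # equal scores: lexicographic order
  cs2 <- candidate_set(c("z", "a"), c(0.5, 0.5), "dense")
  expect_identical(cs2$code, c("a", "z"))
})

test_that("dense index persistence round-trips", {
  tab <- tiny_concepts()
  idx <- build_dense_index(tab, hash_encoder(dim = 32, seed = 1))
  dir <- withr::local_tempdir()
  save_dense_index(idx, dir)
  back <- load_dense_index(dir)
  expect_equal(back$matrix, idx$matrix)
  expect_identical(back$codes, idx$codes)
  expect_identical(back$fingerprint, idx$fingerprint)
  q <- "biopsy of thyroid"
  expect_identical(dense_search(back, q, 3)$code, dense_search(idx, q, 3)$code)
})
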