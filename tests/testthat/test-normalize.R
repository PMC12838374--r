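test_that("entity types route to their terminologies", {
  expect_identical(route_terminologies("SAMPLE_TYPE"), "SNOMEDCT")
  expect_identical(route_terminologies("TEST_PERFORMED"), "LOINC")
  expect_identical(route_terminologies("FINDING"), c("SNOMEDCT", "ICD11"))
  expect_error(route_terminologies("DRUG"), "unknown entity type")
})

test_that("code classifier fits, predicts proper distributions, validates codes", {
  surfaces <- c(rep("thyroid biopsy", 6), rep("osteosarcoma", 6))
  codes <- c(rep("111009", 6), rep("222009", 6))
  enc <- hash_encoder(dim = 64, seed = 2)
  m <- fit_code_classifier(surfaces, codes, "SNOMEDCT", enc,
                           coder_config(epochs = 20, seed = 1))
  P <- predict(m, c("thyroid biopsy", "osteosarcoma", "random text"))
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-9)
  expect_identical(colnames(P)[max.col(P)][1:2], c("111009", "222009"))
  # a gold code missing from the concept table is an error naming the code
  expect_error(fit_code_classifier(surfaces, c(codes[-1], "999"), "SNOMEDCT",
                                   enc, table = tiny_concepts()), "999")
  expect_error(fit_code_classifier("x", "1", "SNOMEDCT", enc), "2 distinct")
})

test_that("early stopping halts before the epoch cap when validation stalls", {
  # tiny dataset + large learning rate makes validation loss oscillate
  set.seed(3)
  surfaces <- paste0("term ", sample(letters, 40, replace = TRUE))
  codes <- sample(c("a", "b", "c"), 40, replace = TRUE)
  m <- fit_code_classifier(surfaces, codes, "SNOMEDCT",
                           hash_encoder(dim = 32, seed = 1),
                           coder_config(epochs = 10, learning_rate = 5,
                                        patience = 2, seed = 2))
  expect_lt(m$fit$epochs_run, 10)
})

test_that("classifier candidates are the top-k of the probability vector", {
  surfaces <- c(rep("alpha text", 5), rep("beta text", 5), rep("gamma text", 5))
  codes <- rep(c("1", "2", "3"), each = 5)
  m <- fit_code_classifier(surfaces, codes, "SNOMEDCT",
                           hash_encoder(dim = 32, seed = 4),
                           coder_config(epochs = 15, seed = 1))
  p <- predict(m, "alpha text")[1, ]
  cs <- classifier_candidates(m, "alpha text", k = 2)
  # full-sort oracle
  want <- names(sort(p, decreasing = TRUE))[1:2]
  expect_identical(cs$code, want)
  expect_true(all(diff(cs$score) <= 0))
  expect_identical(classifier_candidates(m, "alpha text", k = 1)$code,
                   names(which.max(p)))
  expect_warning(all3 <- classifier_candidates(m, "alpha text", k = 10),
                 "label space")
  expect_equal(nrow(all3), 3L)
})

test_that("fuse applies the weighted rule and the confidence fallback", {
  clf <- candidate_set(c("A", "B"), c(0.8, 0.2), "classifier", "q")
  dense <- candidate_set(c("B", "C"), c(0.9, 0.4), "dense", "q")
  # w = 1, confident: classifier argmax
  expect_identical(fuse(clf, dense, fusion_config(w = 1, tau = 0))$code, "A")
  # w = 0: decision reduces to retrieval similarities
  expect_identical(fuse(clf, dense, fusion_config(w = 0, tau = 0))$code, "B")
  # fallback: low confidence routes to dense rank-1 even when the fused
  # score favours the classifier code
  clf_low <- candidate_set(c("A", "B"), c(0.2, 0.1), "classifier", "q")
  dense2 <- candidate_set(c("B"), c(-0.9), "dense", "q")   # sim01 = 0.05
  cfg <- fusion_config(w = 0.9, tau = 0.5)
  dec <- fuse(clf_low, dense2, cfg)
  expect_identical(dec$code, "B")
  expect_identical(dec$source, "retrieval_fallback")
  # fused scores: pool union, missing components read 0
  f <- fuse(clf, dense, fusion_config(w = 0.5, tau = 0))$candidates
  expect_setequal(f$code, c("A", "B", "C"))
  expect_equal(f$score[f$code == "A"], 0.5 * 0.8)
  expect_equal(f$score[f$code == "B"], 0.5 * 0.2 + 0.5 * 0.95)
  # exact ties break lexicographically
  tie <- fuse(candidate_set(c("Z", "M"), c(0.5, 0.5), "classifier"),
              candidate_set(character(0), numeric(0), "dense"),
              fusion_config(w = 1, tau = 0))
  expect_identical(tie$code, "M")
  expect_error(fuse(candidate_set(character(0), numeric(0), "classifier"),
                    candidate_set(character(0), numeric(0), "dense"),
                    fusion_config()), "empty")
})

test_that("optimize_fusion finds configurations matching the data regime", {
  tab <- tiny_concepts()
  enc <- hash_encoder(dim = 64, seed = 5)
  idx <- build_dense_index(tab, enc)
  # surfaces are exact entries: retrieval is perfect, so some config reaches
  # CV accuracy 1 and the winner is reproducible
  surfaces <- rep(c("biopsy of thyroid", "osteosarcoma of the bone",
                    "biopsy of bone"), each = 5)
  codes <- rep(c("111009", "222009", "333009"), each = 5)
  cfg1 <- optimize_fusion(surfaces, codes, "SNOMEDCT", idx, enc, seed = 7,
                          config = coder_config(epochs = 5, seed = 1))
  expect_equal(attr(cfg1, "cv_accuracy"), 1)
  cfg1b <- optimize_fusion(surfaces, codes, "SNOMEDCT", idx, enc, seed = 7,
                           config = coder_config(epochs = 5, seed = 1))
  expect_identical(unclass(cfg1)[c("w", "tau", "k")],
                   unclass(cfg1b)[c("w", "tau", "k")])
  # grid membership
  expect_true(cfg1$w %in% seq(0, 1, by = 0.1))
  expect_true(cfg1$tau %in% seq(0, 0.9, by = 0.1))
  # winner is never below both degenerate corners
  tab_cv <- attr(cfg1, "cv_table")
  corner_clf <- tab_cv$mean_accuracy[tab_cv$w == 1 & tab_cv$tau == 0]
  corner_ret <- tab_cv$mean_accuracy[tab_cv$w == 0 & tab_cv$tau == 0]
  expect_gte(attr(cfg1, "cv_accuracy"), max(corner_clf, corner_ret))
  # useless-classifier / exact-retrieval regime routes to retrieval: every
  # code occurs once, so in cross-validation the held-out code is always
  # outside the fold classifier's label space while retrieval is exact
  gcfg <- generator_config(n_reports = 1,
                           n_concepts = c(sample_type = 8, test_performed = 5,
                                          finding = 8),
                           distractor_concepts = c(sample_type = 0,
                                                   test_performed = 0,
                                                   finding = 0),
                           seed = 33)
  tab2 <- generate_terminology(gcfg, "SNOMEDCT")
  idx2 <- build_dense_index(tab2, enc)
  cfg2 <- optimize_fusion(tab2$concepts$label, tab2$concepts$code, "SNOMEDCT",
                          idx2, enc, seed = 7,
                          config = coder_config(epochs = 2, seed = 1))
  expect_equal(attr(cfg2, "cv_accuracy"), 1)
  # the winning rule follows retrieval on a fresh exact query despite a
  # confident wrong classifier
  probe <- tab2$concepts$label[5]
  dec <- fuse(candidate_set(tab2$concepts$code[1], 0.95, "classifier"),
              dense_search(idx2, probe, 3), cfg2)
  expect_identical(dec$code, tab2$concepts$code[5])
  expect_error(optimize_fusion(surfaces[1:3], codes[1:3], "SNOMEDCT", idx, enc),
               "at least 5")
})

test_that("normalize_mentions produces routed, in-table decisions with trails", {
  corp <- small_corpus(40, noise = zero_noise, seed = 9)
  parts <- split_reports(corp$reports, 0.8, seed = 2)
  enc <- hash_encoder(dim = 128, seed = 3)
  tm <- collect_mentions(parts$train)
  models <- list(); indices <- list()
  for (term in terminologies()) {
    m <- pathocode:::routed_mentions(tm, term)
    models[[term]] <- fit_code_classifier(m$surface, m[[term]], term, enc,
                                          coder_config(seed = 1))
    indices[[term]] <- build_dense_index(corp$tables[[term]], enc)
  }
  sm <- collect_mentions(parts$test)
  res <- normalize_mentions(sm, models, indices, fusion_config(w = 0.3, tau = 0.5))
  # one row per mention and routed terminology
  expect_equal(nrow(res), sum(vapply(sm$entity_type, function(t)
    length(route_terminologies(t)), integer(1))))
  for (term in terminologies()) {
    rows <- res[res$terminology == term, ]
    expect_true(all(rows$code %in% corp$tables[[term]]$concepts$code))
  }
  # the chosen code is always in the fused candidate pool
  trail <- attr(res, "trail")
  for (i in seq_len(nrow(res)))
    expect_true(res$code[i] %in% trail[[i]]$fused$code)
  # zero-noise corpus: fused decisions at least as accurate as classifier-only
  acc_fused <- mean(res$code == res$gold)
  clf_only <- vapply(seq_len(nrow(res)), function(i)
    trail[[i]]$classifier$code[1], "")
  expect_gte(acc_fused, mean(clf_only == res$gold))
  # empty input and missing models
  empty <- normalize_mentions(collect_mentions(list()), models, indices)
  expect_equal(nrow(empty), 0L)
  expect_error(normalize_mentions(sm, models["LOINC"], indices),
               "no model")
})
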