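# End-to-end pipeline: simulate/ingest -> report split -> tagger training ->
# knowledge-base indexing -> code-classifier training -> fusion optimisation
# -> normalization of the four system variants -> evaluation and paired
# comparisons. Every artifact is stamped with the configuration hash and
# seed; a re-run with identical inputs is bit-identical.

#' Pipeline configuration
#'
#' @param corpus either `NULL` (simulate with `generator`) or a list with
#'   `reports` (JSONL path) and per-terminology concept TSV paths.
#' @param generator a [generator_config()] used when `corpus` is NULL.
#' @param encoder_dim embedding dimensionality for mention encoding and
#'   retrieval.
#' @param tagger a [tagger_config()].
#' @param coder a [coder_config()].
#' @param grid_w,grid_tau fusion grids (see [optimize_fusion()]).
#' @param k candidate depth.
#' @param n_boot bootstrap iterations for the tagging confidence interval.
#' @param n_perm permutation iterations for system comparisons.
#' @param train_frac report-level training fraction.
#' @param seed global pipeline seed; stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = NULL, generator = generator_config(),
                            encoder_dim = 256L,
                            tagger = tagger_config(),
                            coder = coder_config(),
                            grid_w = seq(0, 1, by = 0.1),
                            grid_tau = seq(0, 0.9, by = 0.1),
                            k = 5L, n_boot = 10000L, n_perm = 10000L,
                            train_frac = 0.8, seed = 1L) {
  structure(list(corpus = corpus, generator = generator,
                 encoder_dim = as.integer(encoder_dim), tagger = tagger,
                 coder = coder, grid_w = grid_w, grid_tau = grid_tau,
                 k = as.integer(k), n_boot = as.integer(n_boot),
                 n_perm = as.integer(n_perm), train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `corpus`, `generator`, `encoder_dim`,
#' `tagger`, `coder`, `grid_w`, `grid_tau`, `k`, `n_boot`, `n_perm`,
#' `train_frac`, `seed`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  args <- list()
  for (k in names(y)) {
    args[[k]] <- switch(k,
      generator = do.call(generator_config, y[[k]]),
      tagger = do.call(tagger_config, y[[k]]),
      coder = do.call(coder_config, y[[k]]),
      y[[k]])
  }
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  sprintf("%x", str_hash(paste(deparse(unclass(config)), collapse = ""), 7L))
}

# gold mention rows routed to one terminology (findings appear in both
# SNOMEDCT and ICD11 slices)
routed_mentions <- function(mentions, terminology) {
  ok <- vapply(mentions$entity_type,
               function(ty) terminology %in% route_terminologies(ty), logical(1))
  m <- mentions[ok & !is.na(mentions[[terminology]]), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, report-level split, tagger training and
#' evaluation, index building, per-terminology classifier training, fusion
#' optimisation, normalization under five system variants (classifier only,
#' dense retrieval only, BM25 retrieval only, classifier + BM25 fusion,
#' classifier + dense fusion), and the statistical comparison of the fused
#' system against the classifier-only and sparse-fusion baselines.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, `report.json` and corpus
#'   artifacts are written there.
#' @return list of class `pipeline_result` with elements `ner` (tagging
#'   evaluation + bootstrap CI), `coding` (per-terminology table of the
#'   systems), `comparisons` (per-terminology [compare_systems()] objects),
#'   `fusion` (optimized configs), `meta` (seed, config hash, sizes).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  # ingest or simulate ------------------------------------------------------
  if (is.null(config$corpus)) {
    gen <- config$generator
    gen$seed <- as.integer(derive_seed(seed, "generator") %% 2147483647)
    corpus <- generate_corpus(gen)
    tables <- corpus$tables
    reports <- corpus$reports
  } else {
    cp <- config$corpus
    if (is.null(cp$reports) || !file.exists(cp$reports))
      stop("stage ingest: missing reports path")
    reports <- read_reports(cp$reports)
    tables <- list()
    for (t in terminologies()) {
      p <- cp[[tolower(t)]]
      if (is.null(p) || !file.exists(p))
        stopf("stage build-kb: missing concept table path for %s", t)
      tables[[t]] <- load_concepts(p)
    }
  }
  # split --------------------------------------------------------------------
  split_tag <- attr(reports, "split")
  if (!is.null(split_tag)) {
    parts <- list(train = reports[split_tag == "train"],
                  test = reports[split_tag == "test"])
  } else {
    parts <- split_reports(reports, train_frac = config$train_frac,
                           seed = derive_seed(seed, "split"))
  }
  # tagger -------------------------------------------------------------------
  tcfg <- config$tagger
  tcfg$seed <- as.integer(derive_seed(seed, "tagger") %% 2147483647)
  tagger <- train_tagger(parts$train, tcfg)
  tagged <- lapply(parts$test, function(r) tag_report(tagger, r))
  ner <- evaluate_tagging(parts$test, tagged)
  f1_ci <- bootstrap_ci(ner$unit_scores, mean, n_boot = config$n_boot,
                        seed = derive_seed(seed, "boot"))
  # knowledge base + indices -------------------------------------------------
  encoder <- hash_encoder(dim = config$encoder_dim,
                          seed = as.integer(derive_seed(seed, "encoder") %% 2147483647))
  dense <- lapply(tables, build_dense_index, encoder = encoder)
  sparse <- lapply(tables, build_sparse_index)
  # classifiers + fusion -----------------------------------------------------
  train_mentions <- collect_mentions(parts$train)
  test_mentions <- collect_mentions(parts$test)
  ccfg <- config$coder
  ccfg$seed <- as.integer(derive_seed(seed, "coder") %% 2147483647)
  models <- list(); fusions <- list()
  for (term in terminologies()) {
    m <- routed_mentions(train_mentions, term)
    models[[term]] <- fit_code_classifier(m$surface, m[[term]], term,
                                          encoder = encoder, config = ccfg,
                                          table = tables[[term]])
    fusions[[term]] <- optimize_fusion(m$surface, m[[term]], term,
                                       index = dense[[term]],
                                       encoder = encoder,
                                       grid_w = config$grid_w,
                                       grid_tau = config$grid_tau,
                                       k = config$k, seed = derive_seed(seed, "fusion"),
                                       config = ccfg)
  }
  # four system variants -----------------------------------------------------
  coding <- list(); comparisons <- list(); predictions <- list()
  for (term in terminologies()) {
    m <- routed_mentions(test_mentions, term)
    gold <- m[[term]]
    clf_sets <- lapply(m$surface, function(s)
      suppressWarnings(classifier_candidates(models[[term]], s, k = config$k)))
    dense_sets <- lapply(m$surface, function(s)
      dense_search(dense[[term]], s, k = config$k))
    sparse_sets <- lapply(m$surface, function(s)
      sparse_search(sparse[[term]], s, k = config$k))
    cfg_t <- fusions[[term]]
    pred <- list(
      classifier = vapply(clf_sets, function(cs) cs$code[1], ""),
      dense = vapply(dense_sets, function(ds) ds$code[1], ""),
      sparse = vapply(sparse_sets, function(ss)
        if (nrow(ss)) ss$code[1] else NA_character_, ""),
      sparse_fusion = vapply(seq_along(gold), function(i)
        fuse(clf_sets[[i]], sparse_sets[[i]], cfg_t)$code, ""),
      fusion = vapply(seq_along(gold), function(i)
        fuse(clf_sets[[i]], dense_sets[[i]], cfg_t)$code, ""))
    evals <- lapply(pred, function(p) suppressWarnings(evaluate_codes(gold, p)))
    coding[[term]] <- data.frame(
      system = names(evals),
      accuracy = vapply(evals, function(e) e$accuracy, 0),
      precision_macro = vapply(evals, function(e) unname(e$macro["precision"]), 0),
      recall_macro = vapply(evals, function(e) unname(e$macro["recall"]), 0),
      f1_macro = vapply(evals, function(e) unname(e$macro["f1"]), 0),
      kappa = vapply(evals, function(e) e$kappa, 0),
      mcc = vapply(evals, function(e) e$mcc, 0),
      row.names = NULL, stringsAsFactors = FALSE)
    comparisons[[term]] <- list(
      fusion_vs_classifier = compare_systems(gold, pred$fusion, pred$classifier,
                                             n_perm = config$n_perm,
                                             seed = derive_seed(seed, paste0("perm1", term))),
      fusion_vs_sparse = compare_systems(gold, pred$fusion, pred$sparse_fusion,
                                         n_perm = config$n_perm,
                                         seed = derive_seed(seed, paste0("perm2", term))))
    predictions[[term]] <- c(list(gold = gold), pred)
  }
  result <- structure(list(
    ner = list(eval = ner, f1_ci = f1_ci),
    coding = coding, comparisons = comparisons, fusion = fusions,
    predictions = predictions,
    meta = list(seed = seed, config_hash = config_hash(config),
                n_reports = length(reports),
                n_train = length(parts$train), n_test = length(parts$test),
                n_test_mentions = nrow(test_mentions))),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(jsonlite::toJSON(pipeline_report_json(result), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "report.json"))
  }
  result
}

# serialisable summary of a pipeline result (schema version 1)
pipeline_report_json <- function(result) {
  list(
    schema = "pathocode-report/1",
    meta = result$meta,
    ner = list(micro = as.list(result$ner$eval$micro),
               macro = as.list(result$ner$eval$macro),
               per_type = result$ner$eval$per_type,
               f1_ci = list(lo = unname(result$ner$f1_ci["lo"]),
                            hi = unname(result$ner$f1_ci["hi"]),
                            point = attr(result$ner$f1_ci, "point"))),
    fusion = lapply(result$fusion, function(f)
      list(w = f$w, tau = f$tau, k = f$k, cv_accuracy = attr(f, "cv_accuracy"))),
    coding = result$coding,
    comparisons = lapply(result$comparisons, function(cs) lapply(cs, function(x)
      list(n = x$n, accuracy_a = x$accuracy_a, accuracy_b = x$accuracy_b,
           accuracy_difference = x$accuracy_difference,
           mcnemar_b = unname(x$mcnemar["b"]), mcnemar_c = unname(x$mcnemar["c"]),
           mcnemar_p = unname(x$mcnemar["p"]), permutation_p = x$permutation_p))))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed=%d hash=%s | %d reports (%d train / %d test)\n",
              x$meta$seed, x$meta$config_hash, x$meta$n_reports,
              x$meta$n_train, x$meta$n_test))
  cat(sprintf("NER micro-F1 %.3f (95%% CI %.3f-%.3f)\n",
              x$ner$eval$micro["f1"], x$ner$f1_ci["lo"], x$ner$f1_ci["hi"]))
  for (term in names(x$coding)) {
    cat("\n", term, " coding (N = ", x$comparisons[[term]]$fusion_vs_classifier$n,
        "):\n", sep = "")
    df <- x$coding[[term]]
    df[-1] <- round(df[-1], 4)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
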