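# Mention-to-code normalization: per-terminology softmax classification
# heads over mention embeddings, entity-type -> terminology routing, and the
# fusion/reranking rule combining classifier probabilities with retrieval
# similarities under a confidence-based retrieval fallback.

#' Route an entity type to its terminologies
#'
#' Specimens map to the clinical-concept terminology, methods to the
#' laboratory-observation terminology, and diagnoses to both the clinical
#' and disease-classification terminologies.
#'
#' @param entity_type one of [entity_types()].
#' @return character vector of terminologies.
#' @export
route_terminologies <- function(entity_type) {
  switch(entity_type,
         SAMPLE_TYPE = "SNOMEDCT",
         TEST_PERFORMED = "LOINC",
         FINDING = c("SNOMEDCT", "ICD11"),
         stopf("unknown entity type '%s'", entity_type))
}

#' Code classifier configuration
#'
#' Defaults mirror the standardization training protocol: at most 10 epochs
#' of AdamW with early stopping when the validation loss (a seeded 10% split
#' of the training mentions) fails to improve for 2 consecutive epochs.
#'
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs.
#' @param val_frac validation fraction of the training mentions.
#' @inheritParams tagger_config
#' @return list of class `coder_config`.
#' @export
coder_config <- function(epochs = 10L, learning_rate = 0.05, batch_size = 8L,
                         weight_decay = 0.01, patience = 2L, val_frac = 0.1,
                         seed = 1L) {
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, weight_decay = weight_decay,
                 patience = patience, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "coder_config")
}

#' Fit a per-terminology code classifier
#'
#' Softmax head over mention embeddings with the code label space fixed at
#' fit time. Gold codes may optionally be checked against a concept table.
#'
#' @param surfaces character vector of mention surfaces.
#' @param codes gold codes, parallel to `surfaces` (>= 2 distinct).
#' @param terminology terminology tag.
#' @param encoder a `pathocode_encoder`.
#' @param config a [coder_config()].
#' @param table optional [concept_table()]; a gold code absent from it is an
#'   error naming the code.
#' @return object of class `code_classifier`.
#' @export
fit_code_classifier <- function(surfaces, codes, terminology,
                                encoder = hash_encoder(),
                                config = coder_config(), table = NULL) {
  stopifnot(length(surfaces) == length(codes))
  if (!is.null(table)) {
    missing <- setdiff(codes, table$concepts$code)
    if (length(missing))
      stopf("gold code(s) absent from the %s table: %s", terminology,
            paste(unique(missing), collapse = ", "))
  }
  space <- sort(unique(codes))
  if (length(space) < 2L) stop("need at least 2 distinct codes")
  y <- match(codes, space)
  X <- encode(encoder, surfaces)
  n <- length(y)
  n_val <- max(1L, floor(config$val_frac * n))
  idx <- with_seed(derive_seed(config$seed, paste0("coder-split-", terminology)),
                   sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  # keep the label space intact: if a code only occurs in the validation
  # slice, move one instance back into training
  missing_cls <- setdiff(seq_along(space), unique(y[tr_idx]))
  for (m in missing_cls) {
    mv <- val_idx[which(y[val_idx] == m)[1]]
    tr_idx <- c(tr_idx, mv); val_idx <- setdiff(val_idx, mv)
  }
  val <- if (length(val_idx)) list(X = X[val_idx, , drop = FALSE], y = y[val_idx]) else NULL
  fit <- softmax_sgd_fit(X[tr_idx, , drop = FALSE], y[tr_idx],
                         n_classes = length(space),
                         epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         weight_decay = config$weight_decay,
                         seed = derive_seed(config$seed, paste0("coder-", terminology)),
                         val = val, patience = config$patience)
  structure(list(terminology = terminology, fit = fit, codes = space,
                 encoder = encoder, config = config),
            class = "code_classifier")
}

#' @export
print.code_classifier <- function(x, ...) {
  cat(sprintf("<code_classifier %s> %d codes, %d epoch(s) run\n",
              x$terminology, length(x$codes), x$fit$epochs_run))
  invisible(x)
}

#' @export
predict.code_classifier <- function(object, surfaces, ...) {
  X <- encode(object$encoder, surfaces)
  P <- softmax_predict_prob(object$fit, X)
  colnames(P) <- object$codes
  P
}

#' Top-k classifier candidates
#'
#' @param model a [fit_code_classifier()] result.
#' @param text mention surface.
#' @param k candidate depth (capped at the label-space size with a warning).
#' @return a [candidate_set()] with `source = "classifier"`.
#' @export
classifier_candidates <- function(model, text, k = 5L) {
  p <- predict(model, text)[1, ]
  if (k > length(p)) {
    warnf("k = %d exceeds the label space (%d); returning all", k, length(p))
    k <- length(p)
  }
  candidate_set(names(p), as.numeric(p), "classifier", query = text, k = k)
}

#' Fusion configuration
#'
#' @param w fusion weight in `[0, 1]` on the classifier probability.
#' @param tau confidence threshold in `[0, 1]`: below it the retrieval
#'   rank-1 candidate overrides the fused decision.
#' @param k candidate depth (>= 1).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(w = 0.5, tau = 0.3, k = 5L) {
  stopifnot(w >= 0, w <= 1, tau >= 0, tau <= 1, k >= 1)
  structure(list(w = w, tau = tau, k = as.integer(k)), class = "fusion_config")
}

# map retrieval scores into [0, 1] for fusion: cosine -> (cos+1)/2; BM25 ->
# score / max score in the candidate set (documented choice; BM25 is
# unbounded)
rescale_retrieval <- function(cand) {
  if (!nrow(cand)) return(numeric(0))
  if (identical(cand$source[1], "sparse")) {
    mx <- max(cand$score)
    if (mx > 0) cand$score / mx else rep(0, nrow(cand))
  } else (cand$score + 1) / 2
}

#' Fuse classifier and retrieval candidates
#'
#' The candidate pool is the union of both sets' codes. Fused score
#' `s(c) = w * p_clf(c) + (1 - w) * sim01(c)` where `sim01` is the
#' retrieval similarity rescaled to `[0, 1]` (cosine via `(cos+1)/2`, BM25
#' via division by the in-set maximum); a missing component reads 0.
#' Fallback: when the classifier's maximum probability is below `tau`, the
#' retrieval rank-1 code is returned regardless of the fused scores. Ties
#' break to the lexicographically smaller code.
#'
#' @param clf a classifier [candidate_set()] (may be empty).
#' @param retr a dense or sparse retrieval [candidate_set()] (may be empty).
#' @param cfg a [fusion_config()].
#' @return list with `code` (the decision), `source` (`"fused"` or
#'   `"retrieval_fallback"`), and `candidates` (the fused candidate set).
#' @export
fuse <- function(clf, retr, cfg = fusion_config()) {
  if ((is.null(clf) || !nrow(clf)) && (is.null(retr) || !nrow(retr)))
    stop("both candidate sets are empty")
  if (is.null(clf)) clf <- candidate_set(character(0), numeric(0), "classifier")
  if (is.null(retr)) retr <- candidate_set(character(0), numeric(0), "dense")
  pool <- union(clf$code, retr$code)
  p_clf <- stats::setNames(rep(0, length(pool)), pool)
  if (nrow(clf)) p_clf[clf$code] <- clf$score
  sim01 <- stats::setNames(rep(0, length(pool)), pool)
  if (nrow(retr)) sim01[retr$code] <- rescale_retrieval(retr)
  fused_scores <- cfg$w * p_clf + (1 - cfg$w) * sim01
  fused <- candidate_set(pool, as.numeric(fused_scores), "fused",
                         query = attr(clf, "query") %||% attr(retr, "query"))
  conf <- if (nrow(clf)) max(clf$score) else 0
  retr1 <- if (nrow(retr)) retr$code[1] else NA_character_
  dec <- fuse_decide(pool, p_clf, sim01, retr1, conf, cfg$w, cfg$tau)
  list(code = dec$code, source = dec$source, candidates = fused)
}

# the bare fusion decision rule, shared between fuse() and the
# cross-validated grid search so the two can never disagree
fuse_decide <- function(pool, p_clf, sim01, retr1, conf, w, tau) {
  if (conf < tau && !is.na(retr1))
    return(list(code = retr1, source = "retrieval_fallback"))
  s <- w * p_clf + (1 - w) * sim01
  o <- order(-s, pool)
  list(code = pool[o[1]], source = "fused")
}

#' Optimize the fusion rule by cross-validation
#'
#' Exhaustive grid search over `(w, tau)` maximizing the mean k-fold
#' accuracy of the fused decision. Within each fold a fresh code classifier
#' is fitted on the training folds while the retrieval index is fixed; every
#' grid point is then scored on the held-out fold. Folds are seeded and
#' stratified by code where possible. Ties break to smaller `tau`, then
#' smaller `w`.
#'
#' @param surfaces,codes training mentions (>= 5) with gold codes.
#' @param terminology terminology tag.
#' @param index a retrieval index ([build_dense_index()] or
#'   [build_sparse_index()]).
#' @param encoder encoder for the fold classifiers.
#' @param grid_w,grid_tau candidate grids (defaults 0..1 by 0.1 and 0..0.9
#'   by 0.1).
#' @param k candidate depth.
#' @param folds number of folds, default 5.
#' @param seed RNG seed for fold assignment.
#' @param config a [coder_config()] for the fold classifiers.
#' @return a [fusion_config()] with attributes `cv_accuracy` (winning mean
#'   accuracy) and `cv_table` (the full grid).
#' @export
optimize_fusion <- function(surfaces, codes, terminology, index,
                            encoder = hash_encoder(),
                            grid_w = seq(0, 1, by = 0.1),
                            grid_tau = seq(0, 0.9, by = 0.1),
                            k = 5L, folds = 5L, seed = 1L,
                            config = coder_config()) {
  n <- length(surfaces)
  stopifnot(length(codes) == n)
  if (n < 5L) stop("need at least 5 mentions to cross-validate")
  # stratified fold assignment: shuffle within code, deal round-robin
  fold_id <- integer(n)
  with_seed(derive_seed(seed, paste0("fusion-folds-", terminology)), {
    start <- 0L
    for (cd in unique(codes)) {
      ii <- which(codes == cd)
      ii <- ii[sample.int(length(ii))]
      fold_id[ii] <- ((start + seq_along(ii) - 1L) %% folds) + 1L
      start <- start + length(ii)
    }
  })
  grid <- expand.grid(w = grid_w, tau = grid_tau)
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- fold_id == f
    if (!any(te) || length(unique(codes[tr])) < 2L) next
    cfg_f <- config; cfg_f$seed <- as.integer(derive_seed(seed, paste0("fold", f)) %% 2147483647)
    model <- fit_code_classifier(surfaces[tr], codes[tr], terminology,
                                 encoder = encoder, config = cfg_f)
    te_idx <- which(te)
    # precompute, per held-out mention, the ingredients of the decision rule
    pre <- lapply(te_idx, function(i) {
      clf <- suppressWarnings(classifier_candidates(model, surfaces[i], k = k))
      retr <- if (inherits(index, "dense_index")) dense_search(index, surfaces[i], k = k)
        else sparse_search(index, surfaces[i], k = k)
      pool <- union(clf$code, retr$code)
      p_clf <- stats::setNames(rep(0, length(pool)), pool)
      p_clf[clf$code] <- clf$score
      sim01 <- stats::setNames(rep(0, length(pool)), pool)
      if (nrow(retr)) sim01[retr$code] <- rescale_retrieval(retr)
      list(pool = pool, p_clf = p_clf, sim01 = sim01,
           retr1 = if (nrow(retr)) retr$code[1] else NA_character_,
           conf = if (nrow(clf)) max(clf$score) else 0)
    })
    for (g in seq_len(nrow(grid))) {
      pred <- vapply(pre, function(p)
        fuse_decide(p$pool, p$p_clf, p$sim01, p$retr1, p$conf,
                    grid$w[g], grid$tau[g])$code, "")
      acc[g, f] <- mean(pred == codes[te_idx])
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  # ties: smaller tau, then smaller w
  o <- order(-mean_acc, grid$tau, grid$w)
  best <- o[1]
  out <- fusion_config(grid$w[best], grid$tau[best], k)
  attr(out, "cv_accuracy") <- mean_acc[best]
  attr(out, "cv_table") <- cbind(grid, mean_accuracy = mean_acc)
  out
}

#' Normalize mentions to codes
#'
#' For every mention and every terminology its entity type routes to, fuses
#' the classifier candidates with retrieval candidates and records the
#' decision with its full candidate trail.
#'
#' @param mentions data.frame as from [collect_mentions()] (columns
#'   `surface`, `entity_type`, plus optional gold-code columns named by
#'   terminology).
#' @param models named list of [fit_code_classifier()] objects, one per
#'   routed terminology (missing model = error).
#' @param indices named list of retrieval indices, one per routed
#'   terminology.
#' @param configs named list of [fusion_config()]s (a single config is
#'   recycled).
#' @param k candidate depth.
#' @return data.frame of class `normalization_result` with one row per
#'   (mention, terminology): `report_id`, `surface`, `entity_type`,
#'   `terminology`, `code`, `source`, `gold` (NA if absent); the candidate
#'   trails are in attribute `"trail"`.
#' @export
normalize_mentions <- function(mentions, models, indices,
                               configs = fusion_config(), k = 5L) {
  if (inherits(configs, "fusion_config"))
    configs <- stats::setNames(rep(list(configs), length(terminologies())),
                               terminologies())
  rows <- list(); trail <- list()
  for (i in seq_len(nrow(mentions))) {
    ty <- mentions$entity_type[i]
    for (term in route_terminologies(ty)) {
      if (is.null(models[[term]]))
        stopf("no model for routed terminology %s", term)
      if (is.null(indices[[term]]))
        stopf("no retrieval index for routed terminology %s", term)
      surf <- mentions$surface[i]
      clf <- suppressWarnings(classifier_candidates(models[[term]], surf, k = k))
      retr <- if (inherits(indices[[term]], "dense_index"))
        dense_search(indices[[term]], surf, k = k)
      else sparse_search(indices[[term]], surf, k = k)
      dec <- fuse(clf, retr, configs[[term]])
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = mentions$report_id[i] %||% NA_character_,
        surface = surf, entity_type = ty, terminology = term,
        code = dec$code, source = dec$source,
        gold = if (!is.null(mentions[[term]])) mentions[[term]][i] else NA_character_,
        stringsAsFactors = FALSE)
      trail[[length(trail) + 1L]] <- list(classifier = clf, retrieval = retr,
                                          fused = dec$candidates)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(report_id = character(0), surface = character(0),
               entity_type = character(0), terminology = character(0),
               code = character(0), source = character(0), gold = character(0))
  attr(out, "trail") <- trail
  class(out) <- c("normalization_result", "data.frame")
  out
}
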