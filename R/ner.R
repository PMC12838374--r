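# Reference token-level entity tagger: windowed hashing embeddings feeding a
# softmax head trained with AdamW on the BIO cross-entropy objective. The
# tagger fills the TokenClassifier contract at desk scale; a transformer
# token classifier can replace it behind the same interface.

#' Tagger configuration
#'
#' Training protocol defaults mirror a short transformer fine-tune: 3 epochs,
#' AdamW, batch size 8, weight decay 0.01. The learning rate default (0.05)
#' is the transformer-scale 2e-5 rescaled for this shallow hashed-feature
#' head, whose gradients are orders of magnitude smaller than a deep
#' network's; it is configurable.
#'
#' @param epochs,learning_rate,batch_size,weight_decay optimizer settings.
#' @param window context window half-width; token features concatenate the
#'   hashed embeddings of the token and its `window` neighbours on each side
#'   (zero padding at sentence edges).
#' @param dim hashing-embedding dimensionality per token.
#' @param seed pipeline seed; split, initialisation and batch order derive
#'   from it.
#' @return list of class `tagger_config`.
#' @export
tagger_config <- function(epochs = 3L, learning_rate = 0.05, batch_size = 8L,
                          weight_decay = 0.01, window = 2L, dim = 128L,
                          seed = 1L) {
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, weight_decay = weight_decay,
                 window = as.integer(window), dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "tagger_config")
}

#' Report-level train/test split
#'
#' Disjoint, exhaustive partition of report ids; fractions within one report
#' of the requested split.
#'
#' @param reports list of reports.
#' @param train_frac fraction of reports in the training partition.
#' @param seed RNG seed.
#' @return list with `train` and `test` report lists.
#' @export
split_reports <- function(reports, train_frac = 0.8, seed = 1L) {
  n <- length(reports)
  n_train <- round(train_frac * n)
  idx <- with_seed(seed, sample.int(n))
  list(train = reports[sort(idx[seq_len(n_train)])],
       test = reports[sort(idx[setdiff(seq_len(n), seq_len(n_train))])])
}

#' Windowed token features
#'
#' Feature row for token i = concatenation of the hashing embeddings of
#' tokens i-window .. i+window (zero vectors beyond the sentence edges), so
#' each row has `(2*window+1)*dim` columns. Deterministic.
#'
#' @param tokens character vector (one sentence).
#' @param encoder a `pathocode_encoder`.
#' @param window context half-width (>= 0).
#' @return numeric matrix, one row per token.
#' @export
featurize_tokens <- function(tokens, encoder, window = 2L) {
  stopifnot(window >= 0L)
  n <- length(tokens)
  E <- encode(encoder, stringi::stri_trans_tolower(tokens), unit_norm = TRUE)
  d <- ncol(E)
  out <- matrix(0, n, (2L * window + 1L) * d)
  for (off in -window:window) {
    cols <- (off + window) * d + seq_len(d)
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, cols] <- E[src[ok], , drop = FALSE]
  }
  out
}

# assemble the (features, label-id) training matrix over all sentences;
# labels are 1-based indices into bio_labels()
tagger_design <- function(reports, encoder, window) {
  Xs <- list(); ys <- list()
  for (r in reports) {
    for (si in seq_along(r$sentences)) {
      ts <- spans_to_bio(r, si)
      if (!length(ts$tokens)) next
      Xs[[length(Xs) + 1L]] <- featurize_tokens(ts$tokens, encoder, window)
      ys[[length(ys) + 1L]] <- match(ts$tags, bio_labels())
    }
  }
  if (!length(Xs)) stop("no tokens in training reports")
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

#' Train the reference entity tagger
#'
#' Fits a multinomial softmax head over windowed hashing features by
#' minibatch AdamW on the BIO cross-entropy objective. Seeded and
#' deterministic. Labels equal to the ignore index (-100) are excluded from
#' the fit (they can arise when training from subword-aligned examples).
#'
#' @param reports training reports (>= 1, with sentences).
#' @param config a [tagger_config()].
#' @return object of class `entity_tagger` with `predict`/`print` methods;
#'   see [tag_report()] for decoding whole reports.
#' @export
train_tagger <- function(reports, config = tagger_config()) {
  if (!length(reports)) stop("empty training set")
  encoder <- hash_encoder(dim = config$dim, seed = config$seed)
  des <- tagger_design(reports, encoder, config$window)
  present <- sort(unique(des$y))
  if (length(present) < length(bio_labels()))
    warnf("training data covers %d of %d BIO labels", length(present),
          length(bio_labels()))
  fit <- fit_token_classifier(des$X, des$y, config, encoder = encoder)
  fit
}

#' @rdname train_tagger
#' @param X feature matrix; `y` integer ids in 1..7 (positions labelled
#'   -100 are dropped).
#' @param y integer labels, 1-based into [bio_labels()], or -100.
#' @param encoder encoder used to build `X` (stored for tagging).
#' @export
fit_token_classifier <- function(X, y, config = tagger_config(), encoder = NULL) {
  keep <- y != IGNORE_INDEX
  X <- as.matrix(X)[keep, , drop = FALSE]; y <- y[keep]
  if (!length(y)) stop("no unmasked positions")
  fit <- softmax_sgd_fit(X, y, n_classes = length(bio_labels()),
                         epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         weight_decay = config$weight_decay,
                         seed = derive_seed(config$seed, "tagger"))
  structure(list(fit = fit, encoder = encoder %||% hash_encoder(config$dim, config$seed),
                 window = config$window, labels = bio_labels(),
                 config = config),
            class = "entity_tagger")
}

#' @export
print.entity_tagger <- function(x, ...) {
  cat(sprintf("<entity_tagger> window=%d, dim=%d, %d epochs, final loss %.4f\n",
              x$window, x$encoder$dim, x$fit$epochs_run,
              utils::tail(x$fit$loss_history, 1)))
  invisible(x)
}

#' @export
predict.entity_tagger <- function(object, tokens, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  X <- featurize_tokens(tokens, object$encoder, object$window)
  P <- softmax_predict_prob(object$fit, X)
  colnames(P) <- object$labels
  if (type == "prob") P else object$labels[max.col(P, ties.method = "first")]
}

#' Tag a report
#'
#' Runs the tagger over every sentence (argmax label per token), repairs
#' illegal BIO transitions, and decodes entity spans. Deterministic.
#'
#' @param model a trained [train_tagger()] object.
#' @param rep a [report()].
#' @return a copy of the report whose `entities` are the predicted mentions;
#'   the per-sentence [tagged_sequence()]s are attached as attribute
#'   `"tagged"`.
#' @export
tag_report <- function(model, rep) {
  if (!inherits(model, "entity_tagger")) stop("untrained or invalid model")
  seqs <- list(); ents <- list()
  for (si in seq_along(rep$sentences)) {
    s <- rep$sentences[[si]]
    toks <- word_tokenize(substr(rep$text, s[1] + 1L, s[2]), shift = s[1])
    if (!nrow(toks)) next
    tags <- predict(model, toks$token, type = "label")
    ts <- tagged_sequence(toks$token, repair_bio(tags), toks[, c("start", "end")])
    seqs[[length(seqs) + 1L]] <- ts
    ents <- c(ents, bio_to_spans(ts, text = rep$text))
  }
  out <- rep
  out$entities <- ents
  attr(out, "tagged") <- seqs
  out
}

#' Token-level tagging evaluation
#'
#' Compares gold and predicted annotations token by token on the collapsed
#' entity-type labels (`O`, `SAMPLE_TYPE`, `TEST_PERFORMED`, `FINDING`), the
#' unit the per-entity precision/recall/F1 tables use. Micro metrics treat
#' the three entity types as the positive classes (`O` is the negative
#' class). A span-level exact-match F1 is included as a secondary view.
#'
#' @param gold_reports,pred_reports aligned report lists (same ids/texts).
#' @return list of class `ner_eval`: `confusion` (4x4), `per_type` metrics
#'   data.frame, `micro` and `macro` P/R/F1, `span` exact-match metrics, and
#'   per-report micro-F1 scores (`unit_scores`) for bootstrap use.
#' @export
evaluate_tagging <- function(gold_reports, pred_reports) {
  stopifnot(length(gold_reports) == length(pred_reports))
  types <- entity_types()
  labs <- c("O", types)
  collapse <- function(tags) sub("^[BI]-", "", tags)
  g_all <- character(0); p_all <- character(0); unit <- numeric(0)
  span_tp <- 0L; span_fp <- 0L; span_fn <- 0L
  for (i in seq_along(gold_reports)) {
    gr <- gold_reports[[i]]; pr <- pred_reports[[i]]
    g_tags <- character(0); p_tags <- character(0)
    for (si in seq_along(gr$sentences)) {
      g_tags <- c(g_tags, collapse(spans_to_bio(gr, si)$tags))
      p_tags <- c(p_tags, collapse(spans_to_bio(pr, si)$tags))
    }
    g_all <- c(g_all, g_tags); p_all <- c(p_all, p_tags)
    ent <- g_tags != "O" | p_tags != "O"
    tp <- sum(g_tags == p_tags & g_tags != "O")
    fp <- sum(p_tags != "O" & g_tags != p_tags)
    fn <- sum(g_tags != "O" & g_tags != p_tags)
    unit <- c(unit, if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn))
    gs <- vapply(gr$entities, function(e) paste(e$start, e$end, e$entity_type), "")
    ps <- vapply(pr$entities, function(e) paste(e$start, e$end, e$entity_type), "")
    span_tp <- span_tp + length(intersect(gs, ps))
    span_fp <- span_fp + length(setdiff(ps, gs))
    span_fn <- span_fn + length(setdiff(gs, ps))
  }
  cm <- confusion_matrix(factor(g_all, labs), factor(p_all, labs))
  per <- prf(cm)
  per_type <- per$per_label[per$per_label$label %in% types, , drop = FALSE]
  tp <- sum(g_all == p_all & g_all != "O")
  fp <- sum(p_all != "O" & g_all != p_all)
  fn <- sum(g_all != "O" & g_all != p_all)
  micro <- c(precision = if (tp + fp) tp / (tp + fp) else 0,
             recall = if (tp + fn) tp / (tp + fn) else 0)
  micro["f1"] <- if (sum(micro)) 2 * prod(micro) / sum(micro) else 0
  span_p <- if (span_tp + span_fp) span_tp / (span_tp + span_fp) else 0
  span_r <- if (span_tp + span_fn) span_tp / (span_tp + span_fn) else 0
  structure(list(confusion = cm, per_type = per_type,
                 micro = micro,
                 macro = c(precision = mean(per_type$precision),
                           recall = mean(per_type$recall),
                           f1 = mean(per_type$f1)),
                 span = c(precision = span_p, recall = span_r,
                          f1 = if (span_p + span_r) 2 * span_p * span_r / (span_p + span_r) else 0),
                 unit_scores = unit),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat("Token-level entity metrics (2 dp):\n")
  df <- x$per_type
  df[c("precision", "recall", "f1")] <- round(df[c("precision", "recall", "f1")], 2)
  print(df, row.names = FALSE)
  cat(sprintf("micro P/R/F1: %.2f/%.2f/%.2f   macro F1: %.2f   span F1: %.2f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"],
              x$macro["f1"], x$span["f1"]))
  invisible(x)
}
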