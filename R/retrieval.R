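# Dense cosine nearest-neighbour search and Okapi BM25 sparse search over
# terminology text entries. Both searches are exact and exhaustive — the
# entry sets here are terminology subsets of at most a few thousand rows, so
# the reference backend is a full scan; any approximate backend must satisfy
# the same contract.

#' Ranked candidate set
#'
#' Ranked `(code, score)` pairs from one retrieval or classification source.
#' Scores are non-increasing and codes unique (best score per code kept);
#' ties are broken by lexicographically smaller code.
#'
#' @param codes,scores parallel vectors (possibly with repeated codes; the
#'   best score per code is retained).
#' @param source one of `"classifier"`, `"dense"`, `"sparse"`, `"fused"`.
#' @param query the query text.
#' @param k keep at most the top `k` codes (NULL = all).
#' @return object of class `candidate_set`: data.frame `code`, `score`,
#'   `source` with attribute `query`.
#' @export
candidate_set <- function(codes, scores, source, query = "", k = NULL) {
  stopifnot(length(codes) == length(scores))
  if (length(codes)) {
    o <- order(-scores, codes)
    codes <- codes[o]; scores <- scores[o]
    keep <- !duplicated(codes)
    codes <- codes[keep]; scores <- scores[keep]
    if (!is.null(k) && length(codes) > k) {
      codes <- codes[seq_len(k)]; scores <- scores[seq_len(k)]
    }
  }
  structure(data.frame(code = as.character(codes), score = as.numeric(scores),
                       source = rep(source, length(codes)),
                       stringsAsFactors = FALSE),
            query = query, class = c("candidate_set", "data.frame"))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> query='%s', %d candidate(s)\n",
              attr(x, "query"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

# -- dense ------------------------------------------------------------------

#' Build a dense terminology index
#'
#' Encodes every text entry (label and each synonym separately) of a concept
#' table into a unit-norm embedding row. Deterministic for a fixed encoder
#' configuration.
#'
#' @param table a [concept_table()].
#' @param encoder a `pathocode_encoder` (see [hash_encoder()]).
#' @return object of class `dense_index`.
#' @export
build_dense_index <- function(table, encoder) {
  entries <- text_entries(table)
  E <- encode(encoder, entries$text, unit_norm = TRUE)
  structure(list(matrix = E, codes = entries$code, texts = entries$text,
                 terminology = table$terminology, encoder = encoder,
                 fingerprint = encoder_fingerprint(encoder)),
            class = "dense_index")
}

#' @export
print.dense_index <- function(x, ...) {
  cat(sprintf("<dense_index %s> %d entries / %d codes, %s\n", x$terminology,
              length(x$codes), length(unique(x$codes)), x$fingerprint))
  invisible(x)
}

#' Dense cosine nearest-neighbour search
#'
#' Scores every entry by cosine similarity to the query embedding and ranks
#' codes by the best score over each code's entries. Exact (exhaustive).
#'
#' @param index a [build_dense_index()] result.
#' @param query query text.
#' @param k number of codes to return (>= 1).
#' @return a [candidate_set()] with `source = "dense"`.
#' @export
dense_search <- function(index, query, k = 5L) {
  if (!length(index$codes)) stop("empty dense index")
  stopifnot(k >= 1L)
  q <- encode(index$encoder, query, unit_norm = TRUE)[1, ]
  sims <- as.vector(index$matrix %*% q)
  candidate_set(index$codes, sims, "dense", query = query, k = k)
}

# -- sparse (Okapi BM25) ----------------------------------------------------

# lowercase word tokens, same tokenizer as the corpus module
bm25_tokens <- function(text) {
  stringi::stri_trans_tolower(word_tokenize(text)$token)
}

#' Build a BM25 sparse index
#'
#' Okapi BM25 over the same per-entry texts as the dense index, with
#' lowercase word tokenization shared with the corpus module.
#'
#' @param table a [concept_table()].
#' @param k1 term-frequency saturation parameter (> 0), default 1.5.
#' @param b length-normalisation parameter in `[0, 1]`, default 0.75.
#' @return object of class `sparse_index`.
#' @export
build_sparse_index <- function(table, k1 = 1.5, b = 0.75) {
  stopifnot(k1 > 0, b >= 0, b <= 1)
  entries <- text_entries(table)
  toks <- lapply(entries$text, bm25_tokens)
  tf <- lapply(toks, function(t) table(t))
  lens <- vapply(toks, length, integer(1))
  df_counts <- table(unlist(lapply(toks, unique)))
  structure(list(tf = tf, lens = lens, df = df_counts, N = length(toks),
                 avg_len = mean(lens), codes = entries$code,
                 texts = entries$text, terminology = table$terminology,
                 k1 = k1, b = b),
            class = "sparse_index")
}

#' @export
print.sparse_index <- function(x, ...) {
  cat(sprintf("<sparse_index %s> %d entries, k1=%.2f b=%.2f\n",
              x$terminology, x$N, x$k1, x$b))
  invisible(x)
}

#' Okapi BM25 score of one entry for a tokenized query
#'
#' `sum_t idf(t) * tf*(k1+1) / (tf + k1*(1 - b + b*len/avglen))` with
#' `idf(t) = ln((N - df + 0.5)/(df + 0.5) + 1)` (never negative). Query terms
#' absent from the entry contribute 0.
#'
#' @param index a [build_sparse_index()] result.
#' @param query_tokens character vector of lowercase query tokens.
#' @param entry_id 1-based entry index.
#' @return scalar score.
#' @export
bm25_score <- function(index, query_tokens, entry_id) {
  tf <- index$tf[[entry_id]]
  if (!length(query_tokens) || !length(tf)) return(0)
  norm <- index$k1 * (1 - index$b + index$b * index$lens[entry_id] / index$avg_len)
  s <- 0
  for (t in query_tokens) {
    f <- tf[t]
    if (is.na(f)) next
    f <- as.numeric(f)
    df_t <- as.numeric(index$df[t])
    idf <- log((index$N - df_t + 0.5) / (df_t + 0.5) + 1)
    s <- s + idf * f * (index$k1 + 1) / (f + norm)
  }
  unname(s)
}

#' BM25 sparse search
#'
#' Ranks codes by the best BM25 score over each code's entries; ties break
#' to the lexicographically smaller code. An empty query (after
#' tokenization) returns an empty candidate set.
#'
#' @inheritParams dense_search
#' @param index a [build_sparse_index()] result.
#' @return a [candidate_set()] with `source = "sparse"`.
#' @export
sparse_search <- function(index, query, k = 5L) {
  stopifnot(k >= 1L)
  qt <- bm25_tokens(query)
  if (!length(qt)) return(candidate_set(character(0), numeric(0), "sparse", query))
  scores <- vapply(seq_len(index$N), function(i) bm25_score(index, qt, i),
                   numeric(1))
  candidate_set(index$codes, scores, "sparse", query = query, k = k)
}

# -- persistence ------------------------------------------------------------

#' Persist / restore a dense index
#'
#' Writes a directory holding the entry matrix (binary doubles), the
#' entry-to-code table (TSV) and a JSON manifest (terminology, encoder
#' fingerprint, dimensions). Only hashing-encoder indices can be restored
#' (an external encoder is not serialisable).
#'
#' @param index a `dense_index`.
#' @param dir directory to create/use.
#' @export
save_dense_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "matrix.bin"), "wb")
  writeBin(as.vector(index$matrix), con, size = 8)
  close(con)
  utils::write.table(data.frame(code = index$codes, text = index$texts),
                     file.path(dir, "entries.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  enc <- index$encoder
  manifest <- list(terminology = index$terminology,
                   fingerprint = index$fingerprint,
                   n_entries = length(index$codes), dim = ncol(index$matrix),
                   encoder = if (inherits(enc, "hash_encoder"))
                     list(type = "hashing", dim = enc$dim, seed = enc$seed,
                          ngram = enc$ngram) else list(type = "external"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_dense_index
#' @export
load_dense_index <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(manifest$encoder$type, "hashing"))
    stop("only hashing-encoder indices can be restored from disk")
  entries <- utils::read.delim(file.path(dir, "entries.tsv"),
                               colClasses = "character", quote = "",
                               fileEncoding = "UTF-8")
  con <- file(file.path(dir, "matrix.bin"), "rb")
  v <- readBin(con, "double", n = manifest$n_entries * manifest$dim, size = 8)
  close(con)
  enc <- hash_encoder(manifest$encoder$dim, manifest$encoder$seed,
                      manifest$encoder$ngram)
  structure(list(matrix = matrix(v, nrow = manifest$n_entries),
                 codes = entries$code, texts = entries$text,
                 terminology = manifest$terminology, encoder = enc,
                 fingerprint = manifest$fingerprint),
            class = "dense_index")
}
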