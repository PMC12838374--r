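# Numeric kernels (softmax, scaled dot-product attention, masked
# cross-entropy, cosine similarity) and the deterministic character-n-gram
# feature-hashing text encoder used by retrieval, the tagger and the code
# classifiers.

#' Numerically stable softmax
#'
#' @param z finite numeric vector of logits (length >= 1).
#' @return probability vector summing to 1; invariant to adding a constant.
#' @export
softmax <- function(z) {
  if (!length(z)) stop("softmax of an empty vector")
  if (any(!is.finite(z))) stop("softmax requires finite logits")
  e <- exp(z - max(z))
  e / sum(e)
}

# row-wise stable softmax of a matrix
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`: each output row is a convex
#' combination of the rows of `V`.
#'
#' @param Q query matrix (n_q x d_k).
#' @param K key matrix (n_k x d_k).
#' @param V value matrix (n_k x d_v).
#' @return n_q x d_v output matrix.
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d_k <- ncol(Q)
  if (d_k == 0L) stop("key dimensionality d_k must be positive")
  if (ncol(K) != d_k) stopf("Q and K disagree on d_k (%d vs %d)", d_k, ncol(K))
  if (nrow(K) != nrow(V)) stopf("K and V disagree on row count (%d vs %d)",
                                nrow(K), nrow(V))
  W <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  W %*% V
}

#' Masked cross-entropy loss
#'
#' Mean of `-log(p_true)` over positions whose label is not the ignore
#' index. Natural log.
#'
#' @param prob matrix of predicted probabilities, one row per position.
#' @param labels integer true-class indices (1-based columns of `prob`), with
#'   `ignore_index` marking masked positions.
#' @param ignore_index label value excluded from the loss (default -100).
#' @param eps probability floor guarding `log(0)`.
#' @return non-negative scalar loss.
#' @export
cross_entropy <- function(prob, labels, ignore_index = -100L, eps = 1e-12) {
  prob <- as.matrix(prob)
  if (nrow(prob) != length(labels)) stop("prob rows and labels differ in length")
  keep <- which(labels != ignore_index)
  if (!length(keep)) stop("no unmasked positions")
  p <- prob[cbind(keep, labels[keep])]
  mean(-log(pmax(p, eps)))
}

#' Cosine similarity
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return scalar in `[-1, 1]`; 1 for parallel vectors, scale-invariant.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# -- feature-hashing encoder ------------------------------------------------

# character n-grams of the '#'-padded lowercased text
char_ngrams <- function(text, nmin, nmax) {
  s <- paste0("#", stringi::stri_trans_tolower(text), "#")
  nc <- nchar(s)
  out <- character(0)
  for (n in nmin:nmax) {
    if (nc >= n) out <- c(out, substring(s, 1:(nc - n + 1L), n:nc))
  }
  out
}

# 32-bit modular multiply, exact in doubles
mul32 <- function(a, b) {
  lo <- a %% 65536; hi <- a %/% 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
}

# signed-bucket hash of one text; returns an unnormalised dim-vector. The
# polynomial hash is finalised by a multiplicative (Fibonacci) scramble and
# buckets/signs are read from the high bits — low bits of a plain polynomial
# hash are too structured (parity correlates across n-grams).
hash_features <- function(text, dim, seed, nmin, nmax) {
  grams <- char_ngrams(text, nmin, nmax)
  v <- numeric(dim)
  if (!length(grams)) return(v)
  for (g in grams) {
    h1 <- str_hash(g, seed = seed, mult = 31)
    h2 <- str_hash(g, seed = seed + 1, mult = 131)
    m1 <- mul32(h1, 2654435761)
    m2 <- mul32(h2, 2246822519)
    idx <- floor(m1 / 4294967296 * dim) + 1
    v[idx] <- v[idx] + if (m2 < 2147483648) 1 else -1
  }
  v
}

#' Deterministic character-n-gram hashing encoder
#'
#' Maps texts to dense unit-norm vectors by feature hashing of character
#' n-grams with signed buckets. Deterministic for a fixed `(dim, seed,
#' ngram)` configuration and identical across platforms; an all-empty text
#' maps to the first unit basis vector. Per-string results are memoised, so
#' repeated tokens are encoded once.
#'
#' @param dim embedding dimensionality (>= 16).
#' @param seed hash seed.
#' @param ngram integer vector `c(min, max)` n-gram sizes.
#' @return object of class `hash_encoder`.
#' @seealso [external_encoder()] for plugging in a transformer-style encoder.
#' @export
hash_encoder <- function(dim = 256L, seed = 1L, ngram = c(3L, 5L)) {
  dim <- as.integer(dim)
  if (dim < 16L) stop("dim must be >= 16")
  structure(list(dim = dim, seed = as.integer(seed),
                 ngram = as.integer(ngram), cache = new.env(parent = emptyenv())),
            class = c("hash_encoder", "pathocode_encoder"))
}

#' Adapter for an external (e.g. transformer) text encoder
#'
#' Wraps a user-supplied `encode_fn(texts) -> n x dim matrix` (for instance a
#' call into a served transformer model with mean pooling over non-special
#' tokens) behind the same contract as [hash_encoder()]. Rows are re-normalised
#' to unit L2 norm.
#'
#' @param encode_fn function mapping a character vector to a numeric matrix.
#' @param dim embedding dimensionality the function returns.
#' @param id identifier string used in index fingerprints.
#' @return object of class `external_encoder`.
#' @export
external_encoder <- function(encode_fn, dim, id = "external") {
  stopifnot(is.function(encode_fn), dim >= 1)
  structure(list(dim = as.integer(dim), encode_fn = encode_fn, id = id),
            class = c("external_encoder", "pathocode_encoder"))
}

#' Encode texts into embedding rows
#'
#' @param encoder a `pathocode_encoder`.
#' @param texts character vector.
#' @param unit_norm rescale rows to unit L2 norm (default TRUE).
#' @return numeric matrix, one row per text.
#' @export
encode <- function(encoder, texts, unit_norm = TRUE) UseMethod("encode")

#' @export
encode.hash_encoder <- function(encoder, texts, unit_norm = TRUE) {
  out <- matrix(0, nrow = length(texts), ncol = encoder$dim)
  for (i in seq_along(texts)) {
    key <- paste0("t:", texts[[i]])   # prefix: "" is not a legal env name
    v <- encoder$cache[[key]]
    if (is.null(v)) {
      v <- hash_features(texts[[i]], encoder$dim, encoder$seed,
                         encoder$ngram[1], encoder$ngram[2])
      if (all(v == 0)) v[1] <- 1  # empty/degenerate text -> fixed basis vector
      assign(key, v, envir = encoder$cache)
    }
    out[i, ] <- v
  }
  if (unit_norm) out <- out / sqrt(rowSums(out^2))
  out
}

#' @export
encode.external_encoder <- function(encoder, texts, unit_norm = TRUE) {
  out <- encoder$encode_fn(texts)
  out <- as.matrix(out)
  if (ncol(out) != encoder$dim || nrow(out) != length(texts))
    stopf("external encoder returned %dx%d, expected %dx%d",
          nrow(out), ncol(out), length(texts), encoder$dim)
  if (unit_norm) out <- out / sqrt(rowSums(out^2))
  out
}

#' @rdname encode
#' @export
encoder_fingerprint <- function(encoder) UseMethod("encoder_fingerprint")

#' @export
encoder_fingerprint.hash_encoder <- function(encoder) {
  sprintf("hash:dim=%d:seed=%d:ngram=%d-%d", encoder$dim, encoder$seed,
          encoder$ngram[1], encoder$ngram[2])
}

#' @export
encoder_fingerprint.external_encoder <- function(encoder) {
  sprintf("external:%s:dim=%d", encoder$id, encoder$dim)
}

#' @export
print.hash_encoder <- function(x, ...) {
  cat("<hash_encoder>", encoder_fingerprint(x), "\n"); invisible(x)
}

#' @export
print.external_encoder <- function(x, ...) {
  cat("<external_encoder>", encoder_fingerprint(x), "\n"); invisible(x)
}
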