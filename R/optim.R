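# Minibatch AdamW trainer for a multinomial softmax head, used by both the
# reference token tagger and the per-terminology code classifiers. Written
# against a fixed contract: cross-entropy loss, -100 positions excluded
# upstream, decoupled weight decay, optional early stopping on a validation
# loss, and bit-reproducible results under a seed.

# Fit W (d x K), bias (K). y: integer class ids in 1..K. Positions labelled
# with the ignore index must be removed by the caller.
softmax_sgd_fit <- function(X, y, n_classes, epochs = 3L, learning_rate = 0.05,
                            batch_size = 8L, weight_decay = 0.01, seed = 1L,
                            val = NULL, patience = NULL,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); K <- as.integer(n_classes)
  if (n == 0L) stop("empty training set")
  stopifnot(length(y) == n, all(y >= 1L & y <= K))
  W <- matrix(0, d, K); b0 <- numeric(K)
  mW <- matrix(0, d, K); vW <- matrix(0, d, K)
  mb <- numeric(K); vb <- numeric(K)
  step <- 0L
  Yind <- cbind(seq_len(n), y)
  loss_of <- function(W, b0, X, y) {
    P <- softmax_rows(sweep(X %*% W, 2, b0, "+"))
    cross_entropy(P, y)
  }
  history <- numeric(0); val_history <- numeric(0)
  best <- list(W = W, b = b0, loss = Inf); bad_epochs <- 0L
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        yb <- y[rows]
        P <- softmax_rows(sweep(Xb %*% W, 2, b0, "+"))
        P[cbind(seq_along(rows), yb)] <- P[cbind(seq_along(rows), yb)] - 1
        gW <- crossprod(Xb, P) / length(rows)
        gb <- colSums(P) / length(rows)
        step <- step + 1L
        mW <- beta1 * mW + (1 - beta1) * gW
        vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        mh <- mW / (1 - beta1^step); vh <- vW / (1 - beta2^step)
        # decoupled weight decay: applied to W directly, not through the moments
        W <- W - learning_rate * (mh / (sqrt(vh) + eps) + weight_decay * W)
        b0 <- b0 - learning_rate * (mb / (1 - beta1^step)) /
          (sqrt(vb / (1 - beta2^step)) + eps)
      }
      history <- c(history, loss_of(W, b0, X, y))
      if (!is.null(val) && !is.null(patience)) {
        vl <- loss_of(W, b0, val$X, val$y)
        val_history <- c(val_history, vl)
        if (vl < best$loss - 1e-12) {
          best <- list(W = W, b = b0, loss = vl); bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
          if (bad_epochs >= patience) break
        }
      }
    }
  })
  if (!is.null(val) && !is.null(patience) && is.finite(best$loss)) {
    W <- best$W; b0 <- best$b
  }
  list(W = W, b = b0, n_classes = K, loss_history = history,
       val_history = val_history, epochs_run = length(history))
}

softmax_predict_prob <- function(fit, X) {
  X <- as.matrix(X)
  softmax_rows(sweep(X %*% fit$W, 2, fit$b, "+"))
}
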