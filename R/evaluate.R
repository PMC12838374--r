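# Metrics and statistical tests: confusion-matrix precision/recall/F1,
# per-label error rates, bootstrap percentile confidence intervals,
# one-sample t-tests against a baseline, Cohen's kappa, multiclass Matthews
# correlation, the exact McNemar test and a paired sign-flip permutation
# test, plus a paired-system comparison report.

#' Confusion matrix
#'
#' Gold labels in rows, predictions in columns; row sums equal the gold
#' support per label.
#'
#' @param gold,pred equal-length vectors (coerced to a common factor).
#' @param labels optional label ordering (defaults to the sorted union).
#' @return object of class `confusion_matrix` (an integer matrix).
#' @export
confusion_matrix <- function(gold, pred, labels = NULL) {
  if (length(gold) != length(pred)) stop("gold and pred differ in length")
  if (is.null(labels)) labels <- sort(unique(c(as.character(gold), as.character(pred))))
  g <- factor(as.character(gold), levels = labels)
  p <- factor(as.character(pred), levels = labels)
  m <- table(gold = g, predicted = p)
  structure(unclass(m), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (gold x predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Precision, recall and F1 per label
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; a zero denominator
#' yields 0 with a warning. Macro averages are unweighted means over labels.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `per_label` (data.frame `label`, `precision`, `recall`,
#'   `f1`, `support`), `macro` (named vector) and `accuracy`.
#' @export
prf <- function(cm) {
  m <- unclass(cm)
  if (!length(m)) stop("empty confusion matrix")
  labels <- rownames(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  zero <- (tp + fp == 0) | (tp + fn == 0)
  if (any(zero)) warnf("zero-denominator metric(s) reported as 0 for: %s",
                       paste(labels[zero], collapse = ", "))
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  per <- data.frame(label = labels, precision = unname(p), recall = unname(r),
                    f1 = unname(f1), support = unname(rowSums(m)),
                    stringsAsFactors = FALSE)
  list(per_label = per,
       macro = c(precision = mean(p), recall = mean(r), f1 = mean(f1)),
       accuracy = sum(tp) / sum(m))
}

#' F1 from a precision/recall pair
#'
#' Harmonic mean `2PR/(P + R)`; 0 when both are 0.
#'
#' @param precision,recall rates in `[0, 1]`.
#' @return scalar F1.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Absolute and relative error per label
#'
#' Absolute error = off-diagonal mass of the label's gold row; relative
#' error = absolute / gold support (NA when the support is zero).
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame `label`, `absolute`, `relative`, `support`.
#' @export
error_rates <- function(cm) {
  m <- unclass(cm)
  support <- rowSums(m)
  absolute <- support - diag(m)
  relative <- ifelse(support > 0, absolute / support, NA_real_)
  data.frame(label = rownames(m), absolute = unname(absolute),
             relative = unname(relative), support = unname(support),
             stringsAsFactors = FALSE)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples the per-unit scores with replacement `n_boot` times and takes
#' percentile bounds of the metric. The resampling unit is whatever the
#' scores vector represents (reports for tagging metrics, mentions for
#' coding metrics). Resamples on which the metric is undefined (NA/NaN) are
#' redrawn, counted and warned about. Deterministic given `seed`.
#'
#' @param scores numeric per-unit scores (length >= 2).
#' @param metric function of a numeric vector (default [mean()]).
#' @param n_boot number of bootstrap iterations, default 10000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed.
#' @return named vector `c(lo, hi)` with attribute `"point"` (the metric on
#'   the full sample) and `"redrawn"`.
#' @export
bootstrap_ci <- function(scores, metric = mean, n_boot = 10000L, level = 0.95,
                         seed = 1L) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 units")
  stats <- numeric(n_boot)
  redrawn <- 0L
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      repeat {
        v <- metric(scores[sample.int(n, n, replace = TRUE)])
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * n_boot) stop("metric undefined on almost all resamples")
      }
      stats[i] <- v
    }
  })
  if (redrawn > 0L) warnf("%d undefined resample(s) redrawn", redrawn)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha)))
  structure(c(lo = ci[1], hi = ci[2]), point = metric(scores), redrawn = redrawn)
}

#' One-sample t-test against a baseline
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with a two-sided p-value from the t
#' distribution with `n - 1` degrees of freedom.
#'
#' @param values numeric sample (n >= 2, positive variance).
#' @param mu0 baseline value, default 0.5.
#' @return named vector `c(t, p)`.
#' @export
one_sample_t <- function(values, mu0 = 0.5) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  c(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with multiclass
#' marginals.
#'
#' @param gold,pred equal-length label vectors.
#' @return scalar kappa.
#' @export
cohen_kappa <- function(gold, pred) {
  cm <- unclass(confusion_matrix(gold, pred))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("chance agreement p_e = 1; kappa undefined")
  (po - pe) / (1 - pe)
}

#' Matthews correlation coefficient (multiclass)
#'
#' Generalised MCC in the covariance form
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' where `c` is total correct, `s` total count, `p_k`/`t_k` the predicted /
#' true marginals. A zero-variance marginal yields 0 with a warning
#' (convention).
#'
#' @param gold,pred equal-length label vectors.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(gold, pred) {
  cm <- unclass(confusion_matrix(gold, pred))
  s <- sum(cm); correct <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  denom2 <- (s^2 - sum(pk^2)) * (s^2 - sum(tk^2))
  if (denom2 <= 0) {
    warnf("zero-variance marginal; MCC reported as 0")
    return(0)
  }
  (correct * s - sum(pk * tk)) / sqrt(denom2)
}

#' Exact McNemar test on paired correctness
#'
#' Counts discordant pairs (`b` = items only system A got right, `c` = only
#' system B) and tests `b ~ Binomial(b + c, 1/2)` exactly. The default
#' two-sided p-value is `min(1, 2 * min(tails))`; a one-sided mode tests the
#' smaller tail only. No discordant pairs gives p = 1 with a warning.
#'
#' @param a_correct,b_correct equal-length logical vectors.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return named vector `c(b, c, p)`.
#' @export
mcnemar_exact <- function(a_correct, b_correct,
                          alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a_correct) == length(b_correct))
  a_correct <- as.logical(a_correct); b_correct <- as.logical(b_correct)
  b <- sum(a_correct & !b_correct)
  cc <- sum(!a_correct & b_correct)
  n <- b + cc
  if (n == 0L) {
    warnf("no discordant pairs; p = 1")
    return(c(b = b, c = cc, p = 1))
  }
  lo <- stats::pbinom(min(b, cc), n, 0.5)
  p <- if (alternative == "two.sided") min(1, 2 * lo) else lo
  c(b = b, c = cc, p = p)
}

#' Paired sign-flip permutation test on accuracy difference
#'
#' The statistic is the accuracy difference `mean(a) - mean(b)`. The null
#' distribution swaps each item's A/B outcomes independently with
#' probability 1/2 (equivalently flips the sign of its paired difference);
#' the p-value is the raw proportion of permuted `|diff|` at or above the
#' observed `|diff|` (`smooth = TRUE` applies add-one smoothing).
#' Deterministic given `seed`.
#'
#' @param a_correct,b_correct equal-length logical (or 0/1) vectors.
#' @param n_perm number of permutations, default 10000 (warns below 100).
#' @param seed RNG seed.
#' @param smooth add-one smoothing `(r + 1)/(n_perm + 1)` if TRUE.
#' @return scalar p-value.
#' @export
permutation_test <- function(a_correct, b_correct, n_perm = 10000L, seed = 1L,
                             smooth = FALSE) {
  stopifnot(length(a_correct) == length(b_correct))
  if (n_perm < 100L) warnf("n_perm = %d is very small", n_perm)
  d <- as.numeric(a_correct) - as.numeric(b_correct)
  obs <- abs(mean(d))
  n <- length(d)
  r <- with_seed(seed, {
    hits <- 0L
    # vectorised in blocks to bound memory
    block <- max(1L, min(n_perm, as.integer(2e6 / n)))
    done <- 0L
    while (done < n_perm) {
      m <- min(block, n_perm - done)
      S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
      hits <- hits + sum(abs(S %*% d) / n >= obs - 1e-15)
      done <- done + m
    }
    hits
  })
  if (smooth) (r + 1) / (n_perm + 1) else r / n_perm
}

#' Paired comparison of two systems
#'
#' Bundles accuracies, the accuracy difference (computed from integer
#' correct counts), the exact McNemar test, the permutation test, and
#' per-system agreement measures (kappa, MCC) for two prediction vectors
#' against a shared gold standard.
#'
#' @param gold,preds_a,preds_b equal-length label vectors.
#' @param n_perm permutation iterations.
#' @param seed RNG seed for the permutation test.
#' @param mcnemar_alternative passed to [mcnemar_exact()].
#' @return object of class `system_comparison`.
#' @export
compare_systems <- function(gold, preds_a, preds_b, n_perm = 10000L, seed = 1L,
                            mcnemar_alternative = "two.sided") {
  if (length(gold) != length(preds_a) || length(gold) != length(preds_b))
    stop("gold and predictions differ in length")
  a_ok <- as.character(preds_a) == as.character(gold)
  b_ok <- as.character(preds_b) == as.character(gold)
  n <- length(gold)
  mc <- mcnemar_exact(a_ok, b_ok, alternative = mcnemar_alternative)
  structure(list(
    n = n,
    correct_a = sum(a_ok), correct_b = sum(b_ok),
    accuracy_a = sum(a_ok) / n, accuracy_b = sum(b_ok) / n,
    accuracy_difference = (sum(a_ok) - sum(b_ok)) / n,
    mcnemar = mc,
    permutation_p = permutation_test(a_ok, b_ok, n_perm = n_perm, seed = seed),
    kappa_a = cohen_kappa(gold, preds_a), kappa_b = cohen_kappa(gold, preds_b),
    mcc_a = mcc(gold, preds_a), mcc_b = mcc(gold, preds_b)),
    class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  cat(sprintf("Paired system comparison (N = %d)\n", x$n))
  cat(sprintf("  accuracy A: %.4f (%d/%d)   accuracy B: %.4f (%d/%d)\n",
              x$accuracy_a, x$correct_a, x$n, x$accuracy_b, x$correct_b, x$n))
  cat(sprintf("  accuracy difference: %.4f\n", x$accuracy_difference))
  cat(sprintf("  McNemar exact: b=%d c=%d p=%.4g   permutation p=%.4g\n",
              x$mcnemar["b"], x$mcnemar["c"], x$mcnemar["p"], x$permutation_p))
  cat(sprintf("  kappa A/B: %.4f/%.4f   MCC A/B: %.4f/%.4f\n",
              x$kappa_a, x$kappa_b, x$mcc_a, x$mcc_b))
  invisible(x)
}

#' Coding evaluation for one system
#'
#' Accuracy, macro precision/recall/F1 over the union label space, kappa and
#' MCC for predicted codes against gold codes. Formatted at 4 decimals by
#' the print method, the convention for coding tables.
#'
#' @param gold,pred equal-length code vectors.
#' @return object of class `coding_eval`.
#' @export
evaluate_codes <- function(gold, pred) {
  cm <- confusion_matrix(gold, pred)
  pr <- suppressWarnings(prf(cm))
  structure(list(n = length(gold), accuracy = pr$accuracy, macro = pr$macro,
                 kappa = cohen_kappa(gold, pred), mcc = mcc(gold, pred),
                 confusion = cm),
            class = "coding_eval")
}

#' @export
print.coding_eval <- function(x, ...) {
  cat(sprintf("Coding evaluation (N = %d): accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f, kappa %.4f, MCC %.4f\n",
              x$n, x$accuracy, x$macro["precision"], x$macro["recall"],
              x$macro["f1"], x$kappa, x$mcc))
  invisible(x)
}
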