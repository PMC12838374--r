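test_that("precision/recall/F1 reproduce printed-table arithmetic", {
  # diagonal matrix: everything 1
  cm <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"))
  pr <- prf(cm)
  expect_true(all(pr$per_label[c("precision", "recall", "f1")] == 1))
  expect_equal(pr$accuracy, 1)
  # harmonic mean of P = 0.97, R = 0.90 rounds to 0.93
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.97, 0.90), 2), 0.93)
  # zero-denominator labels report 0 with a warning
  cm0 <- confusion_matrix(c("a", "a"), c("b", "b"), labels = c("a", "b"))
  expect_warning(pr0 <- prf(cm0), "zero-denominator")
  expect_equal(pr0$per_label$recall[pr0$per_label$label == "a"], 0)
})

test_that("prf and error_rates agree with the counting oracle", {
  set.seed(13)
  for (i in 1:60) {
    n_lab <- sample(2:7, 1)
    labs <- LETTERS[1:n_lab]
    v <- random_labels(n_lab, sample(10:50, 1), labs)
    cm <- confusion_matrix(v$gold, v$pred, labels = labs)
    pr <- suppressWarnings(prf(cm))
    er <- error_rates(cm)
    oracle <- count_oracle(v$gold, v$pred, labs)
    for (l in labs) {
      row <- pr$per_label[pr$per_label$label == l, ]
      expect_equal(row$precision, oracle[[l]]$precision)
      expect_equal(row$recall, oracle[[l]]$recall)
      expect_equal(row$f1, oracle[[l]]$f1)
      erow <- er[er$label == l, ]
      expect_equal(erow$absolute, oracle[[l]]$absolute)
      if (oracle[[l]]$support > 0)
        expect_equal(erow$relative, oracle[[l]]$absolute / oracle[[l]]$support)
      else expect_true(is.na(erow$relative))
    }
    expect_equal(pr$accuracy, mean(v$gold == v$pred))
  }
})

test_that("error_rates handles diagonal and single-label cases", {
  cm <- confusion_matrix(rep("a", 20), c(rep("a", 18), "b", "b"),
                         labels = c("a", "b"))
  er <- error_rates(cm)
  expect_equal(er$absolute[er$label == "a"], 2)
  expect_equal(er$relative[er$label == "a"], 0.10)
  expect_true(is.na(er$relative[er$label == "b"]))
})

test_that("bootstrap percentile CI behaves on degenerate and typical samples", {
  expect_equal(unname(bootstrap_ci(rep(0.9, 10), n_boot = 200, seed = 1)),
               c(0.9, 0.9), ignore_attr = TRUE)
  x <- c(0.8, 0.85, 0.9, 0.95, 1)
  ci <- bootstrap_ci(x, mean, n_boot = 2000, seed = 2)
  expect_lte(ci["lo"], mean(x)); expect_gte(ci["hi"], mean(x))
  expect_identical(ci, bootstrap_ci(x, mean, n_boot = 2000, seed = 2))
  expect_error(bootstrap_ci(1), "at least 2")
  # undefined resamples are redrawn and warned about
  y <- c(0, 0, 1)
  weird <- function(v) if (sum(v) == 0) NaN else mean(v)
  expect_warning(bootstrap_ci(y, weird, n_boot = 500, seed = 3), "redrawn")
})

test_that("one-sample t reproduces the closed form", {
  expect_equal(unname(one_sample_t(c(0.4, 0.6), mu0 = 0.5)["t"]), 0)
  expect_equal(unname(one_sample_t(c(0.4, 0.6), mu0 = 0.5)["p"]), 1)
  # hand computation: mean .956667, sd .049329, t = 16.03
  t3 <- one_sample_t(c(0.98, 0.99, 0.90), mu0 = 0.5)
  expect_equal(unname(t3["t"]), 16.034, tolerance = 1e-3)
  expect_lt(t3["p"], 0.01)
  # |t| grows with n at fixed mean/sd
  x <- c(0.6, 0.7, 0.8)
  expect_gt(abs(one_sample_t(rep(x, 4))["t"]), abs(one_sample_t(x)["t"]))
  expect_error(one_sample_t(rep(0.7, 5)), "degenerate")
})

test_that("Cohen's kappa matches hand computations", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # constant prediction against balanced binary gold is chance level
  expect_equal(cohen_kappa(c("a", "a", "b", "b"), rep("a", 4)), 0)
  # p_o = 0.75, p_e = 0.5 -> kappa 0.5
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.5)
})

test_that("multiclass MCC matches the binary formula and conventions", {
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mcc(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  # TP=1 FN=1 FP=0 TN=2 -> 2/sqrt(12)
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 0, 0, 0)), 2 / sqrt(12))
  expect_warning(z <- mcc(c("a", "a"), c("a", "a")), "zero-variance")
  expect_equal(z, 0)
})

test_that("kappa and MCC agree with independent reference formulas on random data", {
  set.seed(7)
  for (i in 1:40) {
    v <- random_labels(sample(2:5, 1), 40)
    cm <- table(v$gold, v$pred)
    n <- sum(cm); po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    if (pe < 1)
      expect_equal(cohen_kappa(v$gold, v$pred), (po - pe) / (1 - pe))
    s <- n; cc <- sum(diag(cm)); tk <- rowSums(cm); pk <- colSums(cm)
    d2 <- (s^2 - sum(pk^2)) * (s^2 - sum(tk^2))
    if (d2 > 0)
      expect_equal(mcc(v$gold, v$pred), (cc * s - sum(pk * tk)) / sqrt(d2))
  }
})

test_that("exact McNemar counts discordance and computes exact tails", {
  same <- rep(TRUE, 10)
  expect_warning(r0 <- mcnemar_exact(same, same), "no discordant")
  expect_equal(unname(r0["p"]), 1)
  # b = 0, c = 2: two-sided p = 2 * P(X <= 0 | n = 2) = 0.5
  a <- c(TRUE, TRUE, TRUE); b <- c(TRUE, FALSE, FALSE)
  r <- mcnemar_exact(b, a)
  expect_equal(unname(r["b"]), 0); expect_equal(unname(r["c"]), 2)
  expect_equal(unname(r["p"]), 0.5)
  # symmetric discordance: p = 1
  a2 <- c(rep(TRUE, 3), rep(FALSE, 3)); b2 <- c(rep(FALSE, 3), rep(TRUE, 3))
  expect_equal(unname(mcnemar_exact(a2, b2)["p"]), 1)
  # one-sided is half the symmetric two-sided tail
  expect_equal(unname(mcnemar_exact(b, a, alternative = "one.sided")["p"]), 0.25)
  # cross-check against the exact binomial test
  set.seed(5)
  for (i in 1:20) {
    x <- runif(30) < 0.6; y <- runif(30) < 0.6
    got <- mcnemar_exact(x, y)
    bb <- got["b"]; cc <- got["c"]
    if (bb + cc > 0) {
      ref <- min(1, 2 * min(pbinom(min(bb, cc), bb + cc, 0.5),
                            pbinom(max(bb, cc) - 1, bb + cc, 0.5, lower.tail = FALSE) +
                              dbinom(max(bb, cc), bb + cc, 0.5)))
      expect_equal(unname(got["p"]), unname(ref))
    }
  }
})

test_that("permutation test is symmetric, deterministic and sane", {
  a <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(permutation_test(a, a, n_perm = 500, seed = 1), 1)
  b <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  p1 <- permutation_test(a, b, n_perm = 2000, seed = 2)
  expect_identical(p1, permutation_test(a, b, n_perm = 2000, seed = 2))
  expect_equal(p1, permutation_test(b, a, n_perm = 2000, seed = 2))
  expect_warning(permutation_test(a, b, n_perm = 50, seed = 1), "small")
  # smoothing bounds p away from zero
  expect_gt(permutation_test(rep(TRUE, 20), rep(FALSE, 20), n_perm = 100,
                             seed = 1, smooth = TRUE), 0)
})

test_that("compare_systems assembles the paired report from counts", {
  gold <- rep(c("x", "y"), each = 5)
  cmp0 <- suppressWarnings(compare_systems(gold, gold, gold, n_perm = 200, seed = 1))
  expect_equal(cmp0$accuracy_difference, 0)
  expect_equal(unname(cmp0$mcnemar["p"]), 1)
  expect_equal(cmp0$permutation_p, 1)
  # bit-identical under a fixed seed
  a <- c(gold[1:8], "x", "x"); b <- c(gold[1:6], "y", "y", "x", "x")
  c1 <- suppressWarnings(compare_systems(gold, a, b, n_perm = 1000, seed = 9))
  c2 <- suppressWarnings(compare_systems(gold, a, b, n_perm = 1000, seed = 9))
  expect_identical(c1, c2)
  expect_error(compare_systems(gold, a[-1], b), "length")
})

test_that("coding evaluation bundles accuracy, macro metrics and agreement", {
  gold <- c("1", "2", "2", "3")
  pred <- c("1", "2", "3", "3")
  ev <- evaluate_codes(gold, pred)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$kappa, cohen_kappa(gold, pred))
  expect_equal(ev$mcc, mcc(gold, pred))
  expect_equal(sum(unclass(ev$confusion)), 4)
})
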