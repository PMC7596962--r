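# Brute-force oracles for every ranking metric, plus the closed-form
# statistics the reporting layer relies on.

auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

auprc_bruteforce <- function(scores, labels) {
  # walk the PR curve over distinct thresholds in decreasing score order
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  area <- 0; prev_rec <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("auroc equals the exhaustive pairwise oracle, ties half-counted", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc endpoints: perfect ranking gives 1, all-tied scores give 0.5", {
  labels <- rep(c(0, 1), each = 10)
  expect_identical(auroc(seq_len(20), labels), 1)
  expect_identical(auroc(rep(0.3, 20), labels), 0.5)
  expect_error(auroc(1:5, rep(1, 5)), "both classes")
})

test_that("auprc matches a brute-force step-curve walk and handles ties", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))
    expect_equal(auprc(scores, labels), auprc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
  expect_identical(auprc(1:10, rep(c(0, 1), each = 5)), 1)
  expect_error(auprc(1:4, rep(0, 4)), "no positive")
})

test_that("auprc of uninformative scores approaches the prevalence", {
  set.seed(303)
  n <- 5000; prev <- 0.15
  labels <- rbinom(n, 1, prev)
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - prev), 0.03)
})

test_that("f1 reproduces confusion-matrix arithmetic and its conventions", {
  # TP=2, FP=1, FN=1 -> precision 2/3, recall 2/3, F1 = 2/3
  scores <- c(0.9, 0.8, 0.7, 0.2)
  labels <- c(1, 1, 0, 1)
  expect_equal(f1_at_threshold(scores, labels), 2 / 3, tolerance = 1e-12)
  expect_identical(f1_at_threshold(c(0.9, 0.1), c(1, 0)), 1)
  expect_identical(f1_at_threshold(c(0.1, 0.2), c(1, 0)), 0)
  set.seed(404)
  for (i in 1:25) {
    n <- 50
    scores <- runif(n); labels <- rbinom(n, 1, 0.4)
    pred <- as.integer(scores >= 0.5)
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    expected <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(f1_at_threshold(scores, labels), expected, tolerance = 1e-12)
  }
})

test_that("metrics are equivariant under sample permutation", {
  set.seed(505)
  scores <- runif(60); labels <- rbinom(60, 1, 0.3)
  labels[1:2] <- c(0, 1)
  perm <- sample(60)
  for (f in list(auroc, auprc, f1_at_threshold)) {
    expect_equal(f(scores, labels), f(scores[perm], labels[perm]))
  }
})

test_that("t confidence interval matches hand computation", {
  v <- c(0.80, 0.82, 0.84, 0.80, 0.84)
  ci <- t_confidence_interval(v)
  m <- mean(v); s <- sd(v)
  expect_equal(unname(ci[1]), m - qt(0.975, 4) * s / sqrt(5), tolerance = 1e-9)
  expect_equal(unname(ci[2]), m + qt(0.975, 4) * s / sqrt(5), tolerance = 1e-9)
  # constant values collapse to a zero-width interval
  expect_equal(unname(t_confidence_interval(rep(0.7, 4))), c(0.7, 0.7))
  expect_error(t_confidence_interval(0.5), "at least 2")
  # width shrinks as 1/sqrt(n) on replicated data
  base <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  w5 <- diff(t_confidence_interval(base))
  w20 <- diff(t_confidence_interval(rep(base, 4)))
  expect_lt(w20, w5 / 1.8)
})

test_that("p-value matrix is symmetric, unit-diagonal, and matches a
           hand-coded Welch test", {
  a <- rep(0.9, 5)
  b <- c(0.60, 0.61, 0.59, 0.60, 0.60)
  cc <- c(0.89, 0.91, 0.90, 0.88, 0.92)
  m <- pvalue_matrix(list(A = a, B = b, C = cc))
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(unname(diag(m)), rep(1, 3))
  expect_identical(m, t(m))
  expect_lt(m["A", "B"], 0.001)
  # closed-form Welch t for the (B, C) pair
  welch <- function(x, y) {
    tstat <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
    df <- (var(x) / length(x) + var(y) / length(y))^2 /
      ((var(x) / length(x))^2 / (length(x) - 1) +
         (var(y) / length(y))^2 / (length(y) - 1))
    2 * pt(-abs(tstat), df)
  }
  expect_equal(m["B", "C"], welch(b, cc), tolerance = 1e-9)
  # zero-variance conventions
  expect_identical(pvalue_matrix(list(x = rep(0.5, 3), y = rep(0.5, 3)))[1, 2], 1)
  expect_identical(pvalue_matrix(list(x = rep(0.5, 3), y = rep(0.6, 3)))[1, 2], 0)
  expect_error(pvalue_matrix(list(x = 1:3, y = 1:4)), "same run count")
})
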