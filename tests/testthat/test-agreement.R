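test_that("ibiAgreement matches hand arithmetic and direct recomputation", {
  same <- ibiAgreement(c(800, 900, 1000), c(800, 900, 1000))
  expect_identical(same$meanError, 0)
  expect_identical(c(same$loaLow, same$loaHigh), c(0, 0))

  r <- ibiAgreement(c(800, 1000), c(792, 990))
  expect_equal(r$absMeanError, 9)
  expect_equal(r$mape, 1.0)

  set.seed(1)
  for (i in 1:25) {
    ref <- stats::runif(50, 500, 1200)
    test <- ref + stats::rnorm(50, 0, 20)
    a <- ibiAgreement(ref, test)
    d <- ref - test
    expect_equal(a$meanError, sum(d) / 50)
    expect_equal(a$absMeanError, sum(abs(d)) / 50)
    expect_equal(a$mape, 100 * sum(abs(d) / ref) / 50)
    expect_equal(a$loaHigh - a$loaLow, 2 * 1.96 * stats::sd(d))
    expect_lte(abs(a$meanError), a$absMeanError)
    # MAPE is invariant under common rescaling
    expect_equal(ibiAgreement(2 * ref, 2 * test)$mape, a$mape)
  }
  expect_error(ibiAgreement(c(0, 800), c(10, 800)), "zero")
})

test_that("classifierMetrics agrees with first-principles recomputation", {
  expect_equal(unname(classifierMetrics(diag(5) * 7)),
               c(1, 1, 1))
  expect_equal(unname(classifierMetrics(matrix(3, 4, 4))),
               c(0.25, 0.25, 0))

  oracle <- function(cm) {
    # independent recomputation via per-class one-vs-rest tallies
    K <- nrow(cm); tot <- sum(cm)
    acc <- sum(vapply(1:K, function(i) cm[i, i], 1)) / tot
    f1 <- numeric(K); w <- numeric(K)
    for (i in 1:K) {
      tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
      p <- if (tp + fp) tp / (tp + fp) else 0
      r <- if (tp + fn) tp / (tp + fn) else 0
      f1[i] <- if (p + r) 2 * p * r / (p + r) else 0
      w[i] <- sum(cm[i, ])
    }
    po <- acc
    pe <- sum(vapply(1:K, function(i) sum(cm[i, ]) * sum(cm[, i]), 1)) / tot^2
    c(acc, sum(f1 * w) / tot, (po - pe) / (1 - pe))
  }
  set.seed(2)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    cm <- matrix(stats::rpois(K * K, 5) + ifelse(diag(K) > 0, 20, 0), K, K)
    m <- classifierMetrics(cm)
    expect_equal(unname(m), oracle(cm))
    expect_lte(m[["kappa"]], m[["accuracy"]] + 1e-12)
    # kappa is 1 iff the off-diagonal is empty
    expect_identical(unname(abs(m[["kappa"]] - 1) < 1e-12),
                     sum(cm) == sum(diag(cm)))
  }
})

test_that("McNemar statistics match their closed forms and stats::mcnemar.test", {
  sym <- mcnemarTest(10, 10)
  expect_identical(c(sym$statistic, sym$p), c(0, 1))
  zero <- mcnemarTest(0, 0)
  expect_identical(c(zero$statistic, zero$p), c(0, 1))

  set.seed(3)
  for (i in 1:20) {
    b <- sample(0:60, 1); c <- sample(0:60, 1)
    if (b + c == 0) next
    r <- mcnemarTest(b, c)
    expect_equal(r$statistic, (b - c)^2 / (b + c))
    tab <- matrix(c(30, b, c, 40), 2, 2, byrow = TRUE)
    ref <- stats::mcnemar.test(tab, correct = FALSE)
    expect_equal(r$statistic, unname(ref$statistic))
    expect_equal(r$p, unname(ref$p.value))
    refC <- stats::mcnemar.test(tab, correct = TRUE)
    rc <- mcnemarTest(b, c, method = "chi2_corrected")
    expect_equal(rc$statistic, unname(refC$statistic))
    ex <- mcnemarTest(b, c, method = "exact")
    expect_gte(ex$p, 0); expect_lte(ex$p, 1)
    expect_equal(ex$p, min(1, unname(stats::binom.test(b, b + c)$p.value)))
    # invariant to the concordant cells
    tab2 <- matrix(c(999, b, c, 1), 2, 2, byrow = TRUE)
    expect_equal(mcnemarTest(tab2)$statistic, r$statistic)
  }
})

test_that("word error rate handles the canonical cases", {
  expect_identical(wordErrorRate("kids are talking by the door",
                                 "Kids are talking by the door")$wer, 0)
  r <- wordErrorRate("Kids are talking by the door.",
                     "kids are walking by door")
  expect_identical(c(r$S, r$D, r$I, r$N), c(1L, 1L, 0L, 6L))
  expect_equal(r$wer, 2 / 6)

  empty <- wordErrorRate(c("a", "b", "c"), character(0), tokenize = FALSE)
  expect_identical(c(empty$wer, empty$D), c(1, 3))
  expect_error(wordErrorRate("", "something"), "empty reference")
})

test_that("word-level edit distance agrees with the C-level oracle on random pairs", {
  vocab <- letters[1:5]
  set.seed(4)
  for (i in 1:200) {
    ref <- sample(vocab, sample(1:8, 1), replace = TRUE)
    hyp <- sample(vocab, sample(0:8, 1), replace = TRUE)
    r <- wordErrorRate(ref, hyp, tokenize = FALSE)
    d <- utils::adist(paste(ref, collapse = ""), paste(hyp, collapse = ""))
    expect_identical(r$S + r$D + r$I, as.integer(d))
    expect_equal(r$wer, as.integer(d) / length(ref))
  }
})

test_that("relative improvement reproduces the language-model gains", {
  expect_equal(relativeImprovement(5.75, 4.16), 27.65217, tolerance = 1e-5)
  expect_equal(relativeImprovement(3.58, 2.73), 23.74302, tolerance = 1e-5)
  expect_identical(relativeImprovement(4, 4), 0)
  expect_error(relativeImprovement(0, 1), "positive")
})

test_that("pairedT matches the textbook formula and stats::t.test", {
  expect_error(pairedT(c(2, 2, 2)), "zero variance")
  r <- pairedT(c(1, -1))
  expect_identical(c(r$t, r$p), c(0, 0.5))

  set.seed(5)
  d <- stats::rnorm(16, 0.4, 0.8)
  one <- pairedT(d, tail = "one")
  ref <- stats::t.test(d, alternative = "greater")
  expect_equal(one$t, unname(ref$statistic))
  expect_equal(one$p, ref$p.value)
  two <- pairedT(d, tail = "two")
  expect_equal(two$p, stats::t.test(d)$p.value)
})
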