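test_that("gravity is removed from the dominant axis with matching sign", {
  n <- 700
  set.seed(1)
  still <- cbind(stats::rnorm(n, 0, 0.05), stats::rnorm(n, 0, 0.05),
                 9.8 + stats::rnorm(n, 0, 0.05))
  out <- removeGravity(still)
  expect_true(all(abs(colMeans(out)) < 0.05))
  flipped <- still; flipped[, 3] <- -flipped[, 3]
  expect_true(all(abs(colMeans(removeGravity(flipped))) < 0.05))

  walking <- still
  walking[, 3] <- walking[, 3] + 2 * sin(2 * pi * 2 * (1:n) / 70)
  expect_true(all(abs(colMeans(removeGravity(walking))) < 0.2))
})

test_that("resampleDynamic emits exactly 2100 samples per 30 s interval", {
  set.seed(2)
  for (nIn in c(1950, 2250)) {
    tm <- sort(stats::runif(nIn, 0, 30 - 1e-6))
    out <- resampleDynamic(tm, stats::rnorm(nIn))
    expect_identical(nrow(out$values), 2100L)
    expect_false(any(out$flagged))
  }
  sparse <- resampleDynamic(seq(0, 29.9, length.out = 900),
                            stats::rnorm(900))
  expect_true(sparse$flagged[1])
})

test_that("resampling a jittered 1 Hz sine keeps RMS error under 1% of amplitude", {
  set.seed(3)
  tm <- cumsum(1 / stats::runif(2400, 65, 75))
  tm <- tm - tm[1]
  tm <- tm[tm < 30]
  out <- resampleDynamic(tm, sin(2 * pi * tm))
  err <- sqrt(mean((out$values[, 1] - sin(2 * pi * out$time))^2))
  expect_lt(err, 0.01)
})

test_that("the rotation rule fires on sustained single-axis rotation only", {
  # constant 72 deg/s for 5 s integrates to 360 degrees
  g1 <- cbind(numeric(350), numeric(350), rep(72, 350))
  expect_true(detectRotation(g1))
  set.seed(4)
  noise <- matrix(stats::rnorm(350 * 3, 0, 20), ncol = 3)
  expect_false(detectRotation(noise))
  # generator rotation bouts integrate >= 360 degrees per 6 s window
  g <- genActivity(data.frame(activity = "rotate", duration_s = 60),
                   seed = 5)
  rs <- resampleDynamic(g$time, g$gyro)
  expect_true(all(detectRotation(rs$values, windowS = 6)))
})

test_that("rotation vs other activities separates at over 99% on a mixed corpus", {
  plan <- data.frame(activity = rep(c("rotate", "walk", "upright", "glide"),
                                    times = 5),
                     duration_s = 30)
  g <- genActivity(plan, seed = 6)
  rs <- resampleDynamic(g$time, g$gyro)
  labGrid <- g$labels[vapply(rs$time, function(t)
    which.min(abs(g$time - t)), 1L)]
  wl <- 70 * 6
  nW <- floor(nrow(rs$values) / wl)
  truth <- pred <- logical(nW)
  for (k in seq_len(nW)) {
    sel <- ((k - 1) * wl + 1):(k * wl)
    ls <- unique(labGrid[sel])
    if (length(ls) != 1) { truth[k] <- NA; next }
    truth[k] <- ls == "rotate"
  }
  pred <- detectRotation(rs$values, windowS = 6)
  keep <- !is.na(truth)
  expect_gt(mean(pred[keep] == truth[keep]), 0.99)
})

test_that("a separable four-activity corpus classifies above 0.95 accuracy", {
  corp <- genActivityCorpus(counts = c(upright = 80, walk = 40, glide = 40,
                                       squat = 40), seed = 8)
  res <- classifyActivities(corp$features, corp$label, nSplits = 3,
                            seed = 8)
  expect_gte(res$pooled[["accuracy"]], 0.95)
  # metric relations on the pooled matrix
  m <- classifierMetrics(res$confusion)
  expect_lte(m[["kappa"]], m[["accuracy"]])
  expect_error(classifyActivities(corp$features,
                                  rep("upright", nrow(corp$features))),
               "two classes")
})

test_that("zero-noise activity classes are perfectly separable", {
  corp <- genActivityCorpus(counts = c(upright = 20, walk = 12, glide = 12,
                                       squat = 12), seed = 9, noiseSd = 0)
  res <- classifyActivities(corp$features, corp$label, nSplits = 2,
                            seed = 9)
  expect_identical(res$pooled[["accuracy"]], 1)
})
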