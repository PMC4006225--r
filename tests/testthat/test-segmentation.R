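test_that("the interval score has its closed forms", {
  expect_equal(scoreInterval(1.2, 0.2, 1, 1), 6.0)
  expect_equal(scoreInterval(rep(-1, 4), 0.5, 1, 4), 4.0)
  expect_equal(scoreInterval(rep(c(0.7, -0.7), 5), 0.1, 1, 10), 0)
})

test_that("the derivative-spread sigma estimator recovers known noise", {
  set.seed(21)
  x <- rnorm(5000, 0, 0.28)
  expect_equal(estimateSigma(x), 0.28, tolerance = 0.05)
  # robust to a CNV shift occupying 10% of probes
  x[2001:2500] <- x[2001:2500] - 1
  expect_equal(estimateSigma(x), 0.28, tolerance = 0.05)
})

test_that("an embedded deletion is called with exact probe bounds", {
  ratio <- rep(0, 20); ratio[8:13] <- -1
  series <- probeSeries(ratio)
  calls <- callAberrations(series, sigma = 0.2, threshold = 6, minProbes = 3)
  expect_equal(length(calls), 1L)
  expect_equal(calls$firstProbe, 8L)
  expect_equal(calls$lastProbe, 13L)
  expect_equal(calls$direction, "loss")
  expect_equal(calls$probeCount, 6L)
  expect_equal(start(calls), start(series)[8])
  expect_equal(end(calls), end(series)[13])
  expect_equal(calls$score, 6 * 5 / sqrt(6), tolerance = 1e-9)
  expect_equal(calls$copies, 1L)
  # all-zero series: nothing
  expect_equal(length(callAberrations(probeSeries(rep(0, 20)), sigma = 0.2)),
               0L)
})

test_that("the minimum-probe rule gates short spikes", {
  ratio <- rep(0, 15); ratio[7:8] <- -1
  series <- probeSeries(ratio)
  # S = 2*5/sqrt(2) = 7.07 >= 6 but only 2 probes
  expect_equal(length(callAberrations(series, sigma = 0.2, minProbes = 3)), 0L)
  got <- callAberrations(series, sigma = 0.2, minProbes = 1)
  expect_equal(length(got), 1L)
  expect_equal(got$probeCount, 2L)
})

test_that("exhaustive search matches its definition on small cases", {
  # unique spike: returns the spike span
  x <- rep(0, 30); x[12:17] <- 1
  b <- exhaustiveBestInterval(x, 0.5, minProbes = 1)
  expect_equal(c(b$i, b$j), c(12, 17))
  # constant positive series: score grows as sqrt(n), full range wins
  b2 <- exhaustiveBestInterval(rep(0.4, 25), 1, minProbes = 1)
  expect_equal(c(b2$i, b2$j), c(1, 25))
  expect_equal(b2$score, 0.4 * sqrt(25))
  # direct double-loop agreement on a random series
  set.seed(31)
  x3 <- rnorm(40)
  b3 <- exhaustiveBestInterval(x3, 1, minProbes = 2)
  brute <- -Inf
  for (i in 1:39) for (j in (i + 1):40) {
    s <- abs(sum(x3[i:j])) / sqrt(j - i + 1)
    if (s > brute) brute <- s
  }
  expect_equal(b3$score, brute)
})

test_that("greedy top call equals the exhaustive optimum (property)", {
  set.seed(41)
  hits <- 0L
  for (rep in 1:60) {
    n <- sample(20:120, 1)
    x <- rnorm(n, 0, 1)
    if (runif(1) < 0.7) {   # plant a shifted window most of the time
      w <- sample(3:10, 1); s0 <- sample(n - w, 1)
      x[s0:(s0 + w)] <- x[s0:(s0 + w)] + sample(c(-1, 1), 1) * runif(1, 2, 4)
    }
    series <- probeSeries(x)
    calls <- callAberrations(series, sigma = 1, threshold = 6, minProbes = 3)
    best <- exhaustiveBestInterval(x, 1, minProbes = 3)
    if (best$score >= 6) {
      hits <- hits + 1L
      top <- calls[which.max(calls$score)]
      expect_equal(top$firstProbe, best$i)
      expect_equal(top$lastProbe, best$j)
      expect_equal(top$score, best$score, tolerance = 1e-12)
    } else {
      expect_equal(length(calls), 0L)
    }
  }
  expect_gt(hits, 10L)  # the property was actually exercised
})

test_that("calls never overlap and thresholds act monotonically", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(50:150, 1)
    x <- rnorm(n)
    k <- sample(3:8, 1); s0 <- sample(n - k, 1)
    x[s0:(s0 + k)] <- x[s0:(s0 + k)] - runif(1, 2, 5)
    series <- probeSeries(x)
    lo <- callAberrations(series, sigma = 1, threshold = 4, minProbes = 3)
    hi <- callAberrations(series, sigma = 1, threshold = 7, minProbes = 3)
    mp <- callAberrations(series, sigma = 1, threshold = 4, minProbes = 6)
    expect_lte(length(hi), length(lo))
    expect_lte(length(mp), length(lo))
    if (length(lo) > 1L)
      expect_equal(sum(countOverlaps(lo, lo) > 1L), 0L)
    # probe conservation: call spans stay within the series
    if (length(lo))
      expect_true(all(start(lo) >= min(start(series)) &
                        end(lo) <= max(end(series))))
  }
})

test_that("non-finite ratios are dropped with a note", {
  ratio <- rep(0, 20); ratio[8:13] <- -1; ratio[2] <- NA; ratio[19] <- Inf
  series <- probeSeries(ratio)
  expect_message(calls <- callAberrations(series, sigma = 0.2), "non-finite")
  expect_equal(length(calls), 1L)
})

test_that("copy states map log2 shifts to the reporting dialect", {
  cs <- estimateCopyState(c(-1, 1, -0.4, 0.48, 1.585))
  expect_equal(cs$copies, c(1L, 4L, 1L, 2L, 6L))
  expect_equal(cs$copiesHigh, c(NA, NA, 2L, 3L, NA))
  expect_equal(cs$kind,
               c("loss", "gain", "mosaic", "mosaic", "amplification"))
  # sex-aware reference: one-copy X gained to two
  expect_equal(estimateCopyState(1, reference = 1L)$copies, 2L)
  expect_equal(referenceCopies("XY")[["X"]], 1L)
  expect_equal(referenceCopies("XX")[["Y"]], 0L)
})
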