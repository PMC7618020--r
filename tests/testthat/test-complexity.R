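# LZ76 parsing, binarization and the LZsum aggregation.

test_that("lz76 reproduces hand-checkable parsings", {
  expect_identical(lz76(rep(0L, 8)), 2L)
  expect_identical(lz76("01010101"), 3L)
  expect_identical(lz76("0"), 1L)
  expect_identical(lz76("1"), 1L)
  expect_error(lz76(integer(0)), "empty")
  expect_error(lz76(c(0L, 2L)), "alphabet")
})

test_that("lz76 agrees with the brute-force parser on random strings", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:60, 1)
    bits <- sample(0:1, n, replace = TRUE, prob = c(runif(1), 1))
    expect_identical(lz76(bits), bruteLZ76(bits))
  }
})

test_that("lz76 word count is monotone under prefix extension", {
  set.seed(7)
  for (rep in 1:20) {
    bits <- sample(0:1, 80, replace = TRUE)
    cuts <- sort(sample(2:80, 6))
    cs <- vapply(cuts, function(k) lz76(bits[seq_len(k)]), integer(1))
    expect_true(all(diff(cs) >= 0))
  }
})

test_that("normalized LZ separates constant, periodic and random signals", {
  n <- 1000
  constBits <- suppressWarnings(binarizeSignal(rep(1, n)))
  set.seed(3)
  block <- sample(0:1, 100, replace = TRUE)   # rich pattern, period 100
  periodic <- rep(block, n / 100)
  iid <- sample(0:1, n, replace = TRUE)
  vConst <- normalizeLZ(lz76(constBits), n)
  vPer <- normalizeLZ(lz76(periodic), n)
  vIid <- normalizeLZ(lz76(iid), n)
  expect_lt(vConst, vPer)
  expect_lt(vPer, vIid)
  expect_gt(vPer - vConst, 0.1)
  expect_gt(vIid - vPer, 0.1)
})

test_that("normalizeLZ applies the asymptotic n / log2(n) scale", {
  expect_equal(normalizeLZ(2, 16), 0.5)
  expect_error(normalizeLZ(2, 1), "n >= 2")
  # periodic 01 string stays tiny at n = 10^4
  expect_lt(normalizeLZ(lz76(rep(c(0L, 1L), 5000)), 10000), 0.05)
})

test_that("binarization follows the stated threshold rules", {
  expect_identical(binarizeSignal(c(1, 3, 2, 4), "signal-median"),
                   c(0L, 1L, 0L, 1L))
  expect_warning(z <- binarizeSignal(rep(2.5, 100)), "constant")
  expect_identical(z, integer(100))
  # amplitude-modulated tone: envelope symmetric about its mean
  tt <- (0:4999) / 1000
  x <- sin(2 * pi * 10 * tt) * (1 + 0.5 * sin(2 * pi * 0.5 * tt))
  frac <- mean(binarizeSignal(x, "hilbert-mean"))
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
})

test_that("binarization and LZsum are invariant to amplitude scaling", {
  set.seed(21)
  x <- rnorm(500)
  for (a in c(0.001, 3, 1e6)) {
    expect_identical(binarizeSignal(a * x, "hilbert-mean"),
                     binarizeSignal(x, "hilbert-mean"))
    expect_identical(binarizeSignal(a * x, "signal-median"),
                     binarizeSignal(x, "signal-median"))
  }
  ep <- matrix(rnorm(4 * 500), nrow = 4)
  cfg <- complexityConfig(nSubsampleChannels = 4, seed = 5)
  r1 <- withr::with_seed(1, lzsumEpoch(ep, cfg))
  r2 <- withr::with_seed(1, lzsumEpoch(7 * ep, cfg))
  expect_identical(r1$lzsum, r2$lzsum)
  expect_identical(r1$channelSubset, r2$channelSubset)
})

test_that("lzsumEpoch averages normalized complexities over the drawn subset", {
  # identical channels: mean equals the single-channel value
  set.seed(2)
  x <- rnorm(400)
  ep <- matrix(rep(x, each = 25), nrow = 25)
  r <- lzsumEpoch(ep, complexityConfig(seed = 1))
  single <- normalizeLZ(lz76(binarizeSignal(x)), 400)
  expect_equal(r$lzsum, single)
  expect_length(r$channelSubset, 25)
  # fewer channels than requested: all used, warning
  ep2 <- matrix(rnorm(3 * 400), nrow = 3)
  expect_warning(r2 <- lzsumEpoch(ep2, complexityConfig(seed = 1)),
                 "using all channels")
  expect_identical(r2$channelSubset, 1:3)
})

test_that("IID-noise epochs give normalized LZsum near 1", {
  set.seed(9)
  vals <- replicate(20, {
    ep <- matrix(rnorm(5 * 1000), nrow = 5)
    lzsumEpoch(ep, complexityConfig(nSubsampleChannels = 5,
                                    binarization = "signal-median"))$lzsum
  })
  expect_gt(mean(vals), 0.85)
  expect_lt(mean(vals), 1.15)
})

test_that("lzsumSubject averages kept epochs and is seed-reproducible", {
  set.seed(4)
  mats <- replicate(3, matrix(rnorm(30 * 500), nrow = 30), simplify = FALSE)
  es <- epochSetFromMatrices(mats, 125)
  cfg <- complexityConfig(seed = 99)
  r1 <- lzsumSubject(es, cfg)
  r2 <- lzsumSubject(es, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$lzsum, mean(r1$perEpoch$lzsum))
  # masking epochs changes the aggregate to the kept mean
  es2 <- es
  es2@keptMask <- c(TRUE, FALSE, TRUE)
  r3 <- lzsumSubject(es2, cfg)
  expect_equal(r3$lzsum, mean(r3$perEpoch$lzsum[c(1, 3)]))
  # no kept epochs: missing marker
  es3 <- es
  es3@keptMask <- rep(FALSE, 3)
  expect_warning(r4 <- lzsumSubject(es3, cfg), "missing marker")
  expect_true(is.na(r4$lzsum))
})

test_that("per-subject subset policy holds one channel draw fixed", {
  set.seed(5)
  mats <- replicate(2, matrix(rnorm(10 * 400), nrow = 10), simplify = FALSE)
  es <- epochSetFromMatrices(mats, 100)
  cfg <- complexityConfig(nSubsampleChannels = 4, subsetPolicy = "per-subject",
                          seed = 3)
  r <- lzsumSubject(es, cfg)
  expect_false(anyNA(r$perEpoch$lzsum))
})
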