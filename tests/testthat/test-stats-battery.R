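# Group tests, normality check, OLS models and the full battery.

test_that("Welch t matches the closed-form hand computation", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  r <- welchTTest(a, b)
  h <- handWelch(a, b)
  expect_equal(r$statistic, h$t, tolerance = 1e-10)
  expect_equal(r$df, h$df, tolerance = 1e-10)
  expect_equal(r$pValue, h$p, tolerance = 1e-10)
  expect_lt(abs(r$statistic - (-1.549)), 1e-3)
  expect_lt(abs(r$df - 2.941), 1e-3)
  # identical samples: t = 0, p = 1
  s <- c(1.5, 2.5, 9)
  r0 <- welchTTest(s, s)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pValue, 1)
  # translation invariance
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12, 1)
  r1 <- welchTTest(x, y); r2 <- welchTTest(x + 100, y + 100)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$pValue, r2$pValue, tolerance = 1e-10)
  expect_error(welchTTest(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("Wilcoxon rank-sum reports the rank sum of the first sample", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)                 # ranks 1 + 2
  expect_equal(r$pValue, 1 / 3, tolerance = 1e-10)
  expect_equal(r$pValue, enumRankSumP(c(1, 2), c(3, 4)), tolerance = 1e-10)
  # further enumeration cross-checks at small n
  set.seed(13)
  for (rep in 1:5) {
    a <- round(rnorm(4), 2); b <- round(rnorm(5), 2)
    expect_equal(wilcoxonRankSum(a, b)$pValue, enumRankSumP(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Wilcoxon handles ties via midranks and symmetry gives p = 1", {
  a <- c(1, 2, 2); b <- c(2, 3, 4)
  r <- wilcoxonRankSum(a, b)
  expect_equal(r$statistic, sum(rank(c(a, b))[1:3]))
  same <- c(5, 6, 7)
  expect_equal(wilcoxonRankSum(same, same)$pValue, 1)
  # rank invariance under monotone transforms
  set.seed(2)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  r1 <- wilcoxonRankSum(x, y)
  r2 <- wilcoxonRankSum(exp(x), exp(y))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$pValue, r2$pValue, tolerance = 1e-12)
})

test_that("normality check gives the expected verdicts", {
  set.seed(5)
  normalVerdicts <- replicate(40, checkNormality(rnorm(200))$normal)
  expect_gte(mean(normalVerdicts), 0.9)
  lognormVerdicts <- replicate(40, !checkNormality(exp(rnorm(200)))$normal)
  expect_gte(mean(lognormVerdicts), 0.95)
  expect_true(is.na(checkNormality(rnorm(5))$normal))
  expect_true(is.na(checkNormality(rep(3, 50))$normal))
})

test_that("OLS recovers exact and null relationships", {
  d <- data.frame(x = seq(-3, 3, length.out = 20))
  d$y <- 2 * d$x
  fit <- fitMarkerModel(d, "y", "x")
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(fit$rSquared, 1, tolerance = 1e-10)
  # cross-check all outputs against lm on a noisy fit
  set.seed(6)
  d2 <- data.frame(x = rnorm(50), z = rnorm(50))
  d2$y <- 1 + 0.5 * d2$x + rnorm(50)
  fit2 <- fitMarkerModel(d2, "y", c("x", "z"))
  ref <- summary(lm(y ~ x + z, d2))
  expect_equal(unname(fit2$coefficients), unname(coef(ref)[, 1]),
               tolerance = 1e-10)
  expect_equal(fit2$rSquared, ref$r.squared, tolerance = 1e-10)
  expect_equal(fit2$fStatistic, unname(ref$fstatistic[1]), tolerance = 1e-10)
  # collinear design is named
  d2$w <- d2$x
  expect_error(fitMarkerModel(d2, "y", c("x", "w")), "rank-deficient")
  expect_error(fitMarkerModel(d2, "y", "missing_col"), "missing columns")
})

test_that("independent outcome yields near-zero R^2 and nominal F rejections", {
  set.seed(8)
  rejections <- replicate(60, {
    d <- data.frame(x = rnorm(200))
    d$y <- rnorm(200)
    fitMarkerModel(d, "y", "x")$overallP < 0.05
  })
  expect_lte(mean(rejections), 0.1)
})

test_that("group dummy coding uses control as the reference level", {
  d <- data.frame(
    participant_id = sprintf("s%02d", 1:20),
    group = rep(c("control", "patient"), each = 10),
    age = rep(70, 20), sex = rep(c("F", "M"), 10),
    site = rep(c("CBU", "CTB"), 10), mmse = rep(27, 20),
    lzsum = c(rnorm(10, 0.6, 0.01), rnorm(10, 0.5, 0.01)),
    tar = c(rnorm(10, 1.0, 0.05), rnorm(10, 1.4, 0.05)))
  fit <- fitMarkerModel(d, "lzsum", "group")
  expect_true("grouppatient" %in% names(fit$coefficients))
  expect_lt(fit$coefficients[["grouppatient"]], 0)  # patients lower
})

test_that("the battery runs every configured model once and keeps directions", {
  set.seed(10)
  n <- 30
  d <- data.frame(
    participant_id = sprintf("s%03d", 1:(2 * n)),
    group = rep(c("control", "patient"), each = n),
    age = round(runif(2 * n, 54, 83)),
    sex = sample(c("M", "F"), 2 * n, replace = TRUE),
    site = sample(c("CBU", "CTB"), 2 * n, replace = TRUE))
  sev <- rnorm(2 * n) + (d$group == "patient")
  d$mmse <- round(pmin(pmax(28 - 1.5 * sev + rnorm(2 * n, 0, 0.5), 17), 30))
  d$lzsum <- 0.59 - 0.02 * sev + rnorm(2 * n, 0, 0.005)
  d$tar <- 1.0 + 0.3 * sev + rnorm(2 * n, 0, 0.05)
  rep <- runBattery(d)
  expect_s3_class(rep, "AnalysisReport")
  expect_length(rep$models, 12)
  expect_false(anyDuplicated(names(rep$models)) > 0)
  # directions mirror the configured couplings
  expect_lt(rep$groupTests$lzsum_welch_t$statistic * -1, 0)  # control > patient
  expect_gt(rep$models[["lzsum ~ mmse"]]$coefficients[["mmse"]], 0)
  expect_lt(rep$models[["tar ~ mmse"]]$coefficients[["mmse"]], 0)
  expect_gt(rep$models[["tar ~ group + age"]]$coefficients[["grouppatient"]], 0)
  # adjusted and unadjusted group coefficients both recorded for audit
  expect_true(all(c("lzsum ~ group", "lzsum ~ group + tar") %in%
                    names(rep$models)))
  # BH column exists and is monotone with raw p
  ct <- rep$coefficientTable
  expect_true(all(ct$p_bh >= ct$p - 1e-12))
  # descriptives carry both groups
  expect_equal(unname(ct[1, "n"]), 2 * n)
  expect_equal(rep$descriptives$control[1], n)
})

test_that("battery validates its inputs", {
  d <- data.frame(participant_id = c("a", "b"), group = c("control", "patient"),
                  age = c(60, 70), sex = c("M", "F"),
                  site = c("CBU", "CBU"), mmse = c(28, 25),
                  lzsum = c(0.6, 0.5), tar = c(1, 1.3))
  expect_error(runBattery(d), "degenerate")
  expect_error(runBattery(d[, -7]), "missing required columns")
  d2 <- rbind(d, d)
  expect_error(runBattery(d2), "duplicated participant_id")
})
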