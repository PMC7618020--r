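# Synthetic cohort generator: spectra, determinism, demographics, coupling.

test_that("null parameters give an all-zero recording", {
  p <- signalParams(alphaGain = 0, thetaGain = 0, noiseSd = 0,
                    artifactRate = 0)
  rec <- generateSubjectSignal(p, 3, 250, 8, seed = 1)
  expect_true(all(recData(rec) == 0))
})

test_that("an alpha-only signal concentrates power in 8-12 Hz", {
  p <- signalParams(alphaGain = 1, thetaGain = 0, noiseSd = 0)
  rec <- generateSubjectSignal(p, 2, 250, 12, seed = 2)
  for (ch in 1:2) {
    psd <- welchPsd(recData(rec)[ch, ], 250)
    expect_gt(bandPower(psd, c(8, 12)),
              100 * max(bandPower(psd, c(3, 5)), 1e-300))
  }
})

test_that("signal generation is bit-reproducible and validates inputs", {
  a <- generateSubjectSignal(signalParams(), 3, 250, 8, seed = 5)
  b <- generateSubjectSignal(signalParams(), 3, 250, 8, seed = 5)
  expect_identical(recData(a), recData(b))
  d <- generateSubjectSignal(signalParams(), 3, 250, 8, seed = 6)
  expect_false(identical(recData(a), recData(d)))
  expect_error(generateSubjectSignal(signalParams(), 3, 250, -1, 1),
               "positive|>= 8")
  expect_error(generateSubjectSignal(signalParams(), 3, 250, 4, 1), ">= 8")
})

test_that("artifact bursts appear at the configured rate band", {
  p <- signalParams(artifactRate = 10)
  rec <- generateSubjectSignal(p, 2, 250, 60, seed = 3)
  p0 <- generateSubjectSignal(signalParams(artifactRate = 0), 2, 250, 60,
                              seed = 3)
  hf <- bandPower(welchPsd(recData(rec)[1, ], 250), c(55, 100))
  hf0 <- bandPower(welchPsd(recData(p0)[1, ], 250), c(55, 100))
  expect_gt(hf, 5 * hf0)
})

test_that("cohorts have the configured size, groups and demographics", {
  spec <- cohortSpec(nPerGroup = 83, nChannels = 2, duration = 8, seed = 9)
  cohort <- generateCohort(spec, keepRecordings = FALSE)
  pt <- cohort$participants
  expect_equal(nrow(pt), 166)
  expect_equal(sum(pt$group == "patient"), 83)
  expect_equal(sum(pt$group == "control"), 83)
  expect_true(all(pt$age >= 54 & pt$age <= 83))
  expect_true(all(pt$mmse >= 0 & pt$mmse <= 30))
  expect_true(all(pt$mmse[pt$group == "control"] >= 25))
  expect_true(all(pt$mmse[pt$group == "patient"] >= 17))
  # near-50/50 site balance within each group
  tabs <- table(pt$group, pt$site)
  expect_true(all(abs(tabs - 83 / 2) <= 1))
  # minimal cohort
  c1 <- generateCohort(cohortSpec(nPerGroup = 1, nChannels = 1,
                                  duration = 8, seed = 1))
  expect_equal(nrow(c1$participants), 2)
  expect_setequal(c1$participants$group, c("control", "patient"))
})

test_that("cohort generation is deterministic given the spec seed", {
  spec <- cohortSpec(nPerGroup = 3, nChannels = 2, duration = 8, seed = 4)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$participants, b$participants)
  for (i in seq_along(a$recordings))
    expect_identical(recData(a$recordings[[i]]), recData(b$recordings[[i]]))
  # streaming reconstruction matches kept recordings
  c0 <- generateCohort(spec, keepRecordings = FALSE)
  expect_identical(recData(subjectRecording(c0, 2)),
                   recData(a$recordings[[2]]))
})

test_that("raising thetaGain raises theta band power monotonically", {
  gains <- c(0.3, 0.9, 1.8)
  mean_theta <- vapply(gains, function(g) {
    mean(vapply(1:20, function(s) {
      rec <- generateSubjectSignal(signalParams(thetaGain = g), 1, 250, 8, s)
      bandPower(welchPsd(recData(rec)[1, ], 250), c(3, 5))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_theta) > 0))
})

test_that("raising the AR coefficient lowers normalized LZ (paired)", {
  lzOf <- function(ar, s) {
    rec <- generateSubjectSignal(signalParams(arCoefficient = ar), 4, 250, 8, s)
    es <- epochRecording(rec, preprocessConfig())
    lzsumSubject(es, complexityConfig(nSubsampleChannels = 4, seed = s))$lzsum
  }
  d <- vapply(1:20, function(s) lzOf(0, s) - lzOf(0.9, s), numeric(1))
  expect_true(all(is.finite(d)))
  # sign test: under no effect, P(all-but-one positive) is ~2e-5
  expect_gte(sum(d > 0), 19)
})

test_that("MMSE couples to the severity that drives the signal params", {
  spec <- cohortSpec(nPerGroup = 40, nChannels = 1, duration = 8, seed = 12)
  cohort <- generateCohort(spec, keepRecordings = FALSE)
  sev <- vapply(cohort$subjectParams, function(s) s$severity, numeric(1))
  ar <- vapply(cohort$subjectParams, function(s) s$params@arCoefficient,
               numeric(1))
  th <- vapply(cohort$subjectParams, function(s) s$params@thetaGain,
               numeric(1))
  mmse <- cohort$participants$mmse
  expect_lt(cor(mmse, sev), -0.5)   # lower MMSE = higher severity
  expect_gt(cor(th, sev), 0.5)      # higher severity = more theta (higher TAR)
  expect_gt(cor(ar, sev), 0.5)      # higher severity = more predictable (lower LZ)
})

test_that("a null cohort leaves both groups exchangeable", {
  spec <- cohortSpec(nPerGroup = 50, nChannels = 1, duration = 8, seed = 21,
                     effectTheta = 1, effectAr = 0)
  cohort <- generateCohort(spec, keepRecordings = FALSE)
  th <- vapply(cohort$subjectParams, function(s) s$params@thetaGain,
               numeric(1))
  g <- cohort$participants$group
  # same parameter distribution in both groups (Welch t far from rejection)
  expect_gt(t.test(th[g == "control"], th[g == "patient"])$p.value, 0.01)
})

test_that("invalid cohort specifications are refused", {
  expect_error(cohortSpec(nPerGroup = 0), "nPerGroup")
  expect_error(cohortSpec(duration = 4), ">= 8")
  expect_error(signalParams(arCoefficient = 1), "arCoefficient")
  expect_error(cohortSpec(mmseControl = c(28, 1, 25, 40)), "mmseControl")
})
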