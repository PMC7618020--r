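# Simulated-cohort helper shared by the acceptance properties: generate a
# cohort at a reduced problem size (4 channels, 8 s, i.e. two 4-s epochs) and
# return the subject-level marker table. Channel count and duration are kept
# small so repeated-cohort calibration runs stay cheap; group structure and
# subject counts follow the caller.
simCohortTable <- function(seed, nPerGroup, effectTheta = 1.35,
                           effectAr = 0.12, nChannels = 4, duration = 8) {
  spec <- cohortSpec(nPerGroup = nPerGroup, nChannels = nChannels,
                     duration = duration, seed = seed,
                     effectTheta = effectTheta, effectAr = effectAr)
  cohort <- generateCohort(spec, keepRecordings = FALSE)
  suppressWarnings(cohortMarkers(
    cohort,
    complexityCfg = complexityConfig(nSubsampleChannels = nChannels,
                                     seed = seed)))$subjects
}
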