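## Cohort-level marker computation: preprocess each subject's recording and
## compute subject-level LZsum and TAR.

#' Compute LZsum and TAR for every subject of a cohort
#'
#' Streams through the cohort one subject at a time (regenerating recordings
#' from stored parameters when they were not kept in memory), runs the
#' preprocessing chain, and computes both markers. Channel subsets for LZsum
#' get per-subject seeds derived from \code{complexityCfg@seed} so the whole
#' table is reproducible.
#'
#' @param cohort a cohort from [generateCohort()] (or [readCohort()]).
#' @param preprocessCfg a [PreprocessConfig-class].
#' @param complexityCfg a [ComplexityConfig-class].
#' @param spectralCfg a [SpectralConfig-class].
#' @param verbose emit per-subject progress messages.
#' @return list with \code{subjects} (data.frame: participant_id, group, age,
#'   sex, site, mmse, lzsum, tar, nEpochs, nKept) and \code{perEpoch}
#'   (data.frame of per-epoch marker values).
#' @examples
#' cohort <- generateCohort(cohortSpec(nPerGroup = 2, nChannels = 4,
#'                                     duration = 8, seed = 1))
#' mk <- cohortMarkers(cohort)
#' mk$subjects[, c("participant_id", "lzsum", "tar")]
#' @export
cohortMarkers <- function(cohort,
                          preprocessCfg = preprocessConfig(),
                          complexityCfg = complexityConfig(),
                          spectralCfg = spectralConfig(),
                          verbose = FALSE) {
  meta <- cohort$participants
  n <- nrow(meta)
  nch <- if (!is.null(cohort$spec)) cohort$spec@nChannels
         else nChannels(cohort$recordings[[1L]])
  effK <- min(complexityCfg@nSubsampleChannels, nch)
  if (effK < complexityCfg@nSubsampleChannels)
    warning(sprintf(
      "cohort has %d channels (< %d requested for LZ subsampling): using all",
      nch, complexityCfg@nSubsampleChannels))
  lz <- tar <- rep(NA_real_, n)
  nEp <- nKept <- rep(NA_integer_, n)
  perEpoch <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
           else subjectRecording(cohort, i)
    es <- preprocessRecording(rec, preprocessCfg)
    ccfg <- complexityConfig(
      nSubsampleChannels = effK,
      binarization = complexityCfg@binarization,
      normalization = complexityCfg@normalization,
      subsetPolicy = complexityCfg@subsetPolicy,
      seed = deriveSeed(complexityCfg@seed, i))
    lzr <- lzsumSubject(es, ccfg)
    tr <- tarSubject(es, spectralCfg)
    lz[i] <- lzr$lzsum
    tar[i] <- tr$tar
    nEp[i] <- nEpochs(es)
    nKept[i] <- sum(keptMask(es))
    pe <- merge(lzr$perEpoch, tr$perEpoch[, c("epoch", "valid", "tar")],
                by = "epoch")
    pe$participant_id <- meta$participant_id[i]
    perEpoch[[i]] <- pe
    if (verbose)
      message(sprintf("[markers] %s: lzsum=%.3f tar=%.3f (%d/%d epochs kept)",
                      meta$participant_id[i], lz[i], tar[i], nKept[i], nEp[i]))
  }
  subjects <- cbind(meta, lzsum = lz, tar = tar, nEpochs = nEp, nKept = nKept)
  perEpoch <- do.call(rbind, perEpoch)
  perEpoch <- perEpoch[, c("participant_id", "epoch", "kept", "valid",
                           "lzsum", "tar")]
  list(subjects = subjects, perEpoch = perEpoch)
}
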