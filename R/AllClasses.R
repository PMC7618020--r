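#' @useDynLib MEGmarkers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' MegRecording: a continuous multichannel sensor-space recording
#'
#' Holds a channels x samples matrix of sensor values (arbitrary units,
#' gradiometer-like by default) together with the sampling rate and per-channel
#' metadata. This is the unit of data ingested by the preprocessing chain.
#'
#' @slot data numeric matrix, channels in rows, samples in columns; all values
#'   finite.
#' @slot sfreq sampling frequency in Hz (positive scalar).
#' @slot channelNames character vector, one name per row of \code{data}.
#' @slot channelTypes character vector, one type per channel (\code{"grad"}
#'   for planar gradiometers).
#'
#' @seealso [megRecording()], [resampleRecording()], [epochRecording()]
#' @name MegRecording-class
#' @rdname MegRecording-class
#' @exportClass MegRecording
setClass("MegRecording",
  representation(
    data = "matrix",
    sfreq = "numeric",
    channelNames = "character",
    channelTypes = "character"
  )
)

setValidity("MegRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "'data' must be a numeric matrix")
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    msg <- c(msg, "'sfreq' must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, sprintf(
      "channelNames length (%d) does not match channel count (%d)",
      length(object@channelNames), nrow(object@data)))
  if (length(object@channelTypes) != length(object@channelNames))
    msg <- c(msg, "channelTypes and channelNames must have equal length")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "'data' must contain only finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a MegRecording
#'
#' @param data channels x samples numeric matrix.
#' @param sfreq sampling frequency, Hz.
#' @param channelNames optional channel labels; defaults to
#'   \code{MEG0001 ...}.
#' @param channelTypes optional channel types; defaults to \code{"grad"}.
#' @return A [MegRecording-class] object.
#' @examples
#' rec <- megRecording(matrix(rnorm(200), nrow = 2), sfreq = 100)
#' nChannels(rec)
#' @export
megRecording <- function(data, sfreq,
                         channelNames = sprintf("MEG%04d", seq_len(nrow(data))),
                         channelTypes = rep("grad", nrow(data))) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("MegRecording", data = data, sfreq = as.numeric(sfreq),
      channelNames = as.character(channelNames),
      channelTypes = as.character(channelTypes))
}

#' EpochSet: fixed-length non-overlapping segments of a recording
#'
#' Epochs are stored as an epochs x channels x samples array. The kept/rejected
#' status of every epoch is carried in \code{keptMask}; artifact-rejection
#' diagnostics (per-epoch scores) are in \code{rejectionLog}.
#'
#' @slot epochs numeric array \code{[epoch, channel, sample]}.
#' @slot sfreq sampling frequency, Hz.
#' @slot keptMask logical, one flag per epoch (TRUE = kept).
#' @slot rejectionLog data.frame with per-epoch diagnostics (columns
#'   \code{epoch}, \code{score}, \code{zscore}, \code{rejected}); empty until
#'   [rejectArtifacts()] runs.
#' @slot channelNames character vector of channel labels.
#'
#' @seealso [epochRecording()], [rejectArtifacts()]
#' @name EpochSet-class
#' @rdname EpochSet-class
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    sfreq = "numeric",
    keptMask = "logical",
    rejectionLog = "data.frame",
    channelNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "'epochs' must be a 3-d array [epoch, channel, sample]")
  else {
    if (length(object@keptMask) != d[1L])
      msg <- c(msg, "keptMask length must equal epoch count")
    if (length(object@channelNames) != d[2L])
      msg <- c(msg, "channelNames length must equal channel count")
  }
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "'sfreq' must be a single positive number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Generator parameterisation
## ---------------------------------------------------------------------------

#' SignalParams: spectral and dynamical parameters of a synthetic channel
#'
#' Parameterises one subject's synthetic eyes-closed sensor signal: narrowband
#' alpha (8-12 Hz) and theta (3-5 Hz) oscillations on a 1/f background whose
#' temporal predictability is governed by an AR(1) stage, plus white sensor
#' noise and optional high-frequency muscle-artifact bursts.
#'
#' @slot alphaGain amplitude (a.u.) of the alpha-band oscillation.
#' @slot thetaGain amplitude (a.u.) of the theta-band oscillation.
#' @slot oneOverFExponent spectral slope of the background (power ~ 1/f^e).
#' @slot arCoefficient AR(1) coefficient in [0, 1): higher values make the
#'   background more predictable and lower its normalized LZ complexity.
#' @slot noiseSd standard deviation of additive white noise (a.u.).
#' @slot artifactRate expected muscle bursts per minute (Poisson).
#' @slot artifactBand frequency range (Hz) of artifact bursts.
#'
#' @name SignalParams-class
#' @rdname SignalParams-class
#' @exportClass SignalParams
setClass("SignalParams",
  representation(
    alphaGain = "numeric",
    thetaGain = "numeric",
    oneOverFExponent = "numeric",
    arCoefficient = "numeric",
    noiseSd = "numeric",
    artifactRate = "numeric",
    artifactBand = "numeric"
  ),
  prototype(
    alphaGain = 1.0,
    thetaGain = 0.9,
    oneOverFExponent = 1.0,
    arCoefficient = 0.35,
    noiseSd = 0.5,
    artifactRate = 0,
    artifactBand = c(55, 100)
  )
)

setValidity("SignalParams", function(object) {
  msg <- character()
  if (object@alphaGain < 0 || object@thetaGain < 0)
    msg <- c(msg, "gains must be >= 0")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "arCoefficient must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
  if (length(object@artifactBand) != 2L ||
      object@artifactBand[1] >= object@artifactBand[2])
    msg <- c(msg, "artifactBand must be an increasing length-2 range")
  if (length(msg)) msg else TRUE
})

#' Construct SignalParams
#'
#' @param alphaGain,thetaGain oscillation amplitudes (a.u.).
#' @param oneOverFExponent background spectral slope.
#' @param arCoefficient AR(1) predictability knob in [0, 1).
#' @param noiseSd white-noise SD (a.u.).
#' @param artifactRate expected muscle bursts per minute.
#' @param artifactBand artifact frequency range, Hz.
#' @return A [SignalParams-class] object.
#' @export
signalParams <- function(alphaGain = 1.0, thetaGain = 0.9,
                         oneOverFExponent = 1.0, arCoefficient = 0.35,
                         noiseSd = 0.5, artifactRate = 0,
                         artifactBand = c(55, 100)) {
  new("SignalParams", alphaGain = alphaGain, thetaGain = thetaGain,
      oneOverFExponent = oneOverFExponent, arCoefficient = arCoefficient,
      noiseSd = noiseSd, artifactRate = artifactRate,
      artifactBand = as.numeric(artifactBand))
}

#' CohortSpec: full specification of a synthetic two-group cohort
#'
#' Describes the cohort the generator emulates: two groups (control, patient)
#' of equal size recorded at two sites, ages 54-83, group-specific MMSE
#' distributions, and a patient-group shift of the signal parameters
#' (the "effect"). Defaults mirror the emulated study demographics: 83
#' subjects per group, MMSE 28.88 (range 25-30) in controls and 26.07 (range
#' 17-30) in patients, sites near-balanced across groups.
#'
#' @slot nPerGroup subjects per group.
#' @slot nChannels number of gradiometer-type channels.
#' @slot sfreq raw sampling rate, Hz (250 default; 1000 exercises resampling).
#' @slot duration recording duration, seconds.
#' @slot sites site labels.
#' @slot ageRange inclusive age range, years.
#' @slot mmseControl,mmsePatient numeric c(mean, sd, min, max) per group.
#' @slot baseParams [SignalParams-class] of the control group.
#' @slot effectTheta multiplicative patient-group theta-gain factor.
#' @slot effectAr additive patient-group AR-coefficient shift.
#' @slot subjectSdTheta,subjectSdAr between-subject SDs of the latent
#'   severity mapping (log-theta-gain scale and AR scale).
#' @slot mmseSlope MMSE points lost per 1 SD of latent severity.
#' @slot mmseNoiseSd residual MMSE noise SD (points).
#' @slot seed master RNG seed.
#'
#' @name CohortSpec-class
#' @rdname CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nPerGroup = "integer",
    nChannels = "integer",
    sfreq = "numeric",
    duration = "numeric",
    sites = "character",
    ageRange = "numeric",
    mmseControl = "numeric",
    mmsePatient = "numeric",
    baseParams = "SignalParams",
    effectTheta = "numeric",
    effectAr = "numeric",
    subjectSdTheta = "numeric",
    subjectSdAr = "numeric",
    mmseSlope = "numeric",
    mmseNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@sfreq <= 0 || object@duration <= 0)
    msg <- c(msg, "sfreq and duration must be positive")
  if (object@duration < 8)
    msg <- c(msg, "duration must be >= 8 s (at least two 4-s epochs)")
  if (abs(object@duration * object@sfreq -
          round(object@duration * object@sfreq)) > 1e-9)
    msg <- c(msg, "duration * sfreq must be an integer sample count")
  if (length(object@sites) < 1L) msg <- c(msg, "at least one site required")
  if (length(object@ageRange) != 2L || object@ageRange[1] > object@ageRange[2])
    msg <- c(msg, "ageRange must be an increasing length-2 range")
  for (nm in c("mmseControl", "mmsePatient")) {
    v <- slot(object, nm)
    if (length(v) != 4L || v[3] > v[4] || v[3] < 0 || v[4] > 30)
      msg <- c(msg, sprintf(
        "%s must be c(mean, sd, min, max) with 0 <= min <= max <= 30", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults are the emulated study conditions: 83 subjects per group, 204
#' gradiometers, 250 Hz, 120 s of eyes-closed rest, sites CBU and CTB,
#' ages 54-83, MMSE mean 28.88 (25-30) for controls and 26.07 (17-30) for
#' patients. The patient group's signal parameters are shifted by
#' \code{effectTheta} (theta gain scaled up, raising TAR) and \code{effectAr}
#' (AR coefficient raised, lowering LZ). Set both to zero for a null cohort.
#'
#' @param nPerGroup subjects per group.
#' @param nChannels gradiometer-type channel count.
#' @param sfreq raw sampling rate, Hz.
#' @param duration recording length, seconds (>= 8).
#' @param sites character vector of site labels.
#' @param ageRange length-2 age range in years.
#' @param mmseControl,mmsePatient c(mean, sd, min, max) MMSE per group.
#' @param baseParams control-group [SignalParams-class].
#' @param effectTheta multiplicative patient theta-gain factor (1 = no effect).
#' @param effectAr additive patient AR-coefficient shift (0 = no effect).
#' @param subjectSdTheta,subjectSdAr between-subject severity SDs.
#' @param mmseSlope MMSE points per SD of latent severity.
#' @param mmseNoiseSd residual MMSE noise, points.
#' @param seed master seed; per-subject streams are derived from it.
#' @return A [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerGroup = 2, nChannels = 4, duration = 8, seed = 1)
#' cohort <- generateCohort(spec)
#' cohort$participants
#' @export
cohortSpec <- function(nPerGroup = 83L, nChannels = 204L, sfreq = 250,
                       duration = 120, sites = c("CBU", "CTB"),
                       ageRange = c(54, 83),
                       mmseControl = c(28.88, 1.3, 25, 30),
                       mmsePatient = c(26.07, 3.0, 17, 30),
                       baseParams = signalParams(),
                       effectTheta = 1.35, effectAr = 0.12,
                       subjectSdTheta = 0.18, subjectSdAr = 0.05,
                       mmseSlope = 1.6, mmseNoiseSd = 1.0,
                       seed = 1L) {
  new("CohortSpec",
      nPerGroup = as.integer(nPerGroup), nChannels = as.integer(nChannels),
      sfreq = as.numeric(sfreq), duration = as.numeric(duration),
      sites = as.character(sites), ageRange = as.numeric(ageRange),
      mmseControl = as.numeric(mmseControl),
      mmsePatient = as.numeric(mmsePatient),
      baseParams = baseParams,
      effectTheta = as.numeric(effectTheta), effectAr = as.numeric(effectAr),
      subjectSdTheta = as.numeric(subjectSdTheta),
      subjectSdAr = as.numeric(subjectSdAr),
      mmseSlope = as.numeric(mmseSlope),
      mmseNoiseSd = as.numeric(mmseNoiseSd),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Stage configuration objects
## ---------------------------------------------------------------------------

#' PreprocessConfig: resampling, filtering, epoching and artifact rejection
#'
#' @slot targetSfreq target sampling rate after decimation, Hz.
#' @slot highpass high-pass cutoff, Hz.
#' @slot notch notch (line-noise) frequency, Hz.
#' @slot epochLength epoch length, seconds.
#' @slot artifactZThreshold z-score threshold on log high-frequency power.
#' @slot artifactBand muscle-artifact detection band, Hz.
#' @slot maxRejectFraction fraction of epochs above which rejection warns.
#'
#' @name PreprocessConfig-class
#' @rdname PreprocessConfig-class
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(
    targetSfreq = "numeric", highpass = "numeric", notch = "numeric",
    epochLength = "numeric", artifactZThreshold = "numeric",
    artifactBand = "numeric", maxRejectFraction = "numeric"
  ),
  prototype(targetSfreq = 250, highpass = 0.5, notch = 50, epochLength = 4,
            artifactZThreshold = 3, artifactBand = c(55, 100),
            maxRejectFraction = 0.5)
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  nyq <- object@targetSfreq / 2
  if (!(object@highpass < object@notch && object@notch < nyq))
    msg <- c(msg, "need highpass < notch < Nyquist of targetSfreq")
  ns <- object@epochLength * object@targetSfreq
  if (abs(ns - round(ns)) > 1e-9)
    msg <- c(msg, "epochLength * targetSfreq must be an integer")
  if (object@epochLength <= 0) msg <- c(msg, "epochLength must be positive")
  if (length(object@artifactBand) != 2L ||
      object@artifactBand[1] >= object@artifactBand[2])
    msg <- c(msg, "artifactBand must be an increasing length-2 range")
  if (length(msg)) msg else TRUE
})

#' Construct a PreprocessConfig
#'
#' Defaults follow the emulated pipeline: downsample to 250 Hz, 0.5 Hz
#' zero-phase high-pass, 50 Hz notch, 4-s epochs, and automated rejection of
#' epochs whose 55-100 Hz log power is a > 3 SD outlier within subject.
#'
#' @param targetSfreq,highpass,notch,epochLength,artifactZThreshold,artifactBand,maxRejectFraction see slots.
#' @return A [PreprocessConfig-class].
#' @export
preprocessConfig <- function(targetSfreq = 250, highpass = 0.5, notch = 50,
                             epochLength = 4, artifactZThreshold = 3,
                             artifactBand = c(55, 100),
                             maxRejectFraction = 0.5) {
  new("PreprocessConfig", targetSfreq = targetSfreq, highpass = highpass,
      notch = notch, epochLength = epochLength,
      artifactZThreshold = artifactZThreshold,
      artifactBand = as.numeric(artifactBand),
      maxRejectFraction = maxRejectFraction)
}

#' ComplexityConfig: LZsum computation settings
#'
#' @slot nSubsampleChannels channels drawn per epoch (25 by default).
#' @slot binarization \code{"hilbert-mean"} (instantaneous amplitude vs. its
#'   epoch mean) or \code{"signal-median"}.
#' @slot normalization \code{"asymptotic"} (c / (n / log2 n)) or \code{"none"}.
#' @slot subsetPolicy \code{"per-epoch"} (fresh random draw each epoch) or
#'   \code{"per-subject"} (one fixed draw).
#' @slot seed RNG seed for the channel draws.
#'
#' @name ComplexityConfig-class
#' @rdname ComplexityConfig-class
#' @exportClass ComplexityConfig
setClass("ComplexityConfig",
  representation(
    nSubsampleChannels = "integer", binarization = "character",
    normalization = "character", subsetPolicy = "character", seed = "integer"
  ),
  prototype(nSubsampleChannels = 25L, binarization = "hilbert-mean",
            normalization = "asymptotic", subsetPolicy = "per-epoch",
            seed = 1L)
)

setValidity("ComplexityConfig", function(object) {
  msg <- character()
  if (object@nSubsampleChannels < 1L)
    msg <- c(msg, "nSubsampleChannels must be >= 1")
  if (!object@binarization %in% c("hilbert-mean", "signal-median"))
    msg <- c(msg, "binarization must be 'hilbert-mean' or 'signal-median'")
  if (!object@normalization %in% c("asymptotic", "none"))
    msg <- c(msg, "normalization must be 'asymptotic' or 'none'")
  if (!object@subsetPolicy %in% c("per-epoch", "per-subject"))
    msg <- c(msg, "subsetPolicy must be 'per-epoch' or 'per-subject'")
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexityConfig
#'
#' @param nSubsampleChannels,binarization,normalization,subsetPolicy,seed see
#'   the class slots.
#' @return A [ComplexityConfig-class].
#' @export
complexityConfig <- function(nSubsampleChannels = 25L,
                             binarization = "hilbert-mean",
                             normalization = "asymptotic",
                             subsetPolicy = "per-epoch", seed = 1L) {
  new("ComplexityConfig", nSubsampleChannels = as.integer(nSubsampleChannels),
      binarization = binarization, normalization = normalization,
      subsetPolicy = subsetPolicy, seed = as.integer(seed))
}

#' SpectralConfig: Welch estimation and theta/alpha band definitions
#'
#' @slot thetaBand theta range, Hz (3-5 by default, following the emulated
#'   study's explicit, non-standard definition).
#' @slot alphaBand alpha range, Hz (8-12).
#' @slot welchSegment Welch segment length, seconds.
#' @slot welchOverlap segment overlap fraction in [0, 1).
#' @slot window taper name (\code{"hann"}).
#' @slot alphaFloor minimal admissible mean alpha power relative to total
#'   power; epochs below it carry no valid TAR.
#' @slot ratioConvention \code{"ratio-of-means"} (sensor-mean theta over
#'   sensor-mean alpha) or \code{"mean-of-ratios"}.
#'
#' @name SpectralConfig-class
#' @rdname SpectralConfig-class
#' @exportClass SpectralConfig
setClass("SpectralConfig",
  representation(
    thetaBand = "numeric", alphaBand = "numeric", welchSegment = "numeric",
    welchOverlap = "numeric", window = "character", alphaFloor = "numeric",
    ratioConvention = "character"
  ),
  prototype(thetaBand = c(3, 5), alphaBand = c(8, 12), welchSegment = 2,
            welchOverlap = 0.5, window = "hann", alphaFloor = 1e-12,
            ratioConvention = "ratio-of-means")
)

setValidity("SpectralConfig", function(object) {
  msg <- character()
  for (nm in c("thetaBand", "alphaBand")) {
    b <- slot(object, nm)
    if (length(b) != 2L || b[1] >= b[2] || b[1] <= 0)
      msg <- c(msg, sprintf("%s must be an increasing positive range", nm))
  }
  if (!(object@thetaBand[2] <= object@alphaBand[1] ||
        object@alphaBand[2] <= object@thetaBand[1]))
    msg <- c(msg, "thetaBand and alphaBand must be disjoint")
  if (object@welchOverlap < 0 || object@welchOverlap >= 1)
    msg <- c(msg, "welchOverlap must be in [0, 1)")
  if (object@welchSegment <= 0) msg <- c(msg, "welchSegment must be positive")
  if (!object@window %in% "hann") msg <- c(msg, "only the hann taper is supported")
  if (!object@ratioConvention %in% c("ratio-of-means", "mean-of-ratios"))
    msg <- c(msg, "ratioConvention must be 'ratio-of-means' or 'mean-of-ratios'")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralConfig
#'
#' @param thetaBand,alphaBand,welchSegment,welchOverlap,window,alphaFloor,ratioConvention
#'   see the class slots.
#' @return A [SpectralConfig-class].
#' @export
spectralConfig <- function(thetaBand = c(3, 5), alphaBand = c(8, 12),
                           welchSegment = 2, welchOverlap = 0.5,
                           window = "hann", alphaFloor = 1e-12,
                           ratioConvention = "ratio-of-means") {
  new("SpectralConfig", thetaBand = as.numeric(thetaBand),
      alphaBand = as.numeric(alphaBand), welchSegment = welchSegment,
      welchOverlap = welchOverlap, window = window, alphaFloor = alphaFloor,
      ratioConvention = ratioConvention)
}
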