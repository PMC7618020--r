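## Synthetic two-group resting-state cohort: eyes-closed, alpha-dominant
## multichannel signals with a 1/f background, an AR(1) predictability knob,
## group-modulated theta gain, and an MMSE score coupled to the realized
## signal parameters.

#' Generate one subject's multichannel resting-state signal
#'
#' Each channel is the sum of an alpha-band and a theta-band sinusoid (random
#' frequency inside the band and random phase, independently per channel), a
#' 1/f-shaped noise background passed through an AR(1) filter (the temporal
#' predictability knob: higher \code{arCoefficient} means a more predictable
#' signal and lower normalized LZ), and white sensor noise. Muscle-artifact
#' bursts (0.5 s of band-limited 55-100 Hz noise at 10x the channel SD) are
#' placed by a Poisson process at \code{artifactRate} bursts per minute,
#' simultaneously across channels. The colored background is scaled to
#' \code{noiseSd}; white noise has SD \code{0.2 * noiseSd}.
#'
#' @param params a [SignalParams-class].
#' @param nChannels number of gradiometer-like channels.
#' @param sfreq sampling rate, Hz.
#' @param duration recording length, seconds (>= 8, i.e. two 4-s epochs).
#' @param seed RNG seed; identical inputs give bit-identical output.
#' @return a [MegRecording-class].
#' @examples
#' rec <- generateSubjectSignal(signalParams(), nChannels = 4,
#'                              sfreq = 250, duration = 8, seed = 1)
#' rec
#' @export
generateSubjectSignal <- function(params, nChannels, sfreq, duration, seed) {
  validObject(params)
  if (duration <= 0 || sfreq <= 0)
    stop("duration and sfreq must be positive: invalid specification")
  if (duration < 8)
    stop("duration must be >= 8 s (at least two 4-s epochs)")
  n <- round(duration * sfreq)
  tt <- (seq_len(n) - 1L) / sfreq
  out <- matrix(0, nrow = nChannels, ncol = n)
  withSeed(seed, {
    for (ch in seq_len(nChannels)) {
      x <- numeric(n)
      if (params@alphaGain > 0) {
        fA <- stats::runif(1, 8, 12); phA <- stats::runif(1, 0, 2 * pi)
        x <- x + params@alphaGain * sin(2 * pi * fA * tt + phA)
      }
      if (params@thetaGain > 0) {
        fT <- stats::runif(1, 3, 5); phT <- stats::runif(1, 0, 2 * pi)
        x <- x + params@thetaGain * sin(2 * pi * fT * tt + phT)
      }
      if (params@noiseSd > 0) {
        bg <- .colouredNoise(n, params@oneOverFExponent)
        bg <- as.numeric(stats::filter(bg, params@arCoefficient,
                                       method = "recursive"))
        bg <- bg / stats::sd(bg) * params@noiseSd
        x <- x + bg + stats::rnorm(n, sd = 0.2 * params@noiseSd)
      }
      out[ch, ] <- x
    }
    if (params@artifactRate > 0) {
      nBurst <- stats::rpois(1, params@artifactRate * duration / 60)
      burstLen <- round(0.5 * sfreq)
      if (nBurst > 0 && burstLen > 1 && n > burstLen) {
        starts <- sample.int(n - burstLen, nBurst, replace = TRUE)
        nyq <- sfreq / 2
        band <- pmin(params@artifactBand, nyq * 0.99)
        bf <- signal::butter(4, band / nyq, type = "pass")
        for (s in starts) {
          idx <- s:(s + burstLen - 1L)
          for (ch in seq_len(nChannels)) {
            burst <- signal::filter(bf, stats::rnorm(burstLen))
            sdc <- stats::sd(out[ch, ])
            if (sdc == 0) sdc <- 1
            burst <- burst / max(stats::sd(burst), .Machine$double.eps) *
              10 * sdc
            out[ch, idx] <- out[ch, idx] + burst
          }
        }
      }
    }
  })
  megRecording(out, sfreq)
}

# white noise shaped to a 1/f^e amplitude spectrum, unit SD
.colouredNoise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))         # avoid division by zero at DC
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  W <- W * f^(-exponent / 2)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate a labelled two-group cohort
#'
#' Draws \code{2 * nPerGroup} subjects. Sites are balanced across groups
#' (near 50/50), ages are truncated-normal inside \code{ageRange}, and sex is
#' drawn at the emulated study's 56% male rate. Each subject carries a latent
#' severity score that simultaneously (i) scales the theta gain up, (ii)
#' raises the AR coefficient (lowering expected LZ), and (iii) lowers the
#' MMSE score (linear with Gaussian noise, rounded and clipped to the group
#' range) — so that lower MMSE implies higher TAR and lower LZ by
#' construction. The patient group is additionally shifted by
#' \code{effectTheta} and \code{effectAr}.
#'
#' @param spec a [CohortSpec-class].
#' @param keepRecordings if TRUE (default) the recordings are generated and
#'   returned; with large cohorts set FALSE and stream them one at a time via
#'   [subjectRecording()].
#' @return list with \code{participants} (data.frame: participant_id, group,
#'   age, sex, site, mmse), \code{subjectParams} (per-subject
#'   [SignalParams-class] and seed), \code{recordings} (list of
#'   [MegRecording-class], or NULL), and \code{spec}.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPerGroup = 1, nChannels = 2,
#'                                     duration = 8, seed = 3))
#' cohort$participants
#' @export
generateCohort <- function(spec, keepRecordings = TRUE) {
  validObject(spec)
  nTot <- 2L * spec@nPerGroup
  group <- rep(c("control", "patient"), each = spec@nPerGroup)

  # near-50/50 site balance within each group
  siteOf <- function(k) spec@sites[((seq_len(k) - 1L) %% length(spec@sites)) + 1L]
  site <- c(siteOf(spec@nPerGroup), rev(siteOf(spec@nPerGroup)))

  meta <- NULL
  subjectParams <- vector("list", nTot)
  withSeed(deriveSeed(spec@seed, 0L), {
    age <- round(pmin(pmax(stats::rnorm(nTot, 70.83, 7),
                           spec@ageRange[1]), spec@ageRange[2]))
    sex <- ifelse(stats::runif(nTot) < 0.56, "M", "F")
    severity <- stats::rnorm(nTot)
    alphaJit <- stats::rnorm(nTot, sd = 0.10)
    mmse <- numeric(nTot)
    for (i in seq_len(nTot)) {
      g <- if (group[i] == "patient") spec@mmsePatient else spec@mmseControl
      m <- g[1] - spec@mmseSlope * severity[i] +
        stats::rnorm(1, sd = spec@mmseNoiseSd)
      mmse[i] <- min(max(round(m), g[3]), g[4])
    }
    base <- spec@baseParams
    for (i in seq_len(nTot)) {
      isPat <- group[i] == "patient"
      th <- base@thetaGain * (if (isPat) spec@effectTheta else 1) *
        exp(spec@subjectSdTheta * severity[i])
      ar <- base@arCoefficient + (if (isPat) spec@effectAr else 0) +
        spec@subjectSdAr * severity[i]
      ar <- min(max(ar, 0), 0.97)
      subjectParams[[i]] <- list(
        params = signalParams(
          alphaGain = base@alphaGain * exp(alphaJit[i]),
          thetaGain = th,
          oneOverFExponent = base@oneOverFExponent,
          arCoefficient = ar,
          noiseSd = base@noiseSd,
          artifactRate = base@artifactRate,
          artifactBand = base@artifactBand),
        seed = deriveSeed(spec@seed, i),
        severity = severity[i])
    }
    meta <- data.frame(
      participant_id = sprintf("sub-%03d", seq_len(nTot)),
      group = group, age = as.integer(age), sex = sex, site = site,
      mmse = as.integer(mmse), stringsAsFactors = FALSE)
  })

  recordings <- NULL
  if (keepRecordings) {
    recordings <- vector("list", nTot)
    for (i in seq_len(nTot))
      recordings[[i]] <- generateSubjectSignal(
        subjectParams[[i]]$params, spec@nChannels, spec@sfreq,
        spec@duration, subjectParams[[i]]$seed)
    names(recordings) <- meta$participant_id
  }
  list(participants = meta, subjectParams = subjectParams,
       recordings = recordings, spec = spec)
}

#' Regenerate one subject's recording from a cohort
#'
#' Rebuilds subject \code{i}'s [MegRecording-class] from the stored
#' per-subject parameters and seed; identical to the recording
#' [generateCohort()] would have kept. Lets large cohorts be processed one
#' subject at a time.
#'
#' @param cohort a cohort list from [generateCohort()].
#' @param i subject index (row of \code{cohort$participants}).
#' @return a [MegRecording-class].
#' @export
subjectRecording <- function(cohort, i) {
  sp <- cohort$subjectParams[[i]]
  generateSubjectSignal(sp$params, cohort$spec@nChannels, cohort$spec@sfreq,
                        cohort$spec@duration, sp$seed)
}
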