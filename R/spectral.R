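## Theta-alpha ratio (TAR): Welch band powers averaged over gradiometers,
## theta (3-5 Hz) over alpha (8-12 Hz), per epoch then per subject.

#' Welch power spectral density of one channel segment
#'
#' Average of Hann-tapered, overlapped periodograms with one-sided density
#' scaling, so that the integral of the PSD over frequency approximates the
#' signal's mean power (Parseval). Frequency resolution is
#' \code{1 / welchSegment} (0.5 Hz with the defaults).
#'
#' @param x numeric vector of samples.
#' @param sfreq sampling rate, Hz.
#' @param cfg a [SpectralConfig-class].
#' @return list with \code{freq} (Hz) and \code{psd} (a.u.^2 / Hz).
#' @examples
#' t <- (0:999) / 250
#' p <- welchPsd(sin(2 * pi * 10 * t), 250)
#' p$freq[which.max(p$psd)]  # 10
#' @export
welchPsd <- function(x, sfreq, cfg = spectralConfig()) {
  validObject(cfg)
  ns <- round(cfg@welchSegment * sfreq)
  if (ns > length(x))
    stop("Welch segment longer than the data: invalid configuration")
  step <- max(1L, round(ns * (1 - cfg@welchOverlap)))
  starts <- seq(1L, length(x) - ns + 1L, by = step)
  w <- hannWindow(ns)
  scale <- 1 / (sfreq * sum(w^2))
  nf <- ns %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + ns - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) * scale
    # one-sided: double everything except DC (and Nyquist when ns is even)
    if (ns %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * sfreq / ns, psd = acc / length(starts))
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the density over the bins whose centers lie in the
#' closed band.
#'
#' @param psd a list with \code{freq} and \code{psd} as returned by
#'   [welchPsd()].
#' @param band length-2 numeric range, Hz.
#' @return band power, a.u.^2.
#' @export
bandPower <- function(psd, band) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  if (length(sel) == 0L)
    stop(sprintf("no PSD bins inside band [%g, %g] Hz", band[1], band[2]))
  trapz(psd$freq[sel], psd$psd[sel])
}

#' Theta-alpha ratio of one epoch
#'
#' Per-channel Welch band powers in the theta and alpha bands over ALL
#' channels (no subsampling), then the configured ratio convention:
#' sensor-mean theta over sensor-mean alpha (default, numerically stabler) or
#' the mean of per-sensor ratios. An epoch whose mean alpha power falls below
#' \code{alphaFloor} times the mean total power carries no valid TAR.
#'
#' @param epoch channels x samples numeric matrix.
#' @param sfreq sampling rate, Hz.
#' @param cfg a [SpectralConfig-class].
#' @return list with \code{thetaPower}, \code{alphaPower} (sensor means),
#'   \code{tar}, and \code{valid} (logical).
#' @export
tarEpoch <- function(epoch, sfreq, cfg = spectralConfig()) {
  validObject(cfg)
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 1L) stop("epoch must have at least one channel")
  nch <- nrow(epoch)
  th <- al <- tot <- numeric(nch)
  for (ch in seq_len(nch)) {
    p <- welchPsd(epoch[ch, ], sfreq, cfg)
    th[ch] <- bandPower(p, cfg@thetaBand)
    al[ch] <- bandPower(p, cfg@alphaBand)
    tot[ch] <- trapz(p$freq, p$psd)
  }
  mth <- mean(th); mal <- mean(al)
  floorVal <- cfg@alphaFloor * mean(tot)
  valid <- mal > floorVal && mal > 0
  tar <- if (!valid) NA_real_
  else if (cfg@ratioConvention == "ratio-of-means") mth / mal
  else mean(th / al)
  list(thetaPower = mth, alphaPower = mal, tar = tar, valid = valid)
}

#' Subject-level theta-alpha ratio
#'
#' Arithmetic mean of per-epoch TAR over the kept, valid epochs of an
#' [EpochSet-class].
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [SpectralConfig-class].
#' @return list with \code{tar} (subject mean; \code{NA} with a warning when
#'   no kept epoch has a valid TAR) and \code{perEpoch}, a data.frame of
#'   \code{epoch}, \code{kept}, \code{valid}, \code{thetaPower},
#'   \code{alphaPower}, \code{tar}.
#' @export
tarSubject <- function(epochs, cfg = spectralConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  validObject(cfg)
  ne <- nEpochs(epochs)
  tab <- data.frame(epoch = seq_len(ne), kept = epochs@keptMask,
                    valid = FALSE, thetaPower = NA_real_,
                    alphaPower = NA_real_, tar = NA_real_)
  for (e in which(epochs@keptMask)) {
    ep <- epochs@epochs[e, , , drop = TRUE]
    if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1L)
    r <- tarEpoch(ep, sfreq(epochs), cfg)
    tab$valid[e] <- r$valid
    tab$thetaPower[e] <- r$thetaPower
    tab$alphaPower[e] <- r$alphaPower
    tab$tar[e] <- r$tar
  }
  use <- tab$kept & tab$valid
  if (!any(use)) {
    warning("no kept epoch with valid TAR: subject has no TAR (missing marker)")
    return(list(tar = NA_real_, perEpoch = tab))
  }
  list(tar = mean(tab$tar[use]), perEpoch = tab)
}
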