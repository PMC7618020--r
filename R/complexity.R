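## LZsum: normalized LZ76 complexity of binarized sensor signals, averaged
## over a random gradiometer subset per epoch, then over kept epochs.

#' Analytic-signal amplitude envelope
#'
#' FFT-based Hilbert transform: the instantaneous amplitude of the analytic
#' signal, used by the \code{"hilbert-mean"} binarization rule.
#'
#' @param x numeric vector (one channel, one epoch).
#' @return numeric vector of the same length: \code{Mod(analytic(x))}.
#' @keywords internal
hilbertEnvelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Binarize a single-channel epoch
#'
#' Converts a real-valued signal segment into the 0/1 sequence on which LZ76
#' operates. \code{"hilbert-mean"}: bit t is 1 iff the instantaneous amplitude
#' (analytic-signal envelope) exceeds the epoch-mean envelope.
#' \code{"signal-median"}: bit t is 1 iff the raw sample exceeds the epoch
#' median. Ties map to 0 in both rules (strict inequality).
#'
#' @param x numeric vector, length >= 2, finite.
#' @param method \code{"hilbert-mean"} (default) or \code{"signal-median"}.
#' @return integer vector of 0/1 bits, same length as \code{x}.
#' @examples
#' binarizeSignal(c(1, 3, 2, 4), method = "signal-median")  # 0 1 0 1
#' @export
binarizeSignal <- function(x, method = c("hilbert-mean", "signal-median")) {
  method <- match.arg(method)
  if (length(x) < 2L) stop("binarizeSignal needs at least 2 samples")
  if (any(!is.finite(x))) stop("binarizeSignal requires finite input")
  if (stats::var(x) == 0) {
    warning("constant input: binarized sequence is all zeros")
    return(integer(length(x)))
  }
  bits <- switch(method,
    "hilbert-mean" = {
      env <- hilbertEnvelope(x)
      as.integer(env > mean(env))
    },
    "signal-median" = as.integer(x > stats::median(x))
  )
  bits
}

#' LZ76 complexity of a binary sequence
#'
#' Number of words in the exhaustive-history production parsing of a binary
#' sequence (Lempel-Ziv 1976), computed with the simplified Kaspar-Schuster
#' scan: reading left to right, a new word ends as soon as the current phrase
#' cannot be copied (overlap allowed) from the previously seen prefix; the
#' final, possibly uncompleted word counts.
#'
#' @param bits integer/logical vector over \{0, 1\} (or a character string of
#'   "0"/"1").
#' @return integer word count \code{c >= 1}.
#' @examples
#' lz76(rep(0L, 8))                 # 2
#' lz76(c(0, 1, 0, 1, 0, 1, 0, 1))  # 3
#' @export
lz76 <- function(bits) {
  if (is.character(bits) && length(bits) == 1L)
    bits <- as.integer(strsplit(bits, "")[[1L]])
  bits <- as.integer(bits)
  if (length(bits) == 0L) stop("empty sequence")
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("sequence must be over the alphabet {0, 1}")
  .lz76_count(bits)
}

#' Normalize an LZ76 word count
#'
#' Divides the word count by n / log2(n), the asymptotic expected count for an
#' equiprobable random binary string, yielding approximately 1 for white noise
#' and approximately 0 for highly regular signals.
#'
#' @param c integer LZ76 word count.
#' @param n sequence length, >= 2.
#' @return unitless normalized complexity.
#' @examples
#' normalizeLZ(2, 16)  # 0.5
#' @export
normalizeLZ <- function(c, n) {
  if (n < 2) stop("normalization requires n >= 2")
  c / (n / log2(n))
}

#' LZsum of one epoch
#'
#' Draws \code{min(nSubsampleChannels, nChannels)} channels without
#' replacement (using the current RNG state; seed management is done by
#' [lzsumSubject()]), binarizes each channel, computes its LZ76 word count,
#' normalizes, and averages: the epoch's LZsum.
#'
#' @param epoch channels x samples numeric matrix.
#' @param cfg a [ComplexityConfig-class].
#' @return list with \code{channelSubset} (indices), \code{cPerChannel}
#'   (integer word counts), \code{normalizedPerChannel}, and \code{lzsum}
#'   (their mean).
#' @export
lzsumEpoch <- function(epoch, cfg = complexityConfig()) {
  validObject(cfg)
  epoch <- as.matrix(epoch)
  nch <- nrow(epoch)
  if (nch < 1L) stop("epoch must have at least one channel")
  k <- cfg@nSubsampleChannels
  if (nch < k) {
    warning(sprintf(
      "only %d channels available (< %d requested): using all channels",
      nch, k))
    subset <- seq_len(nch)
  } else {
    subset <- sort(sample.int(nch, k))
  }
  n <- ncol(epoch)
  cvals <- integer(length(subset))
  for (j in seq_along(subset)) {
    bits <- binarizeSignal(epoch[subset[j], ], method = cfg@binarization)
    cvals[j] <- .lz76_count(bits)
  }
  norm <- if (cfg@normalization == "asymptotic")
    normalizeLZ(cvals, n) else as.numeric(cvals)
  list(channelSubset = subset, cPerChannel = cvals,
       normalizedPerChannel = norm, lzsum = mean(norm))
}

#' Subject-level LZsum
#'
#' Computes per-epoch LZsum over the kept epochs of an [EpochSet-class] and
#' aggregates by the arithmetic mean. The channel subset is redrawn per epoch
#' (\code{subsetPolicy = "per-epoch"}) or drawn once and reused
#' (\code{"per-subject"}); both draws are seeded from \code{cfg@seed} so the
#' result is reproducible.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [ComplexityConfig-class].
#' @return list with \code{lzsum} (subject mean over kept epochs; \code{NA}
#'   with a warning if no epoch was kept) and \code{perEpoch}, a data.frame of
#'   \code{epoch}, \code{kept}, \code{lzsum}.
#' @examples
#' rec <- megRecording(matrix(rnorm(4 * 2000), nrow = 4), sfreq = 250)
#' es <- epochRecording(rec, preprocessConfig())
#' lzsumSubject(es, complexityConfig(seed = 7))$lzsum
#' @export
lzsumSubject <- function(epochs, cfg = complexityConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  validObject(cfg)
  kept <- which(epochs@keptMask)
  if (length(kept) == 0L) {
    warning("no kept epochs: subject has no LZsum (missing marker)")
    return(list(lzsum = NA_real_,
                perEpoch = data.frame(epoch = integer(), kept = logical(),
                                      lzsum = numeric())))
  }
  vals <- rep(NA_real_, nEpochs(epochs))
  if (nChannels(epochs) < cfg@nSubsampleChannels &&
      cfg@subsetPolicy == "per-epoch")
    warning(sprintf(
      "only %d channels available (< %d requested): using all channels",
      nChannels(epochs), cfg@nSubsampleChannels))
  withSeed(cfg@seed, {
    if (cfg@subsetPolicy == "per-subject") {
      nch <- nChannels(epochs)
      k <- min(cfg@nSubsampleChannels, nch)
      if (nch < cfg@nSubsampleChannels)
        warning(sprintf(
          "only %d channels available (< %d requested): using all channels",
          nch, cfg@nSubsampleChannels))
      fixedSubset <- sort(sample.int(nch, k))
    }
    for (e in kept) {
      ep <- epochs@epochs[e, , , drop = TRUE]
      if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1L)
      if (cfg@subsetPolicy == "per-subject") {
        sub <- ep[fixedSubset, , drop = FALSE]
        res <- suppressWarnings(
          lzsumEpoch(sub, complexityConfig(
            nSubsampleChannels = nrow(sub), binarization = cfg@binarization,
            normalization = cfg@normalization, seed = cfg@seed)))
      } else {
        res <- suppressWarnings(lzsumEpoch(ep, cfg))
      }
      vals[e] <- res$lzsum
    }
  })
  list(lzsum = mean(vals[kept]),
       perEpoch = data.frame(epoch = seq_len(nEpochs(epochs)),
                             kept = epochs@keptMask, lzsum = vals))
}
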