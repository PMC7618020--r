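# Independent reference implementations and fixture builders used across the
# suite. The brute-force LZ76 parser below follows the exhaustive-history
# definition directly (naive substring search) and shares no code with the
# package's scanning implementation.

# Brute-force LZ76: walk left to right; the current phrase ends the moment it
# stops being a substring (overlap allowed) of everything seen before its
# last symbol; the final, possibly still-copyable phrase counts.
bruteLZ76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  stopifnot(n >= 1L)
  cnt <- 0L
  p <- 1L
  while (p <= n) {
    q <- p
    # extend while s[p..q] occurs inside s[1..q-1]
    while (q <= n &&
           grepl(substr(s, p, q), substr(s, 1L, q - 1L), fixed = TRUE)) {
      q <- q + 1L
    }
    cnt <- cnt + 1L
    if (q > n) break  # final phrase ran off the end (still counts once)
    p <- q + 1L
  }
  cnt
}

# all binary strings of a given length, as integer vectors
allBinaryStrings <- function(len) {
  lapply(0:(2^len - 1L), function(v) {
    bits <- integer(len)
    for (j in seq_len(len)) bits[j] <- (v %/% 2^(j - 1L)) %% 2L
    bits
  })
}

# multichannel pure-tone recording
toneRecording <- function(freqs, amps, sfreq = 250, duration = 10,
                          nChannels = 1) {
  tt <- (seq_len(round(duration * sfreq)) - 1L) / sfreq
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * tt), freqs, amps))
  megRecording(matrix(rep(x, each = nChannels), nrow = nChannels), sfreq)
}

# EpochSet built directly from a list of channels x samples matrices
epochSetFromMatrices <- function(mats, sfreq) {
  ne <- length(mats)
  nch <- nrow(mats[[1L]])
  ns <- ncol(mats[[1L]])
  arr <- array(0, dim = c(ne, nch, ns))
  for (e in seq_len(ne)) arr[e, , ] <- mats[[e]]
  new("EpochSet", epochs = arr, sfreq = sfreq, keptMask = rep(TRUE, ne),
      rejectionLog = data.frame(epoch = integer(), score = numeric(),
                                zscore = numeric(), rejected = logical()),
      channelNames = sprintf("MEG%04d", seq_len(nch)))
}

# closed-form Welch t and Satterthwaite df, written out independently
handWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# exact two-sided rank-sum p by enumeration of all group assignments
enumRankSumP <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  Wobs <- sum(r[seq_len(n1)])
  combs <- combn(n, n1)
  Wall <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- mean(Wall)
  min(1, mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-12))
}
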