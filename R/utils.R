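## Shared numerical and RNG helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, runs \code{expr}, and restores the caller's
#' RNG state afterwards, so seeded module internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Counter-based seed derivation
#'
#' Derives a stream seed from a master seed and a counter so that subjects
#' (and stages) get independent, reproducible RNG streams. Uses a 31-bit
#' multiplicative mix; collisions across the counters used in one run are
#' avoided by construction (distinct counters, fixed master).
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return integer seed in [0, 2^31 - 1).
#' @keywords internal
deriveSeed <- function(master, counter) {
  m <- 2147483647           # 2^31 - 1 (prime)
  s <- (as.numeric(master) %% m + 1) * 48271 %% m
  s <- (s * 69621 + as.numeric(counter) * 40692 + 12345) %% m
  as.integer((s * 48271 + counter) %% m)
}

#' Trapezoidal integration over a frequency axis
#' @param x abscissae (strictly increasing).
#' @param y ordinates.
#' @return the trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Hann taper of length n (periodic form used by Welch averaging)
#' @keywords internal
hannWindow <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}
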