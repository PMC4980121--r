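# Internal helpers shared across modules.

# Deterministic substream seed derived from a global seed and a stream name.
# Keeps independent generators decoupled: adding a generator does not perturb
# the draws of another. Result is always a valid 32-bit integer seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 7919 + h * 104729 + 17) %% 2147483587)
}

# Evaluate expr with the RNG seeded from (seed, name), restoring the caller's
# RNG state afterwards so simulators never perturb user code.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' Round half-up at a fixed number of decimals
#'
#' The rounding convention used for reported percentages and rates (base
#' `round()` is round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Reverse complement for plain character vectors of A/C/G/T/N.
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
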