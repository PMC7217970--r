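## Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a component key to a derived seed, so that each
#' generator (panel, disorder pair, gene sets, ...) draws from its own
#' stream and adding a component never perturbs another's output. All
#' arithmetic stays below 2^53 and the result below 2^31.
#'
#' @param seed master seed (single finite number).
#' @param key character key naming the component/stream.
#' @return An integer seed.
#' @export
substreamSeed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(key)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 69069 + (abs(seed) %% 2147483647) * 1234567) %% 2147483629)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Truncate (not round) to a number of significant figures, matching how
# Bonferroni thresholds are conventionally displayed (0.05/18297 -> 2.7e-6).
truncSignif <- function(x, digits = 2L) {
  stopifnot(all(x > 0), digits >= 1L)
  e <- floor(log10(x))
  scale <- 10^(e - digits + 1)
  # tiny epsilon guards against 9.2249999... artefacts of binary floats
  floor(x / scale + 1e-9) * scale
}

# Standard-normal deviate of an upper-tail p, winsorised so clamped
# p-values (1e-300) do not produce +/-Inf in downstream regressions.
zFromP <- function(p) {
  z <- qnorm(p, lower.tail = FALSE)
  cap <- qnorm(1e-300, lower.tail = FALSE)
  pmin(pmax(z, -cap), cap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
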