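# Internal helpers: seeded sub-streams, seed-preserving evaluation, rounding.

# Deterministic sub-seed derived from a master seed and a stage label, so
# pipeline stages (facilities, participants, each matching method, ...) draw
# from independent reproducible streams and can be re-run in isolation.
# Arithmetic kept below 2^53 so it is exact in doubles; result < 2^26.
subSeed <- function(seed, label) {
  m <- 67108859  # prime < 2^26
  h <- 0
  for (c in utf8ToInt(as.character(label))) h <- (h * 31 + c) %% m
  h <- (h * 31 + (as.numeric(seed) %% m)) %% m
  as.integer(h) + 1L
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round() in R rounds half to even; summary tables use conventional half-up.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

isCount <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    x == as.integer(x)
}
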