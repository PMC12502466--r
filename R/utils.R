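#' @useDynLib mtlseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom sd var aov lm pf pt quantile setNames
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `expr` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(expr)
}

# Derive a stream-specific child seed from a global seed; keeps results
# decoupled across pipeline stages while remaining reproducible.
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647)
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 31 + ch) %% 2147483647
  }
  as.integer(max(1, x))
}

# Round half away from zero at `digits` decimals (printed-percentage rule).
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Tiny FNV-1a over a serialized object; used for manifest config hashes.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (R version stamp)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
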