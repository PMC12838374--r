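# internal helpers: seeded RNG scoping and a portable string hash

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so seeded package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and a stage label; keeps results
# decoupled across pipeline stages while remaining below 2^31.
derive_seed <- function(seed, what) {
  (as.double(seed) * 10007 + str_hash(what, 9973L)) %% 2147483647
}

# Deterministic polynomial rolling hash of a UTF-8 string, exact in doubles
# (all intermediates < 2^53), identical across platforms.
str_hash <- function(text, seed = 0L, mult = 31) {
  h <- as.double(seed)
  for (c in utf8ToInt(text)) h <- (h * mult + c) %% 2147483647
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
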