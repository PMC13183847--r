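# Internal helpers shared across modules.

# Signal a classed condition so callers/tests can match on class rather than
# on message text. All conditions inherit from "gy_error".
gy_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("gy_", class), "gy_error", "error", "condition")))
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards. Keeps all randomness flowing from explicit seeds, no global state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
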