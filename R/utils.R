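# Internal helpers shared across modules.

# Round-half-up (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wsi <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "wsidetect_error")))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a run seed; stays inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + as.numeric(k) * 12289) %% 2147483647
}
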