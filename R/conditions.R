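# Classed conditions so callers (and tests) can distinguish failure modes
# without string-matching messages.

stop_vocims <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "vocims_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

warn_vocims <- function(class, message) {
  cond <- structure(
    class = c(class, "vocims_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cond)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic code in the package funnels through
# this so one integer seed pins down every draw.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Counter-based seed derivation: sample i of a cohort gets a seed independent
# of generation order. Kept strictly below 2^31 - 1 (R integers are 32-bit).
seed_stream <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  a <- 48271      # MINSTD multiplier
  s <- (as.numeric(master) %% m) + 1
  as.integer((a * s + 65537 * as.numeric(index)) %% m)
}
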