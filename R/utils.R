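# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library calls never perturb user randomness.
with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Full-precision numeric formatting for XML/SVG attributes: %.17g round-trips
# IEEE doubles exactly, "60" stays "60".
fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Package-level mutable state (instrumentation counters).
.pd_state <- new.env(parent = emptyenv())
.pd_state$expand_passes <- 0L
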