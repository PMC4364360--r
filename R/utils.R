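#' @keywords internal
"_PACKAGE"

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# seed argument fully determines the result without clobbering the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# round-half-up, as opposed to base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
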