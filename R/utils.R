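#' @importFrom rlang %||% .data :=
#' @importFrom stats cor quantile rbeta rbinom runif rgamma sd setNames
NULL

# Seeded evaluation that restores the caller's RNG state afterwards, so
# package functions never perturb user-level random streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
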