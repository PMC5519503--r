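# Seed plumbing: one top-level seed, deterministic child seeds per stage.

#' Derive a deterministic child seed for a pipeline stage
#'
#' All stochastic stages of a run are driven by one top-level seed; each
#' stage uses a child seed derived by a fixed affine map so that stages are
#' decoupled (re-running one stage does not perturb another) yet the whole
#' run is reproducible from the single seed.
#'
#' @param seed top-level integer seed.
#' @param stage small integer stage index.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(stage)) %%
             2147483646)
}

# Evaluate an expression under a temporary RNG state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
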