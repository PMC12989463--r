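#' @keywords internal
"_PACKAGE"

## Seed substreams: every stochastic stage derives its own 32-bit seed from
## the master seed plus a stage label, so changing one stage's amount of
## random-number consumption never perturbs another stage's draws.

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' @param seed master integer seed.
#' @param label character stage label (e.g. `"rarefy"`, `"titan:perm"`).
#' @param index optional integer index for per-unit substreams.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  ## double-precision arithmetic is exact well beyond these magnitudes
  v <- (abs(seed) * 48271 + h * 16807 + index * 69621) %% (2^31 - 2)
  as.integer(v + 1)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Adjusted R-squared for an lm fit; kept explicit so evaluation code reads
## like the formula it implements.
adj_r2 <- function(fit) summary(fit)$adj.r.squared

`%||%` <- function(a, b) if (is.null(a)) b else a
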