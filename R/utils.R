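#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with a string label (and optional integer
#' qualifiers) into a new 31-bit seed, so that every stochastic stage of a
#' study (pedigree, EPDs, panel, gene drop per replicate, genotyping scheme,
#' optimizer per cell) runs on an independent, named random substream.
#'
#' @param seed master seed (single integer).
#' @param label character label of the substream, e.g. `"drop"`.
#' @param ... optional extra integers (replicate number, tier, ...).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "drop", 3) != derive_seed(1, "drop", 4)
derive_seed <- function(seed, label, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  extra <- c(...)
  codes <- c(utf8ToInt(as.character(label)), 257L, as.integer(extra))
  h <- as.double(seed) %% 2147483647
  for (k in codes) {
    # 32-bit-safe multiplicative mix (all arithmetic stays below 2^53)
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Half-up rounding to cents, used only for reported dollar figures.
round_cents <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
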