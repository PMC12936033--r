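#' Derive a stage seed from a master seed
#'
#' Every source of randomness in the pipeline draws its own seed from the one
#' master seed and a stage name, so stages are individually reproducible and
#' never collide. The derivation is a small deterministic integer hash kept
#' strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647                       # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
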