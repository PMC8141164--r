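#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' (cohort generation, train/test split, fold assignment, forest growing)
#' draws from its own substream so that adding a stage never perturbs the
#' draws of another. The substream seed is a deterministic 31-bit hash of the
#' master seed and the stream name.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the stream (e.g. "cohort", "split").
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(7, "cohort")
#' @export
derive_seed <- function(seed, name) {
  rm_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  rm_assert(is.character(name) && length(name) == 1 && nzchar(name),
            "stream name must be a non-empty string")
  mod <- 2147483647 # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- 5381
  for (c in utf8ToInt(name)) h <- (h * 33 + c) %% mod
  h <- (h + (abs(seed) %% mod) * 7919) %% mod
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, name),
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, name))
  expr
}
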