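#' Derive a stage-specific seed from a master seed
#'
#' Stage seeds are deterministic functions of the master seed and a stage
#' name, so individual pipeline stages can be rerun in isolation while a
#' single master seed still fixes the whole run.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # keep everything in double-safe range, then fold into 31 bits
  as.integer(((abs(seed) %% 2^20) * 1021 + (h * 2654435761) %% 2^30) %%
               .Machine$integer.max)
}

# rank of each element such that ties go to the earlier index: the result is
# always a permutation of 1..n (used for score ranks, which must be)
rank_permutation <- function(x, decreasing = FALSE) {
  ord <- order(x, seq_along(x), decreasing = c(decreasing, FALSE),
               method = "radix")
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

# evaluate `expr` with a locally-set RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

coexsub_log <- function(...) {
  message("[coexsub] ", ...)
}

# upper-triangle index pairs of an n x n matrix, as a 2-column matrix
upper_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
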