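#' Derive a deterministic 31-bit sub-seed from a base seed and counters
#'
#' Monte Carlo runs that are split into independent cells (sweep grid points,
#' reference runs, acceptance targets) each receive their own seed derived
#' from the user's base seed plus integer counters, so results are
#' independent of evaluation order and of any parallel scheduling.
#'
#' @param seed base integer seed.
#' @param ... further non-negative integer counters (model index, case index,
#'   grid indices, ...).
#' @return an integer in `[0, 2^31 - 2]`.
#' @examples
#' sub_seed(1, 2, 3)
#' @export
sub_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 in double arithmetic
  x <- 0
  for (v in idx) x <- (x * 69069 + (abs(v) %% m) + 1) %% m
  as.integer(x)
}

# Run `code` under a given seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
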