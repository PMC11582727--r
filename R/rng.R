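#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from a single root seed; participants,
#' blocks and analysis stages draw from child streams derived by this fixed
#' splitting rule, so any unit is reproducible in isolation. The rule is a
#' multiplicative integer mix modulo 2^31 - 19 (a prime), keeping results in
#' the 32-bit range `set.seed()` accepts.
#'
#' @param root integer root seed.
#' @param ... further non-negative integer indices (e.g. participant, block).
#' @return integer seed.
#' @export
derive_seed <- function(root, ...) {
  idx <- c(as.numeric(root), as.numeric(c(...)))
  m <- 2147483629  # 2^31 - 19
  h <- 17
  for (v in idx) {
    h <- (h * 2654435 + v + 1) %% m
  }
  as.integer(h)
}

local_seed <- function(seed) {
  # evaluate expr under a seed without disturbing the caller's RNG state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    restore <- function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
  set.seed(seed)
  restore
}

with_seed <- function(seed, expr) {
  restore <- local_seed(seed)
  on.exit(restore())
  force(expr)
}
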