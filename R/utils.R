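# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (dataset generation, splitting, ELM initialisation, swarm
#' updates, ...). Substream seeds are derived deterministically from the
#' master seed and a label so each stage can be reproduced in isolation.
#'
#' @param master integer master seed.
#' @param label character label of the substream (e.g. "split", "pso").
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1L, "split")
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master %% 2147483647)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` without clobbering the caller's RNG
# state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite number", name), call. = FALSE)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop(sprintf("`%s` out of range", name), call. = FALSE)
  }
  invisible(x)
}
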