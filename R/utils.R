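# Internal helpers shared across modules.

#' Evaluate code with a private RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so seeded generators never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive independent per-stage sub-seeds from one master seed.
# Kept below 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
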