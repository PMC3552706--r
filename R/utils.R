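#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state; the caller's .Random.seed is restored
# afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' Derive reproducible per-stage seeds from one master seed
#'
#' Each pipeline stage (discretization, subset search, each cross-validation
#' repeat, ...) draws its own seed from this sequence so that any stage can be
#' re-run in isolation with an identical random stream.
#'
#' @param master integer master seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of `n` seeds, each in `[1, 1e6]` (small enough
#'   that derived quantities like `seed * 1000 + repeat` stay well inside
#'   the 32-bit integer range).
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1L)
  with_seed(as.integer(master), sample.int(1000000L, n))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
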