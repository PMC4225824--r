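`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(..., call. = FALSE)

warn_ <- function(...) warning(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Draw a run-specific seed stream
#'
#' Derives `n` reproducible 32-bit sub-seeds from a master seed without
#' disturbing the caller's RNG state.
#' @noRd
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
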