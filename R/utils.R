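#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific 31-bit seed from a base seed and a label, so each
# generator consumes an independent, reproducible stream.
derive_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(label), 16)
  (as.integer(seed) %% 1000003L) * 1009L + sum(h * seq_along(h)) %% 100003L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
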