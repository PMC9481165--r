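#' @keywords internal
"_PACKAGE"

# Internal input-validation helpers. All user-facing errors are classed so
# callers (and the CLI) can distinguish bad input from estimation failure.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mvcnet_invalid_input", "error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mvcnet_estimation_failure", "error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mvcnet_config_error", "error")))
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a finite numeric scalar", name)
  invisible(x)
}

#' Seeded evaluation
#'
#' Runs `expr` under a fixed RNG seed and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  h <- digest::digest(list(as.integer(seed), as.character(stream)),
                      algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
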