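#' @keywords internal
"_PACKAGE"

# Run expr under a private RNG state so generators never disturb (or depend
# on) the caller's global stream. Each generator offsets the user seed by a
# fixed stream id so the same seed can drive several generators without
# producing correlated draws.
local_seed <- function(seed, stream = 0L, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (as.integer(seed) + 1013L * as.integer(stream)) %% .Machine$integer.max
  withr::with_seed(s, expr)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
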