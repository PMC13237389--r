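#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream rule: component i of a run seeded with `seed` uses
# seed_i = (seed + 7919 * i) mod (2^31 - 1). Documented in the methods
# vignette; keeps every derived seed a valid 32-bit integer.
substream_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("`%s` must be a single finite number", name)
  if (strict && x <= min) stop_config("`%s` must be > %g", name, min)
  if (!strict && x < min) stop_config("`%s` must be >= %g", name, min)
  invisible(x)
}
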