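# Internal helpers shared across modules.

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a global seed, stable across runs and
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483562) + 1L
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param("`%s` must be a single number in [0, 1], got %s", name,
               paste(format(x), collapse = ","))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
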