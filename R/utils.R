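`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporary RNG state so fitting helpers are reproducible
## without clobbering the caller's random stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Latin hypercube of n points in the box [lower, upper] (both named, same
## length), returned as an n x p matrix. Used for multistart initialisation.
lhs_box <- function(n, lower, upper) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  u <- lhs::randomLHS(n, length(lower))
  m <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(m) <- names(lower)
  m
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
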