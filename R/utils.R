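# round-half-up to integer minutes; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# validate a time grid: finite, >= 0, strictly increasing
check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0)) {
    stop("'times' must be finite and non-negative", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) > 1L && is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  times
}

check_scalar <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
  }
  as.numeric(x)
}

# run fn() under a temporary RNG seed, restoring the caller's RNG state
eval_with_seed <- function(seed, fn) {
  if (is.null(seed)) {
    return(fn())
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
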