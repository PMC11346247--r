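#' Convert firing rates from Hz to the internal ms^-1 scale
#'
#' All rates and thresholds are expressed internally in events per
#' millisecond; experimental reports usually quote Hz. A 25 Hz decision
#' threshold equals 0.025 ms^-1.
#'
#' @param x numeric, rate(s) in Hz.
#' @return numeric, the same rate(s) in ms^-1.
#' @examples
#' hz(25)
#' @export
hz <- function(x) x / 1000

# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
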