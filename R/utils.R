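#' @importFrom rlang %||%
#' @importFrom stats quantile rbinom runif
#' @importFrom utils modifyList
NULL

log_info <- function(..., .envir = parent.frame()) {
  message("[oralforce] ", sprintf(...))
}

abort_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# length-1 finite numeric check used by all parameter validators
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config("'%s' must be a single finite number", name)
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    abort_config("'%s' = %g is outside %s%g, %g]", name, x,
                 if (lower_open) "(" else "[", lower, upper)
  }
  if (integerish && x != round(x)) {
    abort_config("'%s' must be a whole number", name)
  }
  invisible(x)
}

check_fraction <- function(x, name, lower_open = FALSE) {
  check_scalar(x, name, lower = 0, upper = 1, lower_open = lower_open)
}

# derive an independent sub-seed per generator stream so regenerating one
# artefact does not perturb the others; kept well below 2^31
derive_seed <- function(seed, stream) {
  (abs(as.integer(seed)) %% 2000000L) * 1000L + as.integer(stream)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
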