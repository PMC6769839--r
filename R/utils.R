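#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish configuration problems from
# data problems programmatically.
hsim_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hsimargin_error")))
}

hsim_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "hsimargin_warning")))
}

#' Derive a stream seed from a master seed
#'
#' Counter-based derivation so that per-scene / per-fold seeds are
#' reproducible regardless of how many random draws earlier stages consumed.
#' Result stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 7919 + 1) %% 2147483587) + 1L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# logistic helpers used across classifiers
sigmoid <- function(x) stats::plogis(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
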