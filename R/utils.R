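#' Round half away from zero
#'
#' Base R's `round()` rounds half to even. The instrument's band tables are
#' printed at fixed precisions (integers for rates and pressures, one decimal
#' for temperature), and measured values are rounded half-up to that precision
#' before band lookup, so a dedicated rounding rule is part of the scoring
#' contract.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(0.5)       # 1, not 0
#' round_half_up(37.95, 1)  # 38.0
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition constructors: validation errors (bad data) are distinguished from
# configuration errors (bad tables/generator settings) so the CLI can map the
# former to exit status 2.
validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("pmews_validation_error", "error")))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("pmews_config_error", "error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.pmews_env <- new.env(parent = emptyenv())
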