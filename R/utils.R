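#' @keywords internal
#' @import methods
#' @importFrom stats rnorm runif rbinom
"_PACKAGE"

# Run expr under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Used wherever an operation needs its own reproducible stream (intercept
# calibration, fold assignment) without disturbing the session RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed; kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expit/logit on the natural scale
expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# 97.5% normal quantile used for all Wald 95% intervals
Z975 <- 1.959964

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
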