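# Internal helpers shared across modules.

# Evaluate `expr` under a private, seeded RNG stream, restoring the caller's
# RNG state afterwards so package randomness never perturbs user code.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Strict interior local maxima of a numeric vector, returned as 0-based
# indices (package-wide convention: temporal indices are 0-based frames).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  # which() over the interior window yields interior position = 0-based index
  which(x[i] > x[i - 1] & x[i] > x[i + 1])
}

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hbpnet_invalid_parameter")
}

stop_no_estimate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hbpnet_no_estimate")
}
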