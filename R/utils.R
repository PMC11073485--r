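# Internal helpers: classed conditions, smoothing, seeded evaluation.

if_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ifscreen_error"), call = call))
}

abort_malformed <- function(msg) if_error(msg, "if_malformed_error")
abort_config    <- function(msg) if_error(msg, "if_config_error")
abort_domain    <- function(msg) if_error(msg, "if_domain_error")
abort_fit       <- function(msg) if_error(msg, "if_fit_error")
abort_data      <- function(msg) if_error(msg, "if_data_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Centered moving average with edge shrinkage; k forced odd.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (k - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict interior local minima (plateaus take their first index).
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # collapse zero runs by carrying the previous sign forward
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(s[-1L] > 0 & s[-length(s)] < 0) + 1L
}

# Deterministic 32-bit seed stream: mixes a base seed with an index.
mix_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 1299721) %% 2147483647
  as.integer(x)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Linear resampling of y (on an implicit uniform grid) to m points.
resample_uniform <- function(y, m) {
  n <- length(y)
  if (n == m) return(y)
  stats::approx(seq(0, 1, length.out = n), y, xout = seq(0, 1, length.out = m))$y
}
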