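# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "stentfai_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Moving average with window shrinking at the ends (odd window); the first
# and last samples are preserved so smoothing does not erode a curve's
# endpoints.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  half <- window %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out[1L] <- x[1L]
  out[n] <- x[n]
  out
}
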