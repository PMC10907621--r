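## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All generators funnel their randomness through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Centered moving average with window w (odd); ends use shrinking
## symmetric windows so the output has the same length as the input.
movingAverage <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## Running median with window 3 (ends passed through).
medianFilter3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1L)] <- vapply(2:(n - 1L), function(i) {
    median(x[(i - 1L):(i + 1L)])
  }, numeric(1))
  out
}

## Otsu threshold on a 256-bin histogram of the data range.
otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(as.numeric(h))
  mu <- cumsum(h * mids)
  tot <- w[nbins]
  mu_t <- mu[nbins]
  w0 <- w[-nbins]
  w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu_t * w0[valid] - tot * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  mids[which.max(between)]
}

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
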