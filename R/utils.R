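# Internal helpers: seeded evaluation, Gaussian/boxcar smoothing, FFT-based
# zero-phase filtering and the analytic signal. No signal-processing package
# is assumed; filters are implemented in the frequency domain with the
# magnitude-squared Butterworth response, which is exactly the transfer
# function of forward-backward ("filtfilt") filtering and has zero phase.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed < 2^31 from a parent seed and a stream label.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

#' @keywords internal
gauss_kernel <- function(sd_samples, radius = ceiling(4 * sd_samples)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sd_samples^2))
  k / sum(k)
}

# NA-aware smoothing with edge renormalization: convolve both the series and
# an indicator of finite samples, then divide. Missing samples stay missing.
smooth_series <- function(x, kernel) {
  n <- length(x)
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  conv_same <- function(v) {
    r <- (length(kernel) - 1L) / 2L
    padded <- c(rep(0, r), v, rep(0, r))
    stats::filter(padded, kernel, sides = 2)[(r + 1L):(r + n)]
  }
  num <- conv_same(x0)
  den <- conv_same(as.numeric(ok))
  out <- as.numeric(num / den)
  out[!ok] <- NA_real_
  out
}

gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  smooth_series(x, gauss_kernel(sd_samples))
}

boxcar_smooth <- function(x, width_samples) {
  w <- max(1L, as.integer(width_samples))
  if (w %% 2L == 0L) w <- w + 1L
  smooth_series(x, rep(1 / w, w))
}

# Squared-magnitude Butterworth response at frequencies f (Hz).
butter_mag2 <- function(f, order, low = NULL, high = NULL) {
  h <- rep(1, length(f))
  if (!is.null(high)) h <- h / (1 + (f / high)^(2 * order))         # low-pass edge
  if (!is.null(low)) {
    hp <- ifelse(f == 0, 0, 1 / (1 + (low / pmax(f, .Machine$double.eps))^(2 * order)))
    h <- h * hp                                                     # high-pass edge
  }
  h
}

# Zero-phase Butterworth filtering via FFT. `low` and `high` are the band
# edges in Hz (NULL = unbounded side). Reflection padding suppresses the
# circular wrap-around at the edges.
filtfilt_butter <- function(x, fs, order = 4, low = NULL, high = NULL) {
  n <- length(x)
  npad <- min(n, as.integer(3 * fs / max(low %||% 1, 1)))
  npad <- max(npad, min(n, 256L))
  xe <- c(rev(x[seq_len(npad)]), x, rev(x[(n - npad + 1L):n]))
  m <- length(xe)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)  # two-sided absolute frequency axis
  h <- butter_mag2(f, order = order, low = low, high = high)
  y <- Re(stats::fft(stats::fft(xe) * h, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

# Analytic signal (FFT Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Poisson deviance machinery shared by the encoding module (unit tests pin
# it against hand-computed sums).
poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}
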