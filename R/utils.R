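# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All exported stochastic operations route their randomness through
# this so that identical seeds give bit-identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Analytic signal via the frequency-domain construction (zero out negative
# frequencies, double positive ones).  Returns a complex vector.
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase application of a linear-phase FIR filter (odd length, symmetric):
# reflect-pad, convolve, and remove the integer group delay.
fir_zerophase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  d <- (m - 1L) %/% 2L
  pad <- min(m, n - 1L)
  xe <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- stats::filter(xe, h, method = "convolution", sides = 1L)
  y <- as.numeric(y)
  y[(pad + d + 1L):(pad + d + n)]
}

# Zero-phase IIR filtering robust to DC offsets and edge transients:
# mean-center, reflect-pad by `pad` samples (capped at n - 1), filtfilt, trim,
# restore the mean.  `signal::filtfilt` starts each pass from a zero state, so
# without this a signal with a large baseline acquires edge artifacts
# comparable to the baseline itself at low cut-offs.
filtfilt_pad <- function(bf, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  mu <- mean(x)
  xe <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)])) - mu
  y <- signal::filtfilt(bf, xe)
  y[(pad + 1L):(pad + n)] + mu
}

# Resample a uniformly sampled series to a new rate.  Downsampling goes through
# block averaging (coarse anti-alias) followed by a Butterworth low-pass at
# 0.45 * fs_out and linear interpolation onto the exact output grid;
# upsampling is plain linear interpolation.  Adequate for the very-low-frequency
# signals (EDA, envelopes) this package moves between rates.
resample_uniform <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0, length(x) >= 2L)
  if (fs_in == fs_out) return(x)
  t_in <- (seq_along(x) - 1L) / fs_in
  dur <- t_in[length(t_in)]
  t_out <- seq(0, dur, by = 1 / fs_out)
  if (fs_in < fs_out) {
    return(stats::approx(t_in, x, xout = t_out, rule = 2)$y)
  }
  m <- floor(fs_in / (4 * fs_out))
  if (m >= 2L) {
    nb <- floor(length(x) / m)
    xb <- colMeans(matrix(x[seq_len(nb * m)], nrow = m))
    fs1 <- fs_in / m
    t1 <- (seq_along(xb) - 1L) / fs1 + (m - 1) / (2 * fs_in)
  } else {
    xb <- x
    fs1 <- fs_in
    t1 <- t_in
  }
  wn <- 0.9 * fs_out / fs1  # = (0.45 * fs_out) / (fs1 / 2)
  if (wn < 0.95 && length(xb) > 12L) {
    bf <- signal::butter(2, wn)
    xb <- filtfilt_pad(bf, xb, ceiling(6 / wn))
  }
  stats::approx(t1, xb, xout = t_out, rule = 2)$y
}

# Population standard deviation (divisor N).
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

stop_if_not_finite <- function(x, what = "signal") {
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop(sprintf("%s contains %d non-finite sample(s); first at index %d",
                 what, length(bad), bad[1L]), call. = FALSE)
  }
  invisible(x)
}
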