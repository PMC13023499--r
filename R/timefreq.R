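#' Complex Morlet mother wavelet
#'
#' The product of a Gaussian envelope and a complex carrier,
#' \deqn{\psi(\eta) = (\pi f_b)^{-1/2} \exp(-\eta^2/f_b) \exp(j 2 \pi f_c \eta),}
#' where `fb` is the non-dimensional bandwidth, `fc` the non-dimensional
#' center frequency, and `eta` non-dimensional time.  The squared-magnitude
#' integral (wavelet energy) has the closed form \eqn{1/\sqrt{2 \pi f_b}}, so
#' the \eqn{(\pi f_b)^{-1/2}} factor keeps the energy finite and stable across
#' bandwidth choices.
#'
#' @param eta Numeric vector of non-dimensional times.
#' @param fb Bandwidth parameter (> 0), default 1.5.
#' @param fc Center-frequency parameter, default 1.
#' @return Complex vector of wavelet values; the magnitude is maximal at
#'   `eta = 0`, where it equals `(pi * fb)^(-1/2)`.
#' @export
cmorlet <- function(eta, fb = 1.5, fc = 1) {
  if (fb <= 0) stop("fb must be positive")
  exp(-eta^2 / fb) / sqrt(pi * fb) * exp(2i * pi * fc * eta)
}

#' Log-spaced wavelet scales covering a frequency band
#'
#' Maps a target pseudo-frequency band onto wavelet scales through
#' `f = fc * fs / a` (scales in samples), log-spaced so that the returned
#' pseudo-frequencies span `[f_min, f_max]` exactly.
#'
#' @param f_min,f_max Band limits in Hz, `0 < f_min < f_max <= fs/2`.
#' @param n_scales Number of scales (default 25).
#' @param fc Wavelet center-frequency parameter (default 1).
#' @param fs Sampling rate in Hz.
#' @return Strictly increasing numeric vector of scales with attribute
#'   `frequencies` (the corresponding pseudo-frequencies, decreasing in `a`).
#' @export
scales_for_band <- function(f_min, f_max, n_scales = 25L, fc = 1, fs = 200) {
  stopifnot(f_min > 0, f_max > f_min, n_scales >= 2L)
  if (f_max > fs / 2) stop("f_max exceeds the Nyquist frequency")
  f <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  a <- fc * fs / f
  attr(a, "frequencies") <- f
  a
}

#' Continuous wavelet transform scaleogram (complex Morlet)
#'
#' Evaluates \eqn{CWT(a, b) = \sum_k x[k] \, a^{-1/2} \psi((k - b)/a)} on a
#' discrete translation grid, for each scale, via FFT convolution (sample-time
#' convention: `eta` is measured in samples divided by the scale, so the
#' pseudo-frequency of scale `a` is `fc * fs / a` Hz; the \eqn{a^{-1/2}}
#' factor equalizes daughter-wavelet energy across scales).  Coefficients
#' whose wavelet support (Gaussian envelope truncated where it falls below
#' 1e-4 of its peak) extends beyond the signal are flagged as edge-affected.
#'
#' @param signal Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param scales Positive scales (samples), e.g. from [scales_for_band()].
#' @param fb,fc Wavelet parameters (defaults 1.5 and 1).
#' @param translation_step_s Spacing of the translation grid in seconds
#'   (default 1).
#' @return Object of class `scaleogram`: list with `coefficients` (complex,
#'   scales x translations), `edge` (logical, same shape), `scales`,
#'   `frequencies`, `translations` (seconds), `fb`, `fc`, `fs`.
#' @export
cwt_scaleogram <- function(signal, fs, scales, fb = 1.5, fc = 1,
                           translation_step_s = 1) {
  stopifnot(all(scales > 0), fs > 0)
  stop_if_not_finite(signal, "signal")
  scales <- sort(scales)
  n <- length(signal)
  b_step <- max(1L, round(translation_step_s * fs))
  bidx <- seq(1L, n, by = b_step)
  eta_max <- sqrt(fb * log(1e4))
  coef <- matrix(0i, nrow = length(scales), ncol = length(bidx))
  edge <- matrix(FALSE, nrow = length(scales), ncol = length(bidx))
  for (si in seq_along(scales)) {
    a <- scales[si]
    L <- ceiling(a * eta_max)
    m <- seq(-L, L)
    w <- cmorlet(m / a, fb, fc) / sqrt(a)
    M <- stats::nextn(n + 2L * L + 1L)
    xp <- complex(real = c(signal, rep(0, M - n)))
    vp <- complex(length.out = M)
    # circular convolution kernel v[u] = w[-u]
    vp[1L] <- w[L + 1L]
    vp[1L + seq_len(L)] <- w[L:1L]               # v[u] = w[-u], u = 1..L
    vp[M + 1L - seq_len(L)] <- w[L + 1L + seq_len(L)]  # v[-u] = w[u]
    cc <- stats::fft(stats::fft(xp) * stats::fft(vp), inverse = TRUE) / M
    coef[si, ] <- cc[bidx]
    edge[si, ] <- (bidx - 1L) < L | (bidx - 1L) > (n - 1L - L)
  }
  structure(
    list(coefficients = coef, edge = edge, scales = scales,
         frequencies = fc * fs / scales,
         translations = (bidx - 1L) / fs, fb = fb, fc = fc, fs = fs),
    class = "scaleogram"
  )
}

#' @export
print.scaleogram <- function(x, ...) {
  cat(sprintf(
    "C-Morlet scaleogram: %d scales (%.4g-%.4g Hz), %d translations, fb=%g fc=%g\n",
    length(x$scales), min(x$frequencies), max(x$frequencies),
    length(x$translations), x$fb, x$fc))
  invisible(x)
}

#' Pooled magnitude statistics of a scaleogram over a time window
#'
#' Pools `|coefficients|` over the translations falling in the half-open time
#' range `[window[1], window[2])` seconds.  With `exclude_edges = TRUE`
#' (default) the pool is restricted to scales whose wavelet support fits the
#' record at all (scales with no edge-free coefficient anywhere are dropped);
#' the kept scales contribute every in-window translation, so the pooled grid
#' is identical for every window of a trial and window statistics are
#' comparable across window positions.  If no scale survives, all are used.
#'
#' @param scaleogram A `scaleogram` object.
#' @param window Numeric pair `c(t0, t1)` in seconds.
#' @param exclude_edges Drop scales that are edge-affected everywhere
#'   (default TRUE).
#' @return Named numeric vector `c(mean, std)` (population standard
#'   deviation).
#' @export
wavelet_window_features <- function(scaleogram, window, exclude_edges = TRUE) {
  stopifnot(inherits(scaleogram, "scaleogram"), length(window) == 2L)
  sel <- scaleogram$translations >= window[1L] & scaleogram$translations < window[2L]
  if (!any(sel)) stop("window contains no translation grid points")
  keep <- rep(TRUE, length(scaleogram$scales))
  if (exclude_edges) {
    ok <- rowSums(!scaleogram$edge) > 0
    if (any(ok)) keep <- ok
  }
  mags <- Mod(scaleogram$coefficients[keep, sel, drop = FALSE])
  c(mean = mean(mags), std = sd_pop(as.numeric(mags)))
}

#' Variable frequency complex demodulation (VFCDM) of a signal
#'
#' Decomposes a real signal into band-limited sinusoidal modulation
#' components on a bank of center frequencies `f_oi = (i - 1) * 2 * F_w`
#' (`i = 1` is the DC band).  Each band is obtained by complex demodulation:
#' multiply by `exp(-j 2 pi f_oi t)`, low-pass with a zero-phase linear-phase
#' FIR filter of bandwidth `F_w` and order `N_w`, and remodulate; the filtered
#' analytic product gives first-pass instantaneous amplitude
#' `A(t) = 2 |z_LP(t)|` and phase `arg z_LP(t)`.  A final Hilbert-transform
#' refinement of each real component yields the instantaneous amplitude,
#' phase, and frequency reported, from which the full time-frequency spectrum
#' can be assembled.
#'
#' @param signal Real numeric vector (length well above the filter length).
#' @param fs Sampling rate in Hz.
#' @param F_w Filter (half-)bandwidth in Hz; neighboring center frequencies
#'   are `2 * F_w` apart.  Default 0.03 Hz.
#' @param N_w FIR filter order (taps - 1); default 128.  The filter is
#'   normalized to unit DC gain, so a tone at a band center is recovered with
#'   unit amplitude; shorter filters leak appreciably into neighboring bands
#'   at the default bandwidth.
#' @return Object of class `vfcdm`: list with `dc` (DC-band component),
#'   `components` (matrix, samples x bands, excluding DC),
#'   `center_frequencies` (Hz, excluding DC), `inst_amplitude`,
#'   `inst_frequency`, `inst_phase` (matrices matching `components`),
#'   `F_w`, `N_w`, `fs`.  `dc + rowSums(components)` reconstructs the input
#'   up to filter-bank leakage.
#' @export
vfcdm_decompose <- function(signal, fs, F_w = 0.03, N_w = 128L) {
  stopifnot(F_w > 0, N_w >= 8L)
  stop_if_not_finite(signal, "signal")
  n <- length(signal)
  if (n < 1.5 * (N_w + 1L)) stop("signal too short for the VFCDM filter length")
  f_max <- fs / 2
  n_bands <- floor(f_max / (2 * F_w))
  if (n_bands < 2L) stop("F_w too large: fewer than 2 bands below f_max")
  centers <- (seq_len(n_bands) - 1L) * 2 * F_w
  h <- signal::fir1(N_w, F_w / (fs / 2))
  h <- h / sum(h)  # unit DC gain
  # Reflect-pad the *input* once, and demodulate on the padded time axis, so
  # locally smooth signals demodulate to smooth complex exponentials and the
  # filter sees no artificial kink at the record boundaries.
  P <- min(N_w, n - 1L)
  xe <- c(rev(signal[2L:(P + 1L)]), signal, rev(signal[(n - P):(n - 1L)]))
  te <- (seq_along(xe) - 1L - P) / fs
  d_delay <- (length(h) - 1L) %/% 2L
  conv_center <- function(x) {
    y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1L))
    y[(P + d_delay + 1L):(P + d_delay + n)]
  }
  # filtered series over the whole padded axis, group delay removed; entries
  # before index d_delay + 1 and after length(xe) - d_delay are invalid
  conv_pad <- function(x) {
    y <- as.numeric(stats::filter(c(x, numeric(d_delay)), h,
                                  method = "convolution", sides = 1L))
    y[(d_delay + 1L):(d_delay + length(x))]
  }
  dc <- conv_center(xe)
  K <- n_bands - 1L
  comps <- matrix(0, n, K)
  amp <- matrix(0, n, K)
  phs <- matrix(0, n, K)
  frq <- matrix(0, n, K)
  core <- (P + 1L):(P + n)
  valid <- (d_delay + 1L):(length(xe) - d_delay)
  for (i in seq_len(K)) {
    f0 <- centers[i + 1L]
    carrier_e <- exp(-2i * pi * f0 * te)
    z <- xe * carrier_e
    zlp_e <- complex(real = conv_pad(Re(z)), imaginary = conv_pad(Im(z)))
    d_e <- 2 * Re(zlp_e * Conj(carrier_e))
    comps[, i] <- d_e[core]
    # Hilbert refinement of the real component, over the valid padded span
    u <- analytic_signal(d_e[valid])[core - d_delay]
    amp[, i] <- Mod(u)
    ph <- signal::unwrap(Arg(u))
    phs[, i] <- ph
    dph <- c(ph[2L] - ph[1L], (ph[3L:n] - ph[1L:(n - 2L)]) / 2, ph[n] - ph[n - 1L])
    frq[, i] <- dph * fs / (2 * pi)
  }
  structure(
    list(dc = dc, components = comps, center_frequencies = centers[-1L],
         inst_amplitude = amp, inst_frequency = frq, inst_phase = phs,
         F_w = F_w, N_w = as.integer(N_w), fs = fs),
    class = "vfcdm"
  )
}

#' @export
print.vfcdm <- function(x, ...) {
  cat(sprintf("VFCDM decomposition: %d components at %s Hz (F_w=%g, N_w=%d, fs=%g)\n",
              ncol(x$components),
              paste(signif(x$center_frequencies, 3), collapse = ", "),
              x$F_w, x$N_w, x$fs))
  invisible(x)
}

#' Time-varying sympathetic-tone index (TVSymp) of an EDA signal
#'
#' Sums the VFCDM instantaneous amplitudes of the components whose center
#' frequencies fall in the sympathetic band (default 0.08-0.24 Hz) and
#' normalizes the resulting series to unit variance over the recording.  The
#' decomposition runs at a 2 Hz internal rate (the band of interest lies far
#' below 1 Hz); the index is returned resampled onto the input time grid.
#'
#' @param signal Positive numeric vector, skin conductance in microsiemens.
#' @param fs Input sampling rate in Hz.
#' @param band Numeric pair, component-center band in Hz (default
#'   `c(0.08, 0.24)`).
#' @param fs_internal Internal VFCDM rate in Hz (default 2).
#' @param F_w,N_w VFCDM filter parameters, see [vfcdm_decompose()].
#' @return Numeric vector, same length as `signal`, standard deviation 1,
#'   with attributes `sd_raw` (the pre-normalization amplitude scale in uS)
#'   and `band`.
#' @export
tvsymp <- function(signal, fs, band = c(0.08, 0.24), fs_internal = 2,
                   F_w = 0.03, N_w = 128L) {
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  if (band[2L] > fs_internal / 2) stop("band exceeds the internal Nyquist frequency")
  x2 <- if (fs == fs_internal) signal else resample_uniform(signal, fs, fs_internal)
  v <- vfcdm_decompose(x2, fs_internal, F_w = F_w, N_w = N_w)
  sel <- v$center_frequencies >= band[1L] & v$center_frequencies <= band[2L]
  if (!any(sel)) {
    stop(sprintf("no VFCDM component centers inside [%g, %g] Hz; available: %s",
                 band[1L], band[2L],
                 paste(signif(v$center_frequencies, 3), collapse = ", ")))
  }
  amp <- rowSums(v$inst_amplitude[, sel, drop = FALSE])
  out <- if (fs == fs_internal) amp else {
    t2 <- (seq_along(amp) - 1L) / fs_internal
    tt <- (seq_along(signal) - 1L) / fs
    stats::approx(t2, amp, xout = tt, rule = 2)$y
  }
  s <- stats::sd(out)
  if (!is.finite(s) || s == 0) stop("degenerate TVSymp series (zero variance)")
  res <- out / s
  attr(res, "sd_raw") <- s
  attr(res, "band") <- band
  res
}
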