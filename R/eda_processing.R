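#' Decompose an EDA signal into tonic and phasic components
#'
#' Splits skin conductance into a slowly varying tonic level (skin conductance
#' level, below 0.05 Hz) and a fast phasic residual (skin conductance
#' responses, 0.05-0.15 Hz band and above).  The default `"lowpass"` method is
#' a zero-phase Butterworth low-pass split at `f_split`: the filtering is done
#' at a low internal rate (signal content this far below 1 Hz makes direct IIR
#' filtering at hundreds of Hz numerically fragile), the tonic estimate is
#' interpolated back to the input grid, and `phasic = signal - tonic`, so the
#' decomposition is exactly additive.  The `"sparse-deconvolution"` method
#' additionally peels smoothed positive phasic activity off the low-pass tonic
#' estimate before re-smoothing, a closer stand-in for driver-based
#' decompositions when large responses would otherwise leak into the tonic.
#'
#' @param signal Positive numeric vector, skin conductance in microsiemens.
#' @param fs Sampling rate in Hz.
#' @param method `"lowpass"` (default) or `"sparse-deconvolution"`.
#' @param f_split Tonic/phasic split frequency in Hz (default 0.05).
#' @return Object of class `eda_decomposition`: list with `tonic`, `phasic`
#'   (same length as input, `tonic + phasic == signal` exactly) and `fs`.
#' @export
decompose_eda <- function(signal, fs, method = c("lowpass", "sparse-deconvolution"),
                          f_split = 0.05) {
  method <- match.arg(method)
  stopifnot(is.numeric(signal), fs > 0)
  stop_if_not_finite(signal, "EDA signal")
  if (length(signal) < 10 * fs) stop("need at least 10 s of EDA signal")
  fs_lo <- max(4 * f_split * 10, 2)  # 2 Hz for the default split
  x_lo <- resample_uniform(signal, fs, fs_lo)
  bf <- signal::butter(2, f_split / (fs_lo / 2))
  pad <- ceiling(3 * fs_lo / f_split)
  tonic_lo <- filtfilt_pad(bf, x_lo, pad)
  if (method == "sparse-deconvolution") {
    resid <- pmax(x_lo - tonic_lo, 0)
    tonic_lo <- filtfilt_pad(bf, x_lo - resid, pad)
  }
  t_lo <- (seq_along(tonic_lo) - 1L) / fs_lo
  t_in <- (seq_along(signal) - 1L) / fs
  tonic <- stats::approx(t_lo, tonic_lo, xout = t_in, rule = 2)$y
  structure(list(tonic = tonic, phasic = signal - tonic, fs = fs),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("EDA decomposition: %d samples at %g Hz (tonic mean %.3f uS)\n",
              length(x$tonic), x$fs, mean(x$tonic)))
  invisible(x)
}

#' Detect skin conductance response (SCR) events in a phasic trace
#'
#' Finds local maxima of the phasic component, takes each event's onset as the
#' last local minimum preceding the peak, and keeps events whose
#' onset-to-peak amplitude reaches `amp_threshold`.  The trace is first
#' smoothed with a zero-phase low-pass at `smooth_hz` so that measurement
#' noise does not masquerade as micro-events; genuine responses (rise times
#' near a second) pass unchanged.  Events are returned in onset order.
#'
#' @param phasic Numeric vector (phasic EDA, microsiemens).
#' @param fs Sampling rate in Hz.
#' @param amp_threshold Minimum onset-to-peak amplitude in microsiemens.
#'   Default 0.05 uS (configurable; see the package vignette for why the
#'   much larger thresholds sometimes quoted for raw skin conductance are not
#'   appropriate for phasic response amplitudes).
#' @param smooth_hz Pre-detection smoothing cut-off in Hz (default 1); 0
#'   disables smoothing.
#' @return A data.frame with one row per event: `onset_index`, `peak_index`
#'   (1-based sample indices), `amplitude` (uS), `rise_time_s`
#'   (`(peak_index - onset_index) / fs`).  Empty input gives zero rows.
#' @export
detect_scr_events <- function(phasic, fs, amp_threshold = 0.05, smooth_hz = 1) {
  stopifnot(fs > 0, amp_threshold > 0)
  empty <- data.frame(onset_index = integer(), peak_index = integer(),
                      amplitude = numeric(), rise_time_s = numeric())
  n <- length(phasic)
  if (n < 3L) return(empty)
  stop_if_not_finite(phasic, "phasic signal")
  if (smooth_hz > 0 && fs > 2.5 * smooth_hz && n > 12L) {
    bf <- signal::butter(2, smooth_hz / (fs / 2))
    phasic <- filtfilt_pad(bf, phasic, ceiling(3 * fs / smooth_hz))
  }
  d <- diff(phasic)
  s <- sign(d)
  # peaks: slope turns non-positive after positive; onsets: slope turns
  # positive after non-positive (covers flat baselines before a response)
  peaks <- which(s[-length(s)] > 0 & s[-1L] <= 0) + 1L
  mins <- which(s[-length(s)] <= 0 & s[-1L] > 0) + 1L
  mins <- c(1L, mins)  # series start counts as a candidate onset
  if (!length(peaks)) return(empty)
  onset <- vapply(peaks, function(p) {
    cand <- mins[mins < p]
    if (length(cand)) max(cand) else NA_integer_
  }, integer(1L))
  keep <- !is.na(onset)
  peaks <- peaks[keep]; onset <- onset[keep]
  amp <- phasic[peaks] - phasic[onset]
  keep <- amp >= amp_threshold
  ev <- data.frame(onset_index = onset[keep], peak_index = peaks[keep],
                   amplitude = amp[keep],
                   rise_time_s = (peaks[keep] - onset[keep]) / fs)
  ev[order(ev$onset_index), , drop = FALSE]
}

#' Aggregate SCR events over an observation window
#'
#' Events whose *peak* falls inside the half-open sample range
#' `[window[1], window[2])` are counted and averaged.  A window containing no
#' peaks reports `(0, 0, 0)` rather than missing values, so downstream binning
#' never sees gaps (documented convention).
#'
#' @param events Event table from [detect_scr_events()].
#' @param window Integer pair `c(start, end)`, half-open 1-based sample range.
#' @param fs Sampling rate in Hz (unused in the aggregation itself; kept so
#'   window specifications stay uniform across feature extractors).
#' @return Named numeric vector `c(scr_count, scr_ampl_mean, scr_riset_mean)`.
#' @export
scr_window_features <- function(events, window, fs) {
  stopifnot(length(window) == 2L, window[2L] >= window[1L])
  sel <- events$peak_index >= window[1L] & events$peak_index < window[2L]
  if (!any(sel)) {
    return(c(scr_count = 0, scr_ampl_mean = 0, scr_riset_mean = 0))
  }
  c(scr_count = sum(sel),
    scr_ampl_mean = mean(events$amplitude[sel]),
    scr_riset_mean = mean(events$rise_time_s[sel]))
}

#' Mean and population standard deviation of a component over a window
#'
#' @param component Numeric vector (e.g. tonic or phasic EDA).
#' @param window Integer pair `c(start, end)`, half-open 1-based sample range,
#'   non-empty and within the sequence.
#' @return Named numeric vector `c(mean, std)`; `std` uses divisor N
#'   (population form).
#' @export
component_window_stats <- function(component, window) {
  stopifnot(length(window) == 2L)
  if (window[2L] <= window[1L]) stop("empty window")
  if (window[1L] < 1L || window[2L] > length(component) + 1L) {
    stop("window outside the sequence")
  }
  seg <- component[window[1L]:(window[2L] - 1L)]
  c(mean = mean(seg), std = sd_pop(seg))
}
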