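#' Alpha-band (8-13 Hz) zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase); stop-band
#' attenuation exceeds 20 dB by 6 Hz and 16 Hz.
#'
#' @param eeg Numeric vector, EEG in microvolts.
#' @param fs Sampling rate in Hz, at least 26 Hz (twice the upper band edge).
#' @param band Pass band in Hz, default `c(8, 13)`.
#' @return Filtered signal, same length.
#' @export
bandpass_alpha <- function(eeg, fs, band = c(8, 13)) {
  stopifnot(length(band) == 2L, band[1L] > 0, band[2L] > band[1L])
  if (fs < 2 * band[2L]) stop("sampling rate below twice the upper band edge")
  stop_if_not_finite(eeg, "EEG")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, eeg)
}

#' Window alpha power
#'
#' Time-domain power \eqn{\frac{1}{N} \sum_{n=1}^{N} x[n]^2} of a band-pass
#' filtered channel over a half-open sample window, in microvolts squared.
#'
#' @param filtered Alpha-band filtered EEG (from [bandpass_alpha()]).
#' @param window Integer pair `c(start, end)`, half-open 1-based sample range.
#' @return Power in uV^2.
#' @export
window_alpha_power <- function(filtered, window) {
  stopifnot(length(window) == 2L)
  if (window[2L] <= window[1L]) stop("empty window")
  if (window[1L] < 1L || window[2L] > length(filtered) + 1L) {
    stop("window outside the sequence")
  }
  seg <- filtered[window[1L]:(window[2L] - 1L)]
  mean(seg^2)
}

#' Normalized-ratio frontal alpha asymmetry
#'
#' \eqn{(R - L) / (R + L)} of right (F8) and left (F7) window alpha powers;
#' bounded in \[-1, 1\].  Positive values indicate relatively greater
#' right-alpha power, i.e. greater left cortical activation
#' (approach-related affect).
#'
#' @param l_power,r_power Left and right window alpha powers (uV^2),
#'   non-negative, not both zero.
#' @return Unitless asymmetry in \[-1, 1\].
#' @export
faa_ratio <- function(l_power, r_power) {
  stopifnot(l_power >= 0, r_power >= 0)
  if (l_power + r_power == 0) stop("both alpha powers are zero: FAA undefined")
  (r_power - l_power) / (r_power + l_power)
}

#' Logarithmic frontal alpha asymmetry
#'
#' \eqn{\log(R) - \log(L)} (natural log) of right and left window alpha
#' powers; antisymmetric in the two channels and always sign-consistent with
#' [faa_ratio()].
#'
#' @param l_power,r_power Left and right window alpha powers (uV^2), both
#'   strictly positive.
#' @return Unitless log-asymmetry.
#' @export
faa_log <- function(l_power, r_power) {
  if (l_power <= 0 || r_power <= 0) stop("log asymmetry requires strictly positive powers")
  log(r_power) - log(l_power)
}

#' Alpha-band amplitude envelope
#'
#' Band-passes an EEG channel to 8-13 Hz, takes the analytic-signal magnitude,
#' and smooths it with a zero-phase low-pass (default 2 Hz).  This is the
#' sample sequence entering the mutual-information FAA variant.
#'
#' @param eeg Numeric vector, EEG in microvolts.
#' @param fs Sampling rate in Hz.
#' @param smooth_hz Envelope smoothing cut-off in Hz (default 2).
#' @param band Alpha band in Hz, default `c(8, 13)`.
#' @return Non-negative envelope, same length as input.
#' @export
alpha_envelope <- function(eeg, fs, smooth_hz = 2, band = c(8, 13)) {
  a <- bandpass_alpha(eeg, fs, band)
  env <- Mod(analytic_signal(a))
  bf <- signal::butter(2, smooth_hz / (fs / 2))
  pmax(filtfilt_pad(bf, env, ceiling(3 * fs / smooth_hz)), 0)
}

#' Mutual-information frontal alpha asymmetry
#'
#' The information-theoretic FAA variant: Miller-Madow corrected mutual
#' information (bits) between the left and right alpha-band amplitude
#' envelopes sampled within one observation window, after equal-frequency
#' binning of each side (see [mutual_information_mm()]).  Unlike the ratio and
#' log variants it is sign-free: it measures how strongly the two hemispheric
#' alpha amplitudes co-vary, whatever the direction.
#'
#' @param left_alpha,right_alpha Equal-length envelope sequences (from
#'   [alpha_envelope()]), at least `5 * n_bins` samples, non-constant.
#' @param n_bins Equal-frequency bins (default 12).
#' @return Mutual information in bits.
#' @export
faa_mi <- function(left_alpha, right_alpha, n_bins = 12L) {
  stopifnot(length(left_alpha) == length(right_alpha))
  if (length(left_alpha) < 5L * n_bins) {
    stop("window too short for the requested number of bins")
  }
  if (length(unique(left_alpha)) < n_bins || length(unique(right_alpha)) < n_bins) {
    stop("degenerate envelope (too few distinct values) for equal-frequency binning")
  }
  as.numeric(mutual_information_mm(left_alpha, right_alpha, n_bins))
}
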