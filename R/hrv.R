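#' Root mean square of successive differences (RMSSD)
#'
#' \eqn{\sqrt{\frac{1}{N-1} \sum_{i=1}^{N-1} (RR_{i+1} - RR_i)^2}} over a
#' series of N R-R intervals in milliseconds; the standard short-window
#' time-domain index of parasympathetically mediated heart-rate variability.
#'
#' @param rr_ms Numeric vector of R-R intervals (ms), length >= 2.
#' @return RMSSD in ms (0 iff all successive differences vanish).
#' @examples
#' rmssd(c(800, 810, 790))  # sqrt(250) ~ 15.811
#' @export
rmssd <- function(rr_ms) {
  if (length(rr_ms) < 2L) stop("need at least 2 R-R intervals")
  stop_if_not_finite(rr_ms, "R-R series")
  d <- diff(rr_ms)
  sqrt(sum(d^2) / length(d))
}

#' R-R interval series with beat times
#'
#' @param rr_ms Positive R-R intervals in ms.
#' @return Object of class `rr_series`: list with `rr_ms` and `beat_times_s`,
#'   the cumulative interval-ending beat times in seconds.
#' @export
rr_series <- function(rr_ms) {
  stopifnot(all(rr_ms > 0))
  structure(list(rr_ms = rr_ms, beat_times_s = cumsum(rr_ms) / 1000),
            class = "rr_series")
}

#' RMSSD over a time window
#'
#' Computes [rmssd()] over the intervals whose *ending* beat time falls in the
#' half-open window `[window[1], window[2])` seconds.  Windows holding fewer
#' than 2 intervals return `NA`; callers assembling window tables forward-fill
#' such gaps (documented convention, see [build_feature_table()]).
#'
#' @param series An `rr_series` object (or positive numeric `rr_ms` vector).
#' @param window Numeric pair `c(t0, t1)` in seconds.
#' @return RMSSD in ms, or `NA` if fewer than 2 intervals end in the window.
#' @export
window_rmssd <- function(series, window) {
  if (!inherits(series, "rr_series")) series <- rr_series(series)
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  sel <- series$beat_times_s >= window[1L] & series$beat_times_s < window[2L]
  if (sum(sel) < 2L) return(NA_real_)
  rmssd(series$rr_ms[sel])
}
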