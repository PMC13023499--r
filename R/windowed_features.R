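# Column roster of the per-window feature table.
FEATURE_COLS <- c("Mean_Tn", "Std_Tn", "Mean_Ph", "Std_Ph",
                  "Mean_WL_Tn", "Std_WL_Tn", "Mean_WL_Ph", "Std_WL_Ph",
                  "SCR_Ampl", "SCR_RiseT", "SCR_Count", "TVSymp", "HRV")
TARGET_COLS <- c("P_Asym", "Log_Asym", "MI_Asym")
LABEL_COLS <- c("participant", "task", "trial")

#' Moving-window grid over a sampled trial
#'
#' Half-open windows of `window_len` samples starting at
#' `1, 1 + step, 1 + 2 step, ...`, the last one ending within the signal;
#' the window count is `floor((n_samples - window_len) / step) + 1`.
#'
#' @param n_samples Trial length in samples (>= `window_len`).
#' @param window_len Window length in samples (default 13000, i.e. 65 s at
#'   the 200 Hz reference rate).
#' @param step Hop in samples (default 325, i.e. 1.625 s).
#' @return Object of class `window_grid`: list with `starts` (1-based),
#'   `window_len`, `step`, `n_windows`, `n_samples`.
#' @export
make_window_grid <- function(n_samples, window_len = 13000L, step = 325L) {
  stopifnot(window_len >= 1L, step >= 1L, step <= window_len)
  if (n_samples < window_len) {
    stop("signal shorter than one analysis window")
  }
  n_windows <- floor((n_samples - window_len) / step) + 1L
  structure(
    list(starts = 1L + (seq_len(n_windows) - 1L) * step,
         window_len = as.integer(window_len), step = as.integer(step),
         n_windows = as.integer(n_windows), n_samples = as.integer(n_samples)),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("Window grid: %d windows of %d samples, step %d, over %d samples\n",
              x$n_windows, x$window_len, x$step, x$n_samples))
  invisible(x)
}

#' Build the per-window feature table of a session
#'
#' Runs every feature extractor on the identical moving-window grid for each
#' trial of a session and assembles one row per window: the 13 candidate
#' features (`Mean_Tn`, `Std_Tn`, `Mean_Ph`, `Std_Ph`, `Mean_WL_Tn`,
#' `Std_WL_Tn`, `Mean_WL_Ph`, `Std_WL_Ph`, `SCR_Ampl`, `SCR_RiseT`,
#' `SCR_Count`, `TVSymp`, `HRV`), the three FAA targets (`P_Asym`,
#' `Log_Asym`, `MI_Asym`) and the labels (`participant`, `task`, `trial`,
#' plus `window_start_s`).
#'
#' Processing choices: EDA is resampled to the EEG reference rate before
#' windowing so the same sample grid applies to every signal; wavelet
#' features are computed on the tonic/phasic components decimated to 4 Hz
#' (the 0.005-0.5 Hz analysis band lies far below that Nyquist) with scales
#' from [scales_for_band()]; per-window TVSymp is the in-window mean of the
#' [tvsymp()] series; HRV windows with fewer than two beats are
#' forward-filled (leading gaps back-filled); empty-SCR windows report zeros.
#' The `MI_Asym` envelopes are subsampled to an effective 20 Hz before
#' binning (they are smoothed to 2 Hz bandwidth, so denser sampling adds only
#' autocorrelated duplicates).
#'
#' @param session A `synthetic_session` (from [generate_session()] or
#'   [read_session()]).
#' @param window_len,step Window grid in samples at the EEG rate; default to
#'   the session config.
#' @param scr_threshold SCR detection threshold in uS (default 0.05).
#' @param n_bins Bins for the `MI_Asym` target (default 12).
#' @param cwt_band,cwt_n_scales,cwt_fb,cwt_fc Wavelet feature parameters
#'   (defaults: 0.005-0.5 Hz, 25 scales, fb 1.5, fc 1).
#' @return A data.frame (one row per window) with the columns above;
#'   deterministic given the session.
#' @export
build_feature_table <- function(session,
                                window_len = NULL, step = NULL,
                                scr_threshold = 0.05, n_bins = 12L,
                                cwt_band = c(0.005, 0.5), cwt_n_scales = 25L,
                                cwt_fb = 1.5, cwt_fc = 1) {
  stopifnot(inherits(session, "synthetic_session"))
  cfg <- session$config
  fs <- cfg$fs_eeg
  fs_eda <- cfg$fs_eda
  if (is.null(window_len)) window_len <- cfg$window_len
  if (is.null(step)) step <- cfg$step
  fs_wl <- 4
  scales <- scales_for_band(cwt_band[1L], cwt_band[2L], cwt_n_scales,
                            fc = cwt_fc, fs = fs_wl)
  env_by <- max(1L, floor(fs / 20))
  rows <- lapply(session$trials, function(tr) {
    n <- length(tr$eeg_left)
    if (round(length(tr$eda) / fs_eda * fs) != n) {
      stop(sprintf(
        "participant %s task %s trial %s: EDA and EEG cover different durations",
        tr$participant, tr$task, tr$trial))
    }
    grid <- make_window_grid(n, window_len, step)
    eda <- resample_uniform(tr$eda, fs_eda, fs)
    if (length(eda) < n) eda <- c(eda, rep(eda[length(eda)], n - length(eda)))
    eda <- eda[seq_len(n)]
    dec <- decompose_eda(eda, fs)
    events <- detect_scr_events(dec$phasic, fs, scr_threshold)
    tvs <- tvsymp(eda, fs)
    sg_tn <- cwt_scaleogram(resample_uniform(dec$tonic, fs, fs_wl), fs_wl,
                            scales, cwt_fb, cwt_fc, 1)
    sg_ph <- cwt_scaleogram(resample_uniform(dec$phasic, fs, fs_wl), fs_wl,
                            scales, cwt_fb, cwt_fc, 1)
    rr <- rr_series(tr$rr_ms)
    a_l <- bandpass_alpha(tr$eeg_left, fs)
    a_r <- bandpass_alpha(tr$eeg_right, fs)
    env_l <- alpha_envelope(tr$eeg_left, fs)
    env_r <- alpha_envelope(tr$eeg_right, fs)
    out <- data.frame(participant = tr$participant, task = tr$task,
                      trial = tr$trial,
                      window_start_s = (grid$starts - 1L) / fs)
    feat <- matrix(NA_real_, grid$n_windows, length(FEATURE_COLS) + 3L,
                   dimnames = list(NULL, c(FEATURE_COLS, TARGET_COLS)))
    for (w in seq_len(grid$n_windows)) {
      s <- grid$starts[w]
      win <- c(s, s + window_len)
      tw <- c((s - 1L) / fs, (s - 1L + window_len) / fs)
      st_tn <- component_window_stats(dec$tonic, win)
      st_ph <- component_window_stats(dec$phasic, win)
      wl_tn <- wavelet_window_features(sg_tn, tw)
      wl_ph <- wavelet_window_features(sg_ph, tw)
      scr <- scr_window_features(events, win, fs)
      pl <- window_alpha_power(a_l, win)
      pr <- window_alpha_power(a_r, win)
      idx <- seq(s, s + window_len - 1L, by = env_by)
      feat[w, ] <- c(st_tn[["mean"]], st_tn[["std"]],
                     st_ph[["mean"]], st_ph[["std"]],
                     wl_tn[["mean"]], wl_tn[["std"]],
                     wl_ph[["mean"]], wl_ph[["std"]],
                     scr[["scr_ampl_mean"]], scr[["scr_riset_mean"]],
                     scr[["scr_count"]],
                     mean(tvs[s:(s + window_len - 1L)]),
                     window_rmssd(rr, tw),
                     faa_ratio(pl, pr), faa_log(pl, pr),
                     faa_mi(env_l[idx], env_r[idx], n_bins))
    }
    cbind(out, as.data.frame(feat))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # forward-fill (then back-fill) HRV gaps within each trial
  key <- interaction(tab$participant, tab$task, tab$trial, drop = TRUE)
  tab$HRV <- stats::ave(tab$HRV, key, FUN = fill_na)
  tab
}

fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (!length(ok)) return(x)
  idx <- cumsum(!is.na(x))
  out <- c(x[ok][pmax(idx, 1L)])
  out[idx == 0L] <- x[ok[1L]]   # back-fill leading gap
  out
}

#' Rank features by mutual information with an FAA target
#'
#' Computes the Miller-Madow corrected mutual information between each
#' candidate feature and the chosen FAA variant within groups of windows,
#' averages across groups, and sorts in descending order (ties broken
#' alphabetically).  Groups smaller than `5 * n_bins` rows are skipped with a
#' warning, as are (feature, group) pairs whose feature is too discrete for
#' equal-frequency binning.
#'
#' @param table Feature table from [build_feature_table()].
#' @param target One of `"P_Asym"`, `"Log_Asym"`, `"MI_Asym"`.
#' @param group_by Label columns defining the averaging groups; default
#'   `c("participant", "task", "trial")` (per-trial, appropriate at
#'   full-protocol trial durations); use `c("participant", "task")` when
#'   short trials give too few windows per trial.
#' @param n_bins Equal-frequency bins (default 12).
#' @param features Feature columns to rank (defaults to the 13-column roster).
#' @return data.frame with columns `feature`, `mi` (mean bits across groups),
#'   `n_groups`, sorted by decreasing `mi`.
#' @export
mi_feature_ranking <- function(table, target = c("P_Asym", "Log_Asym", "MI_Asym"),
                               group_by = c("participant", "task", "trial"),
                               n_bins = 12L, features = FEATURE_COLS) {
  target <- match.arg(target)
  stopifnot(all(group_by %in% names(table)), all(features %in% names(table)))
  groups <- split(seq_len(nrow(table)),
                  interaction(table[group_by], drop = TRUE))
  small <- vapply(groups, length, integer(1L)) < 5L * n_bins
  if (any(small)) {
    warning(sprintf("skipping %d group(s) with fewer than %d windows",
                    sum(small), 5L * n_bins))
    groups <- groups[!small]
  }
  if (!length(groups)) {
    stop("no group reaches 5 * n_bins windows; coarsen `group_by`")
  }
  mi <- sapply(features, function(f) {
    vals <- vapply(groups, function(idx) {
      x <- table[[f]][idx]
      y <- table[[target]][idx]
      if (length(unique(x)) < n_bins || length(unique(y)) < n_bins) {
        return(NA_real_)
      }
      as.numeric(suppressWarnings(mutual_information_mm(x, y, n_bins)))
    }, numeric(1L))
    mean(vals, na.rm = TRUE)
  })
  mi[is.nan(mi)] <- 0
  out <- data.frame(feature = features, mi = unname(mi),
                    n_groups = length(groups))
  out <- out[order(-out$mi, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-k features of a mutual-information ranking
#'
#' @param ranking Output of [mi_feature_ranking()].
#' @param k Number of features to keep (default 6).
#' @return Character vector of feature names.
#' @export
select_top_features <- function(ranking, k = 6L) {
  stopifnot(k >= 1L, k <= nrow(ranking))
  ranking$feature[seq_len(k)]
}
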