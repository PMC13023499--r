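#' Configuration for a synthetic recording session
#'
#' Bundles and validates the parameters of the synthetic-session generator.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a slowly varying latent frontal-alpha-asymmetry (FAA) trajectory
#' per trial with a fatigue dip centred on `fatigue_peak_trial`; a tonic skin
#' conductance level monotonically coupled to the latent FAA with strength and
#' sign `coupling_kappa`; Poisson-timed skin conductance responses whose rate
#' rises with the fatigue-linked arousal bump; left/right frontal EEG whose
#' window alpha powers realize the latent FAA; and an R-R interval series with
#' a target RMSSD.
#'
#' @param n_participants Number of participants (default 10).
#' @param tasks Character vector of task identifiers; defaults to the four
#'   cognitive tasks `EAT`, `SHIP`, `NBACK`, `PVT`.
#' @param n_trials Trials per task (default 12, >= 2).
#' @param trial_duration_s Named numeric vector of trial durations in seconds
#'   (defaults: EAT 300, SHIP 1200, NBACK 600, PVT 600).  Unnamed scalar
#'   values are recycled over `tasks`.  Every duration must cover at least one
#'   analysis window (`window_len / fs_eeg` seconds).
#' @param fs_eeg EEG sampling rate in Hz (default 200; also the reference rate
#'   of the window grid).
#' @param fs_eda EDA sampling rate in Hz (default 400).
#' @param coupling_kappa Strength and sign of the tonic-FAA coupling, in
#'   \[-1, 1\] (default 0.6).
#' @param fatigue_peak_trial Trial index of maximal fatigue: the latent FAA
#'   dips, and arousal peaks, at this trial (default 7).
#' @param scr_rate_hz Baseline mean SCR event rate per second (default 0.08).
#' @param mean_rr_ms Mean R-R interval in ms (default 800).
#' @param rmssd_target_ms Target RMSSD of the generated R-R series in ms
#'   (default 40).
#' @param noise_sd Named list of noise scales: `eeg` (broadband EEG noise, uV),
#'   `eda` (white EDA measurement noise, uS), `drift` (slow tonic drift, uS),
#'   `latent` (within-trial latent FAA wander).
#' @param window_len,step Analysis window length and hop in samples at
#'   `fs_eeg` (defaults 13000 and 325).
#' @param alpha_amp Baseline alpha carrier amplitude in uV (default 3).
#' @param tonic_base Mean tonic level in uS (default 8).
#' @param coupling_gain Tonic swing per unit `tanh`-mapped latent FAA at
#'   `|coupling_kappa| = 1`, in uS (default 1.5).
#' @param faa_base,fatigue_dip,fatigue_width Trial-level mean latent FAA
#'   profile: baseline level, dip depth at the fatigue peak, and Gaussian
#'   width of the dip in trials (defaults 0.15, 0.5, 2).  The profile sets
#'   each trial's withdrawal-state probability, so the realized trial mean
#'   matches it in expectation.
#' @param latent_state_amp Dwell level of the bistable affect process: the
#'   latent FAA alternates between approach episodes near
#'   `+latent_state_amp` and withdrawal episodes near `-latent_state_amp`
#'   (default 0.4), making most trials mixed-state.
#' @param latent_dwell_s Mean episode dwell time in seconds (default 45).
#' @param seed Integer seed; sessions are bit-identical given the same config.
#' @return Object of class `session_config` (a validated named list).
#' @export
session_config <- function(n_participants = 10L,
                           tasks = c("EAT", "SHIP", "NBACK", "PVT"),
                           n_trials = 12L,
                           trial_duration_s = c(EAT = 300, SHIP = 1200,
                                                NBACK = 600, PVT = 600),
                           fs_eeg = 200, fs_eda = 400,
                           coupling_kappa = 0.6,
                           fatigue_peak_trial = 7L,
                           scr_rate_hz = 0.08,
                           mean_rr_ms = 800,
                           rmssd_target_ms = 40,
                           noise_sd = list(eeg = 1, eda = 0.02,
                                           drift = 0.05, latent = 0.12),
                           window_len = 13000L, step = 325L,
                           alpha_amp = 3, tonic_base = 8, coupling_gain = 1.5,
                           faa_base = 0.15, fatigue_dip = 0.5,
                           fatigue_width = 2, latent_state_amp = 0.4,
                           latent_dwell_s = 45, seed = 1L) {
  stopifnot(n_participants >= 1L, length(tasks) >= 1L, n_trials >= 2L,
            fs_eeg > 0, fs_eda > 0, scr_rate_hz >= 0,
            mean_rr_ms > 0, rmssd_target_ms >= 0,
            window_len >= 2L, step >= 1L, step <= window_len)
  if (abs(coupling_kappa) > 1) stop("|coupling_kappa| must be <= 1")
  if (rmssd_target_ms > mean_rr_ms) stop("rmssd_target_ms exceeds mean_rr_ms")
  if (is.null(names(trial_duration_s))) {
    trial_duration_s <- stats::setNames(rep_len(trial_duration_s, length(tasks)), tasks)
  }
  if (!all(tasks %in% names(trial_duration_s))) {
    stop("trial_duration_s must name every task")
  }
  trial_duration_s <- trial_duration_s[tasks]
  min_dur <- window_len / fs_eeg
  if (any(trial_duration_s * fs_eeg < window_len)) {
    stop(sprintf("every trial must be at least one analysis window long (%.1f s)",
                 min_dur))
  }
  for (nm in c("eeg", "eda", "drift", "latent")) {
    if (is.null(noise_sd[[nm]])) stop(sprintf("noise_sd$%s missing", nm))
    if (noise_sd[[nm]] < 0) stop("noise scales must be non-negative")
  }
  structure(as.list(environment()), class = "session_config")
}

# Trial-level mean latent FAA profile: positive baseline with a Gaussian
# fatigue dip centred on the fatigue-peak trial.
trial_faa_profile <- function(config, trials = seq_len(config$n_trials)) {
  config$faa_base - config$fatigue_dip *
    exp(-((trials - config$fatigue_peak_trial) / config$fatigue_width)^2)
}

# Arousal bump (0..1) used to modulate the SCR rate across trials.
trial_arousal <- function(config, trials = seq_len(config$n_trials)) {
  exp(-((trials - config$fatigue_peak_trial) / config$fatigue_width)^2)
}

# Latent FAA for one trial: a bistable affect process.  The state s(t)
# alternates between approach (+1) and withdrawal (-1) episodes with mean
# dwell `latent_dwell_s`; the per-trial withdrawal probability rises as the
# trial-level FAA profile falls (fatigue), so the latent dwells near
# +latent_state_amp or -latent_state_amp with a zero-density trough between
# the two states — the two-emotional-states structure the downstream
# clustering is meant to find.  Episode edges are smoothed (~8 s) and an
# AR(1) wander plus participant offset is added.  The trajectory is realized
# on a fine grid of step-length blocks (`$fine`); the window-level ground
# truth (`$window`) is the *mean* of the fine trajectory over each window,
# which is the quantity a windowed power ratio actually realizes.  Consumes
# the caller's RNG.
gen_latent_trial <- function(config, trial, participant_offset, n_windows) {
  A <- config$latent_state_amp
  K <- max(1L, round(config$window_len / config$step))
  n_steps <- n_windows + K - 1L
  step_s <- config$step / config$fs_eeg
  t_s <- (seq_len(n_steps) - 0.5) * step_s
  # stationary withdrawal probability from the trial-level FAA profile
  p_neg <- clamp(0.5 - trial_faa_profile(config, trial) / (2 * A), 0.05, 0.95)
  p_switch <- min(1, step_s / config$latent_dwell_s)
  s <- numeric(n_steps)
  s[1L] <- if (stats::runif(1L) < p_neg) -1 else 1
  u <- stats::runif(n_steps)
  v <- stats::runif(n_steps)
  for (k in seq_len(n_steps)[-1L]) {
    s[k] <- if (u[k] < p_switch) {
      if (v[k] < p_neg) -1 else 1
    } else {
      s[k - 1L]
    }
  }
  # ~8 s moving-average smoothing of the episode edges
  ks <- max(1L, round(8 / step_s))
  s_sm <- stats::filter(c(rep(s[1L], ks), s, rep(s[n_steps], ks)),
                        rep(1 / (2L * ks + 1L), 2L * ks + 1L), sides = 2L)
  s_sm <- as.numeric(s_sm)[(ks + 1L):(ks + n_steps)]
  ar <- 0.97
  innov <- stats::rnorm(n_steps, 0, config$noise_sd$latent * sqrt(1 - ar^2))
  e <- numeric(n_steps)
  e[1L] <- stats::rnorm(1L, 0, config$noise_sd$latent)
  for (w in seq_len(n_steps)[-1L]) e[w] <- ar * e[w - 1L] + innov[w]
  fine <- clamp(A * s_sm + participant_offset + e, -0.95, 0.95)
  window <- vapply(seq_len(n_windows), function(w) {
    mean(fine[w:(w + K - 1L)])
  }, numeric(1L))
  list(fine = fine, window = window, t_fine = t_s)
}

# Tonic trajectory at fs_eda for one trial given the latent FAA trajectory.
# Baseline + kappa-scaled monotone (tanh) map of the latent + slow AR drift.
# `latent` may be a window-level vector (interpolated through window centres)
# or the fine-grid list from gen_latent_trial.
gen_tonic_trial <- function(config, latent, base, n_eda) {
  if (is.list(latent)) {
    centers_s <- latent$t_fine
    latent <- latent$fine
  } else {
    centers_s <- ((seq_along(latent) - 1L) * config$step +
                    config$window_len / 2) / config$fs_eeg
  }
  t_eda <- (seq_len(n_eda) - 1L) / config$fs_eda
  g <- stats::approx(centers_s, latent, xout = t_eda, rule = 2)$y
  fs_drift <- 2
  n_d <- ceiling(n_eda / config$fs_eda * fs_drift) + 2L
  ar <- 0.99
  innov <- stats::rnorm(n_d, 0, config$noise_sd$drift * sqrt(1 - ar^2))
  d <- numeric(n_d)
  d[1L] <- stats::rnorm(1L, 0, config$noise_sd$drift)
  for (k in seq_len(n_d)[-1L]) d[k] <- ar * d[k - 1L] + innov[k]
  drift <- stats::approx((seq_len(n_d) - 1L) / fs_drift, d, xout = t_eda, rule = 2)$y
  # gentle tanh keeps the map monotone and bounded while staying close to
  # linear over the admissible latent range, so the tonic fluctuation scale
  # does not collapse at extreme affect (a saturation artifact real skin
  # conductance does not show)
  base + config$coupling_gain * config$coupling_kappa * tanh(0.8 * g) + drift
}

#' SCR event kernel (difference of exponentials)
#'
#' Bateman-style rise/decay kernel
#' \eqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}}, normalized to unit peak.
#' The analytic onset-to-peak time is
#' \eqn{t^* = \ln(\tau_d/\tau_r) / (1/\tau_r - 1/\tau_d)}.
#'
#' @param fs Sampling rate in Hz.
#' @param tau_rise,tau_decay Rise and decay time constants in seconds
#'   (defaults 0.75 and 2).
#' @param duration_s Kernel support in seconds (default 12).
#' @return Numeric kernel vector with attribute `peak_time_s`.
#' @export
scr_kernel <- function(fs, tau_rise = 0.75, tau_decay = 2, duration_s = 12) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  t <- seq(0, duration_s, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tpk <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  kpk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  structure(k / kpk, peak_time_s = tpk)
}

gen_eda_impl <- function(tonic_trajectory, scr_rate_hz, fs, noise_sd = 0,
                         amp_meanlog = log(0.3), amp_sdlog = 0.4,
                         tau_rise = 0.75, tau_decay = 2,
                         rate_mod = NULL, amp_mod = NULL, tau_mod = NULL) {
  n <- length(tonic_trajectory)
  dur <- n / fs
  out <- tonic_trajectory
  if (scr_rate_hz > 0) {
    mean_mod <- if (is.null(rate_mod)) 1 else mean(rate_mod)
    n_ev <- stats::rpois(1L, scr_rate_hz * dur * mean_mod)
    if (n_ev > 0) {
      # inhomogeneous Poisson event times: sample onsets proportionally to
      # the (possibly time-varying) intensity
      i0s <- if (is.null(rate_mod)) {
        sort(sample.int(n, n_ev, replace = TRUE))
      } else {
        sort(sample.int(n, n_ev, replace = TRUE, prob = rate_mod))
      }
      amps <- stats::rlnorm(n_ev, amp_meanlog, amp_sdlog)
      if (!is.null(amp_mod)) amps <- amps * amp_mod[i0s]
      for (e in seq_len(n_ev)) {
        tm <- if (is.null(tau_mod)) 1 else tau_mod[i0s[e]]
        k <- scr_kernel(fs, tau_rise * tm, tau_decay * tm)
        idx <- i0s[e]:min(n, i0s[e] + length(k) - 1L)
        out[idx] <- out[idx] + amps[e] * k[seq_along(idx)]
      }
    }
  }
  if (noise_sd > 0) out <- out + stats::rnorm(n, 0, noise_sd)
  out
}

#' Generate one synthetic EDA trial
#'
#' Adds Poisson-timed SCR events (difference-of-exponentials kernels with
#' lognormal amplitudes) and optional white measurement noise on top of a
#' given tonic trajectory.  With `scr_rate_hz = 0` and `noise_sd = 0` the
#' output equals the tonic trajectory exactly.
#'
#' @param tonic_trajectory Positive numeric vector (uS) at rate `fs`.
#' @param scr_rate_hz Mean SCR events per second (>= 0).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_sd White-noise standard deviation in uS (default 0).
#' @param amp_meanlog,amp_sdlog Lognormal SCR amplitude parameters
#'   (defaults give a median amplitude of 0.3 uS).
#' @param tau_rise,tau_decay Kernel time constants in seconds, see
#'   [scr_kernel()].
#' @return Numeric EDA vector (uS), same length as the tonic trajectory.
#' @export
generate_eda_trial <- function(tonic_trajectory, scr_rate_hz, fs, seed = 1L,
                               noise_sd = 0, amp_meanlog = log(0.3),
                               amp_sdlog = 0.4, tau_rise = 0.75, tau_decay = 2) {
  if (scr_rate_hz < 0) stop("scr_rate_hz must be non-negative")
  stopifnot(all(tonic_trajectory > 0), fs > 0)
  with_seed(seed, gen_eda_impl(tonic_trajectory, scr_rate_hz, fs, noise_sd,
                               amp_meanlog, amp_sdlog, tau_rise, tau_decay))
}

gen_eeg_pair_impl <- function(g, fs, alpha_amp, noise_sd, alpha_freq = 10) {
  n <- length(g)
  tt <- (seq_len(n) - 1L) / fs
  phl <- stats::runif(1L, 0, 2 * pi)
  phr <- stats::runif(1L, 0, 2 * pi)
  left <- alpha_amp * sqrt(1 - g) * sin(2 * pi * alpha_freq * tt + phl)
  right <- alpha_amp * sqrt(1 + g) * sin(2 * pi * alpha_freq * tt + phr)
  if (noise_sd > 0) {
    left <- left + stats::rnorm(n, 0, noise_sd)
    right <- right + stats::rnorm(n, 0, noise_sd)
  }
  list(left = left, right = right)
}

#' Generate a left/right frontal EEG pair realizing a latent FAA trajectory
#'
#' Builds F7/F8 surrogates whose alpha-band (10 Hz carrier) amplitudes are
#' scaled by \eqn{\sqrt{1 \mp g}} so that the noiseless window alpha-power
#' ratio \eqn{(R - L)/(R + L)} equals the latent value `g` within each
#' analysis window; broadband Gaussian noise is added on top.  The latent
#' trajectory is supplied at window level and interpolated through the window
#' centres of the `window_len`/`step` grid.
#'
#' @param latent_faa Window-level latent FAA values, all strictly inside
#'   (-1, 1).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param alpha_amp Alpha carrier amplitude in uV (default 3).
#' @param noise_sd Broadband noise SD in uV (default 1).
#' @param window_len,step Window grid in samples (defaults 13000, 325); the
#'   generated length is `window_len + (length(latent_faa) - 1) * step`.
#' @return List with numeric `left` and `right` channels (uV).
#' @export
generate_eeg_alpha_pair <- function(latent_faa, fs, seed = 1L, alpha_amp = 3,
                                    noise_sd = 1, window_len = 13000L,
                                    step = 325L) {
  if (any(abs(latent_faa) >= 1)) {
    stop("|latent_faa| = 1 would require zero alpha power on one side")
  }
  n <- window_len + (length(latent_faa) - 1L) * step
  centers <- ((seq_along(latent_faa) - 1L) * step + window_len / 2)
  g <- stats::approx(centers, latent_faa, xout = seq_len(n) - 1L, rule = 2)$y
  with_seed(seed, gen_eeg_pair_impl(g, fs, alpha_amp, noise_sd))
}

gen_rr_impl <- function(duration_s, mean_rr_ms, rmssd_target_ms) {
  target_ms <- duration_s * 1000
  if (rmssd_target_ms == 0) {
    n <- ceiling(target_ms / mean_rr_ms)
    return(rep(mean_rr_ms, n))
  }
  s <- rmssd_target_ms / sqrt(2)
  rr <- numeric(0L)
  total <- 0
  while (total < target_ms) {
    chunk <- pmax(stats::rnorm(256L, mean_rr_ms, s), 0.3 * mean_rr_ms)
    rr <- c(rr, chunk)
    total <- total + sum(chunk)
  }
  n <- which(cumsum(rr) >= target_ms)[1L]
  rr[seq_len(n)]
}

#' Generate an R-R interval series with a target RMSSD
#'
#' Draws independent Gaussian intervals around `mean_rr_ms` with successive
#' -difference scale `rmssd_target_ms / sqrt(2)`, so the sample RMSSD matches
#' the target (within sampling error; better than 15% for durations of
#' 300 s and up).  Generation stops at the first beat crossing the requested
#' duration, so the interval sum matches the duration within one interval.
#'
#' @param duration_s Trial duration in seconds.
#' @param mean_rr_ms Mean R-R interval in ms (> 0).
#' @param rmssd_target_ms Target RMSSD in ms (0 gives a constant series;
#'   must not exceed `mean_rr_ms`).
#' @param seed Integer seed.
#' @return Numeric vector of R-R intervals in ms.
#' @export
generate_rr_trial <- function(duration_s, mean_rr_ms = 800,
                              rmssd_target_ms = 40, seed = 1L) {
  stopifnot(duration_s > 0, mean_rr_ms > 0, rmssd_target_ms >= 0)
  if (rmssd_target_ms > mean_rr_ms) stop("rmssd_target_ms exceeds mean_rr_ms")
  with_seed(seed, gen_rr_impl(duration_s, mean_rr_ms, rmssd_target_ms))
}

#' Generate a full synthetic session
#'
#' Draws every participant x task x trial of the configured protocol: the
#' window-level latent FAA trajectory (the ground truth downstream recovery
#' tests compare against), EDA at `fs_eda` (coupled tonic + SCR events +
#' noise), an F7/F8 EEG pair at `fs_eeg` realizing the latent FAA, and an R-R
#' series.  Deterministic: identical configurations (including seed) give
#' bit-identical sessions.
#'
#' @param config A [session_config()].
#' @return Object of class `synthetic_session`: list with `config` and
#'   `trials`, one entry per participant x task x trial holding
#'   `participant`, `task`, `trial`, `eda`, `eeg_left`, `eeg_right`, `rr_ms`,
#'   and `latent_faa` (window-level ground truth).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    trials <- list()
    for (p in seq_len(config$n_participants)) {
      base_p <- config$tonic_base + stats::rnorm(1L, 0, 0.3)
      offset_p <- stats::rnorm(1L, 0, 0.08)
      for (task in config$tasks) {
        dur <- config$trial_duration_s[[task]]
        n_eeg <- round(dur * config$fs_eeg)
        n_eda <- round(dur * config$fs_eda)
        n_windows <- floor((n_eeg - config$window_len) / config$step) + 1L
        for (tr in seq_len(config$n_trials)) {
          lat <- gen_latent_trial(config, tr, offset_p, n_windows)
          latent <- lat$window
          tonic <- gen_tonic_trial(config, lat, base_p, n_eda)
          # Sympathetic (phasic) arousal rises as the latent affect falls:
          # SCR rate and amplitude are modulated by the |kappa|-scaled latent
          # state plus the trial-level fatigue bump, so event-related and
          # spectral EDA features co-vary with FAA as well as the tonic level.
          g_eda <- stats::approx(lat$t_fine, lat$fine,
                                 xout = (seq_len(n_eda) - 1L) / config$fs_eda,
                                 rule = 2)$y
          arous <- -tanh(0.8 * g_eda)
          ak <- abs(config$coupling_kappa)
          rate_mod <- pmax(1 + 0.8 * ak * arous +
                             0.3 * trial_arousal(config, tr), 0.05)
          amp_mod <- pmax(1 + 0.8 * ak * arous, 0.1)
          # response kinetics slow down with arousal: rise/decay constants
          # stretch together, so detected rise times carry state information
          tau_mod <- pmax(1 + 0.5 * ak * arous, 0.3)
          eda <- gen_eda_impl(tonic, config$scr_rate_hz, config$fs_eda,
                              config$noise_sd$eda,
                              rate_mod = rate_mod, amp_mod = amp_mod,
                              tau_mod = tau_mod)
          g_eeg <- stats::approx(lat$t_fine * config$fs_eeg, lat$fine,
                                 xout = seq_len(n_eeg) - 1L, rule = 2)$y
          eeg <- gen_eeg_pair_impl(g_eeg, config$fs_eeg, config$alpha_amp,
                                   config$noise_sd$eeg)
          rr <- gen_rr_impl(dur, config$mean_rr_ms, config$rmssd_target_ms)
          trials[[length(trials) + 1L]] <- list(
            participant = p, task = task, trial = tr,
            eda = eda, eeg_left = eeg$left, eeg_right = eeg$right,
            rr_ms = rr, latent_faa = latent)
        }
      }
    }
    structure(list(config = config, trials = trials), class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic session: %d participants x %d tasks (%s) x %d trials, kappa=%.2f, seed=%d\n",
    cfg$n_participants, length(cfg$tasks), paste(cfg$tasks, collapse = "/"),
    cfg$n_trials, cfg$coupling_kappa, cfg$seed))
  invisible(x)
}

#' Write a session to per-trial CSV files plus a manifest
#'
#' One `time_s,value` CSV per (participant, task, trial, signal) for the EDA
#' and the two EEG channels, one `beat_time_s,rr_ms` CSV for the R-R series,
#' and a `manifest.csv` tying files to labels and sampling rates.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- session$config
  rows <- lapply(session$trials, function(tr) {
    stem <- sprintf("p%02d_%s_t%02d", tr$participant, tr$task, tr$trial)
    files <- c(eda = paste0(stem, "_eda.csv"),
               eeg_left = paste0(stem, "_eegL.csv"),
               eeg_right = paste0(stem, "_eegR.csv"),
               rr = paste0(stem, "_rr.csv"))
    for (sig in c("eda", "eeg_left", "eeg_right")) {
      fs <- if (sig == "eda") cfg$fs_eda else cfg$fs_eeg
      utils::write.csv(
        data.frame(time_s = (seq_along(tr[[sig]]) - 1L) / fs, value = tr[[sig]]),
        file.path(dir, files[[sig]]), row.names = FALSE)
    }
    utils::write.csv(
      data.frame(beat_time_s = cumsum(tr$rr_ms) / 1000, rr_ms = tr$rr_ms),
      file.path(dir, files[["rr"]]), row.names = FALSE)
    data.frame(participant = tr$participant, task = tr$task, trial = tr$trial,
               eda_file = files[["eda"]], eeg_left_file = files[["eeg_left"]],
               eeg_right_file = files[["eeg_right"]], rr_file = files[["rr"]],
               fs_eda = cfg$fs_eda, fs_eeg = cfg$fs_eeg)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a session back from a manifest directory
#'
#' Inverse of [write_session()] (without the latent ground truth, which real
#' recordings do not carry).  The result can be fed to
#' [build_feature_table()].
#'
#' @param dir Directory containing `manifest.csv` and the per-trial CSVs.
#' @param window_len,step Window grid announced in the resulting config
#'   (defaults 13000, 325).
#' @return A `synthetic_session`-shaped object (with `latent_faa = NULL`).
#' @export
read_session <- function(dir, window_len = 13000L, step = 325L) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    rr <- utils::read.csv(file.path(dir, m$rr_file))
    list(participant = m$participant, task = m$task, trial = m$trial,
         eda = utils::read.csv(file.path(dir, m$eda_file))$value,
         eeg_left = utils::read.csv(file.path(dir, m$eeg_left_file))$value,
         eeg_right = utils::read.csv(file.path(dir, m$eeg_right_file))$value,
         rr_ms = rr$rr_ms, latent_faa = NULL)
  })
  cfg <- list(fs_eda = manifest$fs_eda[1L], fs_eeg = manifest$fs_eeg[1L],
              window_len = window_len, step = step,
              tasks = unique(manifest$task))
  structure(list(config = cfg, trials = trials), class = "synthetic_session")
}
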