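---
title: "Linking electrodermal activity to frontal alpha asymmetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking electrodermal activity to frontal alpha asymmetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Frontal alpha asymmetry (FAA) — the difference in 8–13 Hz EEG power between
the right (F8) and left (F7) frontal channels — is an established marker of
approach- versus withdrawal-related affect: because alpha power is inversely
related to cortical activity, higher FAA indicates relatively greater left
cortical activation and positive/approach states.  Electrodermal activity
(EDA) is far cheaper to record than EEG.  `edafaa` implements a complete,
testable pipeline for asking: *how much information do EDA-derived features
carry about FAA, and can EDA alone reproduce an FAA-defined classification of
emotional state?*

The pipeline has four stages:

1. **Windowed feature extraction.**  All signals are aligned to a 200 Hz
   reference grid and cut into moving windows of 13,000 samples advanced by
   325 samples (65 s windows, 1.625 s hop).  Thirteen candidate features are
   computed per window: mean/SD of the tonic and phasic EDA components,
   mean/SD of complex-Morlet wavelet magnitudes of each component, SCR event
   amplitude/rise-time/count, the TVSymp sympathetic-tone index, and RMSSD
   from the R-R series.  Three FAA variants (normalized ratio, log, and a
   mutual-information variant) are computed on the identical windows.
2. **Dependence analysis.**  Mutual information between each feature and FAA
   is estimated by equal-frequency binning (12 bins) with Miller–Madow bias
   correction, screened by Pearson correlation, and tested by permutation
   (10,000 surrogates, add-one p-value).
3. **Unsupervised state labels.**  The six most informative features are
   standardized and clustered (agglomerative, squared-Euclidean base metric,
   average linkage, cut at two clusters).  The cluster with higher mean ratio
   FAA is named Class 1 (approach), the other Class 2 (withdrawal).  FAA is
   used only for *naming*; it never enters the clustering.
4. **Supervised validation.**  An RBF-kernel SVM trained on the cluster
   labels is evaluated with leave-one-trial-out cross-validation; performance
   is the *coincidence* between predicted classes and the sign of the ratio
   FAA in the held-out trial.

Because no public recording accompanies the analysis, the package includes a
first-class synthetic-session generator whose statistical structure matches
what the analysis assumes; every stage is tested against it.

# Estimators

## Equal-frequency binning and mutual information

Continuous window values are discretized into $B = 12$ uniform-count bins
(counts differ by at most one; ties broken by stable sample order).  This
maximizes the marginal entropy — each marginal is near $\log_2 12 \approx
3.585$ bits — so the mutual information
$$I(X;Y) = \sum_{x,y} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)}$$
is limited by the joint structure, not by an arbitrary grid.  Because
assignments depend only on ranks, the estimate is invariant under monotone
transforms of either variable, and perfectly anti-correlated variables carry
the same information as perfectly correlated ones.

The plug-in estimate is biased upward for finite samples; we subtract the
Miller–Madow first-order term in its occupied-count form
$$\frac{\hat B_{xy} - \hat B_x - \hat B_y + 1}{2N\ln 2}\ \text{bits},$$
flooring the corrected value at zero.  Both the plug-in and corrected values
are retained (as attributes).  With $N = 127$ and a fully occupied
$12\times12$ joint this correction is $121/(254 \ln 2) \approx 0.687$ bits —
at windowed-analysis sample sizes the correction is material, which is why it
is applied everywhere, including inside the permutation null.

Significance uses uniform shuffles of one variable with the add-one estimator
$p = (1 + \#\{I_{perm} \ge I_{obs}\})/(n_{perm}+1)$, so $p$ is never zero and
the attainable floor with 10,000 surrogates is $1/10001 < 2\times10^{-4}$.
Shuffling is done on the precomputed bin assignments (rank invariance), which
makes 10,000 surrogates cheap.  Overlapping windows make successive rows
heavily autocorrelated; plain shuffling therefore overstates the effective
sample size.  We keep plain shuffling as the default estimator definition and
treat its p-values as descriptive at window resolution.

## MI-based FAA

The ratio and log FAA variants need only two window powers.  The
mutual-information FAA variant is defined here as the Miller–Madow corrected
MI between the *left and right alpha amplitude envelopes* (rectified analytic
signal of the 8–13 Hz band, smoothed at 2 Hz) within the window, subsampled
to an effective 20 Hz (the envelopes are band-limited to 2 Hz, so denser
sampling only adds autocorrelated duplicates).  Unlike the other variants it
is sign-free: it quantifies how strongly the two hemispheric alpha amplitudes
co-vary.  Other constructions are conceivable; this one is pluggable behind
`faa_mi()`.

## Time–frequency features

The complex Morlet wavelet
$\psi(\eta) = (\pi f_b)^{-1/2} e^{-\eta^2/f_b} e^{j2\pi f_c \eta}$
(with $f_b = 1.5$, $f_c = 1$) is evaluated in a sample-time convention where
the pseudo-frequency of scale $a$ is $f_c f_s / a$.  The 25 scales are
derived from the target band 0.005–0.5 Hz (covering tonic < 0.05 Hz and
phasic 0.05–0.15 Hz dynamics) by log-spacing pseudo-frequencies — deriving
scales from the band keeps the physiological meaning independent of sampling
rate.  The energy integral of this wavelet is $1/\sqrt{2\pi f_b}$ (the
$(\pi f_b)^{-1/2}$ factor keeps it finite and stable across $f_b$); the
$a^{-1/2}$ factor in the transform equalizes daughter energies across the
grid to within floating-point error.  Wavelet features are computed on the
tonic/phasic components decimated to 4 Hz — the analysis band lies two
decades below that Nyquist, and decimation makes the widest (200 s-period)
wavelets affordable.  Scales whose support cannot fit the record anywhere
are excluded from window statistics *as whole scales*, so every window of a
trial pools the identical scale × translation grid; per-coefficient edge
exclusion would make window statistics depend on window position.

VFCDM decomposes the signal on a bank of center frequencies
$f_{oi} = (i-1)\,2F_\omega$: demodulate by $e^{-j2\pi f_{oi}t}$, low-pass
with a zero-phase FIR of bandwidth $F_\omega$, remodulate, then refine
instantaneous amplitude/phase/frequency with the Hilbert transform of each
real component.  Defaults: internal rate 2 Hz, $F_\omega = 0.03$ Hz, FIR
order 128 normalized to unit DC gain.  The order matters: at this bandwidth
a 64-tap design has a 0.60 band-edge gain and 10% neighbor-band leakage,
which violates amplitude-recovery and reconstruction bounds we test (5% on
AM tones, 10% RMS reconstruction); 128 taps meets both with margin.  The
input is reflect-padded *before* demodulation so record boundaries do not
masquerade as in-band energy.  TVSymp is the summed instantaneous amplitude
of the components whose centers fall in 0.08–0.24 Hz, normalized to unit
variance over the recording.

## EDA decomposition and SCR events

The default tonic/phasic split is a zero-phase Butterworth low-pass at
0.05 Hz (the conventional tonic band edge), computed at a 2 Hz internal rate
and interpolated back, with `phasic = signal - tonic` exactly; a
sparse-deconvolution variant peels positive phasic activity off the tonic
estimate first.  Driver-based convex-optimization decompositions solve a
harder inverse problem; the band split is sufficient for the features used
here and is exactly additive by construction.

SCR events are local maxima of the (1 Hz-smoothed) phasic trace with onset
at the last non-positive-to-positive slope change before the peak; events
below 0.05 uS onset-to-peak amplitude are discarded.  A 5 uS event threshold
is sometimes quoted for raw skin conductance levels, but typical *response*
amplitudes are well below 1 uS, so 5 uS would discard essentially all
events; the threshold is configurable.  Pre-detection smoothing exists so
that measurement noise does not masquerade as micro-events; it biases
detected rise times upward by ~30%, so geometry-sensitive analyses can set
`smooth_hz = 0`.

Empty-window conventions: windows without SCR peaks report zero count and
zero means; HRV windows with fewer than two beats are forward-filled (heads
back-filled).  Downstream equal-frequency binning then never sees gaps.

## Windowing

The window is defined by sample count — 13,000 samples at 200 Hz with a
325-sample hop — which is 65 s (not 64 s, as a duration-based reading would
suggest; the sample count is authoritative here).  The window count over $n$
samples is $\lfloor (n - 13000)/325 \rfloor + 1$, verified against
enumeration.  EDA (400 Hz) is resampled to the 200 Hz reference before
windowing so one grid applies to every signal.

# The synthetic-session generator

The generator emulates the statistical structure the analysis assumes —
including the features of the motivating dataset that are documented in its
printed results — without modeling task psychophysics (tasks differ only by
duration and the shared arousal parameters):

* **Latent affect trajectory.**  The latent FAA $g \in (-1,1)$ is a
  *bistable* process: affect alternates between approach episodes dwelling
  near $+0.4$ and withdrawal episodes near $-0.4$ (mean dwell 45 s, episode
  edges smoothed over ~8 s), plus a participant offset (SD 0.08) and AR(1)
  wander (SD 0.12, ~50 s correlation time).  The per-trial withdrawal
  probability is set by a trial-level profile (baseline mean FAA 0.15 with
  a Gaussian fatigue dip of depth 0.5 and width 2 trials centered on trial
  7 — the late-night fatigue minimum), so fatigued trials dwell mostly in
  the withdrawal state.  Two dwell states with a density trough at zero are
  the structure the downstream two-cluster analysis presumes (positive and
  negative emotional states); a unimodal latent would leave a 2-cluster cut
  nothing to find.  Episode switching also makes trials mixed-state, as in
  the motivating study's validation trials.  The stored per-window ground
  truth is the window *mean* of the fine trajectory — the quantity a
  windowed power ratio realizes.
* **Coupling to EDA.**  Tonic level = participant baseline (8 ± 0.3 uS) +
  $1.5\,\kappa\,\tanh(0.8 g)$ uS + slow AR drift (SD 0.05 uS).  The gentle
  tanh stays near-linear over the admissible range — a harder saturation
  would make the tonic *fluctuation scale* an even function of $g$, an
  artifact real skin conductance does not show.  Sympathetic arousal rises
  as affect falls: SCR event rate and amplitude are modulated by
  $1 + 0.8|\kappa| \cdot (-\tanh(0.8 g))$ (plus a trial-level fatigue bump
  on the rate), and SCR kernel time constants stretch by
  $1 + 0.5|\kappa| \cdot (-\tanh(0.8 g))$, so rise time is genuinely
  state-dependent.  These magnitudes reproduce the strong per-feature
  dependence on FAA that the motivating study reports for event-related and
  spectral features; with them, TVSymp, phasic variability, and wavelet
  features inherit the coupling naturally rather than being painted on.
* **Signals.**  EDA (400 Hz) = tonic + Bateman-style difference-of-
  exponentials SCR kernels (rise 0.75 s, decay 2 s, lognormal amplitudes,
  median 0.3 uS) at inhomogeneous-Poisson times (baseline 0.08 events/s) +
  white noise (0.02 uS).  EEG (200 Hz) = 10 Hz carriers scaled by
  $\sqrt{1 \mp g}$ so the noiseless window alpha-power ratio equals $g$
  *exactly* (a stochastic narrowband carrier would add ~8% power noise per
  window and break exact-recovery tests), plus broadband noise (1 uV on a
  3 uV carrier).  R-R intervals are Gaussian around 800 ms with successive-
  difference scale set to hit a target RMSSD of 40 ms.
* **Determinism.**  One seed drives the whole session; identical
  configurations are bit-identical.

What the generator does *not* emulate: task-specific psychophysics,
artifacts (motion, eye-blink, electrode drift), circadian non-stationarity
beyond the trial-7 dip, participant-specific coupling signs (the motivating
data shows mixed signs across individuals; `coupling_kappa` is signed and
configurable, but a session uses one value), and any EEG structure outside
the alpha band.  Passing tests on this generator therefore demonstrate that
the *pipeline* recovers planted structure of realistic size and noise — not
that real recordings contain such structure.

# Classification design

Standardization statistics, cluster labels, and the SVM are all derived from
the training fold only (test rows provably cannot move the fitted model — a
mutation test asserts this).  Clustering uses squared-Euclidean distances
with average linkage by default; on this package's synthetic data average
linkage aligns the two-cluster cut with the affect split better than single
(which chains) or complete.  The cut extracts the two *main* clusters: a
plain two-way cut of a single/complete/average-linkage tree over thousands
of continuous windows routinely splits off a handful of extreme windows
(outlying fragments attach at the top of such trees), so the tree is cut at
increasing depth until two clusters each hold at least 10% of the rows, and
minor fragments join the nearest main centroid.  On balanced, well-separated
data this is identical to the plain cut.  The cluster with higher mean training-fold
ratio FAA becomes Class 1; `p_faa = 0` rows count with Class 2.  The SVM is
RBF with cost 1 and `gamma = 1/(n_features x mean variance)` — on
standardized features effectively `1/n_features` — all configurable; per-fold
labeling is the default, with a global-labeling mode retained for comparison
only (it leaks label information across folds).

Models are fitted **per participant** within each task: skin-conductance
baselines and reactivity are idiosyncratic, so pooling participants turns a
within-person bimodal feature distribution into a multi-participant
continuum that no 2-cluster cut can split by affect (we measured exactly
this failure on pooled synthetic cohorts).  Per validation trial, the
held-out windows of all participants are pooled and the Table-2-shaped
coincidence is computed on the pool, so the report stays one row per
(task, validation trial).

# Problem sizes and numerical choices

Default test and acceptance runs use 5 participants x 4 tasks x 12 trials of
120 s — about 8,000 windows — which exercises every stage at full windowing
fidelity (13,000-sample windows) while keeping a complete pipeline run to a
few minutes; unit fixtures use seconds-to-minutes of signal.  The
full-protocol trial durations (300–1200 s) are the generator's defaults.

Numerical conventions worth knowing: population (divisor-N) standard
deviations in window statistics; natural log in the log-FAA variant; base-2
logs in all information measures; zero-phase filtering throughout, with
mean-centering and reflect-padding around `signal::filtfilt` (whose zero
initial state otherwise injects baseline-sized edge transients at low
cut-offs); equal-frequency ties broken by stable order and inputs with fewer
distinct values than bins rejected rather than silently merged; permutation
p-values never zero by construction.

# Known limitations

* The MI-FAA variant is one of several defensible constructions; its
  behavior on real data is an open question.
* Plain permutation nulls ignore window overlap; block permutation would be
  more conservative.
* The simplified EDA decomposition attributes everything below 0.05 Hz to
  the tonic component, including slow phasic tails; in particular the tonic
  *estimate* inherits a small fatigue confound from SCR event mass even when
  the generated tonic is uncoupled from affect.
* Agglomerative 2-cluster cuts remain sensitive to heavy-tailed features;
  on weakly coupled data the cut can isolate outliers instead of affect
  states (visible as chance-level coincidence, which is the correct
  negative result there).
* Detected SCR rise times are upward-biased by pre-detection smoothing and
  event overlap at high rates.
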