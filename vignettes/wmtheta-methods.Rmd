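---
title: "Methods: spectral, decoding and coherence analysis of working-memory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, decoding and coherence analysis of working-memory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`wmtheta` implements a complete analysis chain for epoched, multichannel EEG
from working-memory experiments with three tasks (delayed match-to-sample,
1-back, 2-back), together with a synthetic-session generator that carries
ground truth for every effect the chain is meant to detect. The four
analyses are:

1. **Spectral power contrasts** -- a variable-cycle Hanning decomposition
   (2-10 Hz in 0.5 Hz steps, 50 ms hops; 2 cycles at 2-3.5 Hz, 3 at
   4-4.5 Hz, 4 at 5-5.5 Hz, 5 at 6-10 Hz) averaged over the delay period
   and contrasted between conditions with a cluster-based permutation test.
2. **Category decoding** -- two-class shrinkage LDA on channel voltages at
   every time point, 5-fold x 5-repeat stratified cross-validation,
   exemplar pair-averaging, temporal generalization, and a channel
   searchlight over the neighbour graph.
3. **Seed-based coherence** -- magnitude-squared coherence between a
   fronto-medial seed (Fz) and every channel in the theta band (4-8 Hz),
   with trial-count-matched subsampling (10 draws) before condition
   contrasts through the same cluster machinery.
4. **Theta peak-frequency statistic** -- per-trial whole-epoch spectra on a
   4-8 Hz, 0.2 Hz grid over the frontal channel set (channel-mean first),
   most-prominent-peak detection, condition means per participant, and a
   paired test of load-dependent slowing, with IRASA 1/f control and
   sliding-mean smoothing (2-5 grid elements) as robustness variants.

The scientific hypothesis the chain serves is the theta "duty cycle" idea:
holding more items in working memory lengthens the theta cycle, so the peak
frequency over fronto-medial channels should decrease slightly (on the
order of 0.1 Hz) from low to high load, while posterior channels carry the
maintained stimulus content and are theta-coupled to the frontal seed.

# The synthetic generator and what it emulates

`simConfig()` fixes the study conditions. Sessions consist of two DMS runs
of 90 trials (15 exemplars x 6 presentations) and 12 n-back blocks (8 x
2-back with 38 trials, 4 x 1-back with 37, i.e. 36 + n), with stimulus
(0.75 s), response (0.75 s) and delay (2.5 s) epochs. Trial durations are
jittered by 0/50/100/150 ms; jitter options are balanced within block to
within one trial (exact balance is impossible at 37/38/90 trials per
block). Ten-second inter-block baselines are available for the n-back
blocks. Epoch arrays are rectangular at the minimum epoch duration with
200 ms of pre-onset padding, so per-epoch baseline correction needs no
cross-epoch stitching; the jitter is recorded in the metadata.

Signal structure:

* **Background**: independent 1/f^chi noise per trial and channel
  (spectral shaping of white noise; default chi = 1, SD 10 uV).
* **Frontal theta**: a sinusoid on the frontal channel set whose per-trial
  frequency is drawn from Normal(mean, 0.4 Hz), truncated symmetrically to
  +/-1 Hz. Condition means are 5.85 Hz (1-back) and 5.77 Hz (2-back); a
  second "IRASA-scenario" preset pair uses 6.05 / 5.99 Hz. The 0.4 Hz
  per-trial jitter is essential: the condition means sit off the 0.2 Hz
  analysis grid, and only the jitter lets trial-averaged detected peaks
  converge to them.
* **Category patterns**: one fixed random spatial pattern per class, added
  on posterior channels during stimulus and delay epochs (default
  2.5 uV). Patterns are constant in time, which is the simplest structure
  a linear per-timepoint decoder can exploit.
* **Coupling**: a common band-limited (4-8 Hz) signal mixed into the seed
  and posterior targets with weight s, plus independent band noise with
  weight 1 - s; s = 0 leaves channels independent.
* **Behaviour**: Bernoulli accuracies (0.94 / 0.93 / 0.96 for 1-back /
  2-back / DMS) with lognormal RTs -- enough to exercise the behavioural
  summaries and the composite-score exclusion screen, nothing more.

The generator does **not** emulate ocular or muscle artifacts, volume
conduction, channel covariance of real scalp data, non-stationary
background, or evoked transients. Passing tests therefore demonstrate that
the chain recovers known effects embedded in realistic 1/f noise at
plausible SNR -- not that it is robust to every pathology of real
recordings. The oscillator amplitude (5 uV against a 10 uV-SD background)
is a free parameter chosen once so that per-trial peak detection is
reliable; real data dictate no value.

The montage is a synthetic quasi-uniform spherical cap (Fibonacci lattice
on the upper hemisphere) with canonical Fz/Pz/Cz/Oz positions snapped in;
the channel count is configurable (64 by default). Neighbourhood radii are
calibrated against a target mean degree (5.7 by default) rather than fixed
in layout units, because the physical meaning of a radius depends on the
montage convention.

# Numerical choices

* **Whole-epoch spectra** are single Hanning-taper estimates evaluated by
  direct DTFT at the 0.2 Hz grid, numerically identical to zero-padding to
  5 s. The native resolution of a 2.5 s epoch is 0.4 Hz; padding refines
  the grid without adding information, which is exactly what the per-trial
  peak statistic needs.
* **Peak detection**: local maxima are strict interior maxima; band-edge
  maxima are not peaks. Prominence is height above the higher of the two
  flanking bases (the minimum between the peak and the nearest higher
  point, or the band edge). Ties go to the lower frequency --
  a deterministic tie-break is required and the lower-frequency choice is
  conservative for slowing effects. Trials with no interior maximum are
  discarded (flagged, never an error), and discarded fractions are
  reported.
* **IRASA** resamples each trace by factors h in 1.1-1.9 (step 0.05,
  paired with 1/h), takes the geometric mean of each h-up/h-down Hanning
  spectrum pair, and the median across factors as the fractal component;
  the oscillatory residual is original minus fractal and may legitimately
  be negative off-peak. Applied per trial (matching the per-trial peak
  pipeline); a condition-average application is available by averaging
  upstream. Single-taper spectra are chi-squared with 2 degrees of
  freedom, so the square root of a product of two of them is biased low by
  Jensen's inequality; the auxiliary up/down spectra are therefore
  smoothed along frequency (13 grid points, computed on an extended grid
  so edges see full windows) before the geometric mean. This removes the
  bias (residual-to-fractal ratio on pure 1/f noise drops from ~50% to
  ~4%) while the median across 17 factors keeps leaked tone energy from
  the smallest factors out of the fractal estimate.
* **Cluster permutation test**: per-bin paired t with the two-tailed
  critical value at alpha as cluster-forming threshold; clusters connect
  suprathreshold bins of equal sign across channel neighbours and
  adjacent frequency/time bins; clusters spanning fewer than 3 distinct
  channels are discarded. The null is the maximum absolute cluster mass
  over random per-unit condition flips; p-values use the add-one
  estimator (so never exactly 0) and are judged at alpha/2 per tail. The
  phrase "at least three neighbouring channels constituting a cluster"
  admits two readings; the spanning-extent reading is the default because
  it is conservative and directly testable, and the per-bin
  neighbour-count reading is available via
  `channel_criterion = "bin-neighbours"`.
* **Holm correction** is deliberately not truncated at 1 by default
  (adjusted values above 1 are reported as computed, e.g. 1.06); a
  `cap = TRUE` option restores the usual convention.
* **LDA regularization**: the pooled within-class covariance is shrunk
  toward a scaled identity with an analytically chosen Ledoit-Wolf-style
  coefficient. This keeps every fit well-posed when features approach
  trials (searchlights, small folds), at the cost of a (documented, <1%)
  deviation from strict invariance under arbitrary linear feature maps.
* **Searchlight features**: the classifier takes channel voltages as
  features at every time point throughout the package; the searchlight
  accordingly decodes per timepoint over (centre + neighbours) channels
  within the analysis window and averages accuracies over timepoints,
  folds and repeats. This matches the per-timepoint feature definition
  used everywhere else and scales linearly in window length.
* **Folds** are stratified by class and reshuffled per repeat; all seeds
  derive from a master seed via a deterministic integer recurrence, so
  every pipeline stage is reproducible bit for bit. Permutation-null
  draws are positional in the unit order; observed t-maps, cluster
  memberships and masses are exactly invariant under unit reordering,
  p-values up to the Monte-Carlo equivalent of redrawing the null.
* **High-pass filtering** is a zero-phase (forward-backward) order-2
  Butterworth, demeaned first and padded by odd reflection over one
  cutoff period to suppress edge transients -- at EEG cutoffs (0.3 Hz)
  the uncorrected transient would dominate short epochs.
* **Resampling** is Fourier-domain (spectrum truncation at the new
  Nyquist), which is anti-aliasing and amplitude-exact for band-limited
  signals; only downsampling is supported because the pipeline never
  upsamples.
* **Coherence aggregation**: cross-spectral densities are averaged over
  trials per (frequency, time) bin, coherence formed, then averaged over
  the window's time bins. Pooling time bins as pseudo-trials before
  normalisation is the other defensible order; it is not the default
  because it conflates within-trial and between-trial phase consistency.
* **DMS categories**: the DMS stimulus set uses three categories (object,
  scene, face; 5 exemplars each, giving the 15-exemplar runs), while the
  n-back tasks and all decoding use the two-class object/scene design.

# Validation problem sizes

The test suite validates parameter recovery on desk-scale cohorts chosen
to keep the full run within minutes while leaving comfortable statistical
margins: peak-frequency recovery uses 28 participants x 40 delay trials
(16-channel montage; 8 channels for the 20 replicate cohorts of the
slowing-significance check), decoding-at-chance uses 40 trials per class
and 20 permutation seeds, cluster-test calibration uses 200 null datasets
of 12 units x 16 channels x 9 frequencies at 200 permutations, and
injection recovery uses a 28-participant cohort on a 32-channel montage
with 20-48 trials per condition. The acceptance script
(`scripts/acceptance.R`) re-runs the recovery analyses from scratch at the
same sizes.

# Known limitations

* The generator's effects are additive and stationary within epochs; none
  of the analyses are stress-tested against non-stationarity or artifact
  residue.
* IRASA is applied per trial on 2.5 s epochs; very low-frequency fractal
  behaviour (below ~1 Hz) is outside the analysed band and unconstrained.
* The cluster test assumes exchangeability across the paired conditions
  within participant; it controls family-wise error for the maximum
  cluster only, as usual for max-statistic procedures.
* Three-class decoding is out of scope (two-at-a-time decoding covers the
  DMS confirmation analyses).
* Serialization uses a plain-text epoch container (TSV + JSON, lossless
  round trip) rather than a binary format; it trades file size for
  dependency-free portability.
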