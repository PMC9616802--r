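#' Construct an EpochSet
#'
#' @param data numeric array trials x channels x samples (microvolt).
#' @param rate sampling rate (Hz).
#' @param times sample times (s, 0 = epoch onset); defaults to a uniform grid
#'   starting at \code{t0}.
#' @param channels channel labels.
#' @param info per-trial metadata data.frame (may be empty).
#' @param t0 time of the first sample when \code{times} is missing.
#' @return an [EpochSet-class].
#' @export
epochSet <- function(data, rate, times = NULL, channels = NULL,
                     info = data.frame(), t0 = 0) {
  d <- dim(data)
  if (is.null(times)) times <- t0 + (seq_len(d[3L]) - 1L) / rate
  if (is.null(channels)) channels <- sprintf("E%03d", seq_len(d[2L]))
  new("EpochSet", data = data, rate = rate, times = times,
      channels = channels, info = info)
}

#' Simulation configuration for synthetic EEG sessions
#'
#' Bundles every knob of the session generator with defaults that emulate the
#' working-memory study design the analysis pipeline targets: two runs of a
#' delayed match-to-sample (DMS) task of 90 trials each (15 exemplars x 6
#' presentations), and 12 n-back blocks (8 x 2-back with 38 trials, 4 x
#' 1-back with 37 trials), with stimulus (0.75 s), response (0.75 s) and
#' delay (2.5 s) epochs, trial-duration jitter of 0/50/100/150 ms balanced
#' within block, and 10 s inter-block baselines. Background activity is 1/f
#' noise; fronto-medial theta oscillators have load-dependent mean frequency
#' (5.85 Hz at load 1, 5.77 Hz at load 2, per-trial SD 0.4 Hz); posterior
#' channels carry category-specific spatial patterns during stimulus and
#' delay; a frontal seed is theta-band coupled to posterior channels.
#'
#' @param n_channels montage size (default 64, synthetic spherical layout).
#' @param head_radius montage sphere radius.
#' @param sampling_rate Hz.
#' @param noise_exponent 1/f slope chi of the background.
#' @param noise_sd background standard deviation (microvolt).
#' @param theta_presets per-condition oscillator presets; each entry a list
#'   \code{mean_freq}, \code{freq_sd}, \code{amplitude} (microvolt).
#' @param irasa_presets alternative oscillator scenario used by the 1/f
#'   control analyses (means 6.05 / 5.99 Hz).
#' @param category_strength posterior class-pattern amplitude (microvolt).
#' @param coupling_strength per-task seed-target mixing weight in [0, 1].
#' @param coupling_amplitude amplitude of the injected band signal
#'   (microvolt).
#' @param accuracy_presets per-task Bernoulli response-accuracy rates.
#' @param task_plan block structure; see defaults.
#' @param durations epoch durations in seconds (stimulus, response, delay,
#'   pre_onset padding, inter-block baseline) and the jitter options.
#' @param master_seed integer; all per-stage seeds are derived from it, so an
#'   identical config reproduces the session byte for byte.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_channels = 64L,
                      head_radius = 1.0,
                      sampling_rate = 256,
                      noise_exponent = 1.0,
                      noise_sd = 10,
                      theta_presets = list(
                        "1-back" = list(mean_freq = 5.85, freq_sd = 0.4,
                                        amplitude = 5),
                        "2-back" = list(mean_freq = 5.77, freq_sd = 0.4,
                                        amplitude = 5),
                        "dms"    = list(mean_freq = 6.0, freq_sd = 0.4,
                                        amplitude = 2)),
                      irasa_presets = list(
                        "1-back" = list(mean_freq = 6.05, freq_sd = 0.4,
                                        amplitude = 5),
                        "2-back" = list(mean_freq = 5.99, freq_sd = 0.4,
                                        amplitude = 5)),
                      category_strength = 2.5,
                      coupling_strength = c("1-back" = 0.6, "2-back" = 0.6,
                                            "dms" = 0.15),
                      coupling_amplitude = 4,
                      accuracy_presets = c("1-back" = 0.94, "2-back" = 0.93,
                                           "dms" = 0.96),
                      task_plan = list(
                        dms_runs = 2L, dms_exemplars = 15L,
                        dms_presentations = 6L,
                        nback_blocks = c("2-back" = 8L, "1-back" = 4L)),
                      durations = list(stimulus = 0.75, response = 0.75,
                                       delay = 2.5, pre_onset = 0.2,
                                       baseline = 10,
                                       jitter = c(0, 0.05, 0.10, 0.15)),
                      master_seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), head_radius = head_radius,
              sampling_rate = sampling_rate, noise_exponent = noise_exponent,
              noise_sd = noise_sd, theta_presets = theta_presets,
              irasa_presets = irasa_presets,
              category_strength = category_strength,
              coupling_strength = coupling_strength,
              coupling_amplitude = coupling_amplitude,
              accuracy_presets = accuracy_presets, task_plan = task_plan,
              durations = durations, master_seed = as.integer(master_seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  dur <- cfg$durations
  if (any(unlist(dur[c("stimulus", "response", "delay", "baseline")]) <= 0))
    stop("all epoch durations must be positive")
  if (dur$stimulus < 0.75 - 1e-9 || dur$delay < 2.5 - 1e-9)
    stop("stimulus must be >= 0.75 s and delay >= 2.5 s")
  for (p in c(cfg$theta_presets, cfg$irasa_presets)) {
    if (p$mean_freq < 4 || p$mean_freq > 8)
      stop("theta preset mean frequencies must lie in [4, 8] Hz")
    if (p$freq_sd < 0 || p$amplitude < 0)
      stop("preset freq_sd and amplitude must be non-negative")
  }
  if (any(cfg$coupling_strength < 0 | cfg$coupling_strength > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (cfg$noise_exponent < 0) stop("noise exponent must be >= 0")
  invisible(TRUE)
}

# deterministic seed derivation: keeps every derived seed inside 32-bit range
deriveSeed <- function(master, ...) {
  ix <- c(master, ...)
  s <- 0
  for (v in ix) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(s)
}

#' Generate 1/f background noise epochs
#'
#' Each trial and channel is an independent realization of Gaussian noise
#' spectrally shaped so that the average power spectral density is
#' proportional to 1/f^chi; the realization is produced by filtering white
#' noise in the frequency domain (phase-preserving spectral shaping) and is
#' rescaled so the expected time-domain standard deviation equals \code{sd}.
#' The DC component is removed.
#'
#' @param n_trials number of epochs.
#' @param layout a [ChannelLayout-class] (defines channel count and labels).
#' @param duration epoch length from onset, in seconds.
#' @param rate sampling rate (Hz).
#' @param exponent 1/f slope chi (>= 0; 0 = white noise).
#' @param seed integer seed.
#' @param sd target standard deviation in microvolt.
#' @param pre_onset seconds of padding before time 0 included in the epoch.
#' @param info optional per-trial metadata.
#' @return an [EpochSet-class].
#' @export
generateNoise <- function(n_trials, layout, duration, rate, exponent = 1,
                          seed = 1L, sd = 10, pre_onset = 0,
                          info = data.frame()) {
  if (duration <= 0 || rate <= 0) stop("duration and rate must be positive")
  if (duration * rate < 2) stop("duration x rate must be >= 2")
  if (exponent < 0) stop("exponent must be >= 0")
  nch <- nChannels(layout)
  ns <- round((duration + pre_onset) * rate)
  m <- n_trials * nch
  freqs <- c(0, seq_len(ns - 1)) / ns * rate
  freqs <- pmin(freqs, rate - freqs)          # two-sided |f|
  gain <- numeric(ns)
  nz <- freqs > 0
  gain[nz] <- freqs[nz]^(-exponent / 2)
  norm <- sqrt(mean(gain^2))
  w <- withSeed(seed, matrix(stats::rnorm(ns * m), ns, m))
  sh <- Re(stats::mvfft(stats::mvfft(w) * gain, inverse = TRUE)) / ns
  x <- sh * (sd / norm)
  dat <- aperm(array(x, dim = c(ns, n_trials, nch)), c(2, 3, 1))
  epochSet(dat, rate, channels = channelNames(layout), info = info,
           t0 = -pre_onset)
}

#' Embed a theta-band oscillator into target channels
#'
#' Adds, on the listed channels only and for times inside \code{window}
#' (half-open, relative to epoch onset), a sinusoid whose per-trial frequency
#' is drawn from Normal(\code{mean_freq}, \code{freq_sd}) truncated
#' symmetrically to \code{mean_freq} +/- 1 Hz, with an independent uniform
#' phase per trial. The drawn frequencies and phases are returned as the
#' ground-truth manifest.
#'
#' @param epochs an [EpochSet-class].
#' @param channels target channel labels.
#' @param mean_freq,freq_sd oscillator frequency distribution (Hz).
#' @param amplitude sinusoid amplitude (microvolt); 0 returns the input
#'   unchanged.
#' @param seed integer seed.
#' @param window half-open time window [start, end) in seconds; defaults to
#'   all t >= 0 (the pre-onset padding is left untouched).
#' @return list with elements \code{epochs} (modified [EpochSet-class]) and
#'   \code{manifest} (data.frame: trial, freq_hz, phase).
#' @export
embedOscillation <- function(epochs, channels, mean_freq, freq_sd, amplitude,
                             seed = 1L, window = c(0, Inf)) {
  chIdx <- matchChannels(epochs, channels)
  if (mean_freq - 3 * freq_sd < 0)
    stop("mean_freq - 3*freq_sd must stay positive")
  n <- nTrials(epochs)
  draws <- withSeed(seed, {
    f <- stats::rnorm(n, mean_freq, freq_sd)
    bad <- abs(f - mean_freq) > 1
    while (any(bad)) {
      f[bad] <- stats::rnorm(sum(bad), mean_freq, freq_sd)
      bad <- abs(f - mean_freq) > 1
    }
    list(freq = if (freq_sd > 0) f else rep(mean_freq, n),
         phase = stats::runif(n, 0, 2 * pi))
  })
  manifest <- data.frame(trial = seq_len(n), freq_hz = draws$freq,
                         phase = draws$phase)
  if (amplitude != 0) {
    t <- epochTimes(epochs)
    inWin <- t >= window[1] & t < window[2]
    tw <- t[inWin]
    # trials x times sinusoid, added to every target channel
    osc <- amplitude * sin(2 * pi * outer(draws$freq, tw) + draws$phase)
    dat <- epochs@data
    for (ci in chIdx) dat[, ci, inWin] <- dat[, ci, inWin] + osc
    epochs@data <- dat
  }
  list(epochs = epochs, manifest = manifest)
}

#' Embed category-specific spatial patterns
#'
#' Draws one fixed random spatial pattern per class (standard normal over the
#' target channels, scaled by \code{strength}) and adds the pattern of each
#' trial's class to the target channels at all times inside \code{window}.
#' Non-target channels and out-of-window samples are untouched. The class
#' patterns are drawn once from \code{seed}, so the same seed yields the same
#' patterns across epochs of one session (stimulus and delay epochs share
#' their patterns by sharing the seed).
#'
#' @param epochs an [EpochSet-class] whose \code{trialInfo} has a
#'   \code{category} column with at least two classes.
#' @param channels target channel labels.
#' @param strength pattern amplitude (microvolt); 0 returns input unchanged.
#' @param seed pattern seed.
#' @param window half-open time window in seconds (default: all t >= 0).
#' @return list with \code{epochs} and \code{patterns} (class x channel
#'   matrix actually injected).
#' @export
embedCategoryPattern <- function(epochs, channels, strength, seed = 1L,
                                 window = c(0, Inf)) {
  info <- trialInfo(epochs)
  if (!"category" %in% names(info))
    stop("trialInfo must contain a 'category' column")
  classes <- sort(unique(as.character(info$category)))
  if (length(classes) < 2L) stop("at least two classes required")
  chIdx <- matchChannels(epochs, channels)
  pat <- withSeed(seed,
    matrix(stats::rnorm(length(classes) * length(chIdx)), length(classes),
           dimnames = list(classes, epochs@channels[chIdx]))) * strength
  if (strength != 0) {
    t <- epochTimes(epochs)
    inWin <- which(t >= window[1] & t < window[2])
    dat <- epochs@data
    cls <- match(as.character(info$category), classes)
    for (j in seq_along(chIdx)) {
      add <- pat[cls, j]                       # per-trial offset
      dat[, chIdx[j], inWin] <- dat[, chIdx[j], inWin] + add
    }
    epochs@data <- dat
  }
  list(epochs = epochs, patterns = pat)
}

#' Embed band-limited coupling between a seed and target channels
#'
#' Per trial, a common band-limited signal s(t) is generated and mixed into
#' the seed and every target channel with weight \code{strength}; each
#' channel additionally receives an independent band-limited noise with
#' weight \code{1 - strength}. At strength 1 the seed and targets share an
#' identical added signal; at strength 0 all added signals are independent,
#' leaving the channels uncoupled.
#'
#' @param epochs an [EpochSet-class].
#' @param seed_channel seed label.
#' @param target_channels target labels (must not contain the seed).
#' @param band frequency band c(low, high) in Hz of the injected signals.
#' @param strength mixing weight in [0, 1].
#' @param seed integer seed.
#' @param amplitude amplitude (standard deviation, microvolt) of each added
#'   signal.
#' @param window half-open time window in seconds (default: all t >= 0).
#' @return the modified [EpochSet-class].
#' @export
embedCoupling <- function(epochs, seed_channel, target_channels, band,
                          strength, seed = 1L, amplitude = 4,
                          window = c(0, Inf)) {
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  if (seed_channel %in% target_channels)
    stop("seed channel must not be among the targets")
  sIdx <- matchChannels(epochs, seed_channel)
  tIdx <- matchChannels(epochs, target_channels)
  n <- nTrials(epochs)
  t <- epochTimes(epochs)
  inWin <- which(t >= window[1] & t < window[2])
  ns <- length(inWin)
  rate <- samplingRate(epochs)
  nsig <- 1L + length(tIdx)                    # common + one indep per channel
  sig <- withSeed(seed, {
    w <- matrix(stats::rnorm(ns * n * (nsig + 1L)), ns)
    bandLimit(w, rate, band)
  })
  dat <- epochs@data
  allIdx <- c(sIdx, tIdx)
  for (k in seq_along(allIdx)) {
    common <- sig[, seq_len(n)]
    indep <- sig[, k * n + seq_len(n)]
    add <- amplitude * (strength * common + (1 - strength) * indep)
    dat[, allIdx[k], inWin] <- dat[, allIdx[k], inWin] + t(add)
  }
  epochs@data <- dat
  epochs
}

# zero every FFT bin outside [band1, band2] and renormalise columns to sd 1
bandLimit <- function(w, rate, band) {
  ns <- nrow(w)
  f <- (seq_len(ns) - 1) / ns * rate
  f <- pmin(f, rate - f)
  keep <- f >= band[1] & f <= band[2]
  W <- stats::mvfft(w)
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / ns
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

matchChannels <- function(epochs, channels) {
  idx <- match(channels, epochs@channels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  idx
}

#' Frontal / posterior channel sets of a montage
#'
#' Channels within \code{radius} (head-radius units) of the canonical Fz
#' (frontal set) or Pz (posterior set) position; used as the default
#' injection targets of the session generator.
#'
#' @param layout a [ChannelLayout-class].
#' @param radius inclusion radius.
#' @return character vector of labels.
#' @export
frontalChannels <- function(layout, radius = 0.5) {
  nearChannel(layout, c(0, sqrt(0.5), sqrt(0.5)), radius)
}

#' @rdname frontalChannels
#' @export
posteriorChannels <- function(layout, radius = 0.5) {
  nearChannel(layout, c(0, -sqrt(0.5), sqrt(0.5)), radius)
}

nearChannel <- function(layout, ref, radius) {
  pos <- layout@positions / layout@headRadius
  d <- sqrt(colSums((t(pos) - ref)^2))
  layout@labels[d <= radius]
}
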