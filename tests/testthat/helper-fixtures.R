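# Shared fixtures, built in code at test time.

lay16 <- makeMontage(16)
lay8 <- makeMontage(8)
adj16 <- channelNeighbours(lay16, calibrateNeighbourRadius(lay16, 5.7))

# epochs of pure sinusoids: one trial per row of freq/amp/phase
toneEpochs <- function(freq, amp = 1, phase = 0, duration = 2.5,
                       rate = 256, n_channels = 1, pre_onset = 0,
                       info = data.frame()) {
  t <- seq(-pre_onset, duration - 1 / rate, by = 1 / rate)
  n <- length(freq)
  dat <- array(0, c(n, n_channels, length(t)))
  for (i in seq_len(n))
    for (ch in seq_len(n_channels))
      dat[i, ch, ] <- amp[min(i, length(amp))] *
        sin(2 * pi * freq[i] * t + phase[min(i, length(phase))])
  epochSet(dat, rate, channels = sprintf("E%03d", seq_len(n_channels)),
           info = info, t0 = -pre_onset)
}

# random epochs with labelled metadata for decoding fixtures
randomEpochs <- function(n_trials, n_channels, n_samples, rate = 100,
                         seed = 1, t0 = 0, info = data.frame()) {
  set.seed(seed)
  dat <- array(rnorm(n_trials * n_channels * n_samples),
               c(n_trials, n_channels, n_samples))
  epochSet(dat, rate, channels = sprintf("E%03d", seq_len(n_channels)),
           info = info, t0 = t0)
}

# log-log slope of the trial-mean periodogram (independent Welch-style
# oracle for the noise generator)
spectrumSlope <- function(epochs, fmin = 1, fmax = 40) {
  m <- matrix(epochData(epochs)[, 1, ], nrow = dim(epochData(epochs))[1])
  ps <- Mod(stats::mvfft(t(m)))^2
  f <- (seq_len(ncol(m)) - 1) / ncol(m) * samplingRate(epochs)
  sel <- f > fmin & f < fmax
  unname(coef(lm(log(rowMeans(ps)[sel]) ~ log(f[sel])))[2])
}
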