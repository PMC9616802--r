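test_that("time-resolved power: zeros, stationary tone, DFT oracle", {
  zero <- epochSet(array(0, c(2, 1, 640)), 256)
  tf0 <- tfPower(zero)
  expect_true(all(spectralPower(tf0) == 0 | is.na(spectralPower(tf0))))
  tone <- toneEpochs(6, duration = 2.5, pre_onset = 0.2)
  tf <- tfPower(tone)
  pw <- spectralPower(tf)[1, 1, , ]
  valid <- colSums(is.na(pw)) == 0
  expect_true(all(spectralFreqs(tf)[apply(pw[, valid], 2, which.max)] == 6))
  p6 <- pw[spectralFreqs(tf) == 6, valid]
  expect_lt(diff(range(p6)) / mean(p6), 0.01)
  # independent single-window Hanning DFT oracle, identical normalization
  k <- which(spectralFreqs(tf) == 6)
  L <- round(5 / 6 * 256)
  ti <- which.min(abs(spectralTimes(tf) - 1.0))
  ctr <- round((spectralTimes(tf)[ti] - epochTimes(tone)[1]) * 256) + 1
  idx <- (ctr - floor((L - 1) / 2)):(ctr + ceiling((L - 1) / 2))
  hw <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  tau <- (seq_len(L) - (L + 1) / 2) / 256
  oracle <- Mod(sum(epochData(tone)[1, 1, idx] * hw *
                      exp(-2i * pi * 6 * tau)) * 2 / sum(hw))^2
  expect_equal(spectralPower(tf)[1, 1, k, ti], oracle,
               tolerance = 1e-6 * oracle)
  short <- epochSet(array(0, c(1, 1, 100)), 256)
  expect_error(tfPower(short), "2 Hz")
})

test_that("whole-epoch spectrum localises tones and scales as power", {
  tone <- toneEpochs(6, duration = 2.5)
  se <- epochSpectrum(tone)
  sp <- channelMeanSpectra(se)
  expect_equal(seq(4, 8, 0.2)[which.max(sp[1, ])], 6)
  t0 <- seq(0, 2.5 - 1 / 256, by = 1 / 256)
  two <- epochSet(array(2 * sin(2 * pi * 5 * t0) + sin(2 * pi * 7 * t0),
                        c(1, 1, length(t0))), 256)
  sp2 <- channelMeanSpectra(epochSpectrum(two))
  freqs <- seq(4, 8, 0.2)
  expect_gt(sp2[1, freqs == 5], sp2[1, freqs == 7])
  expect_equal(unname(sp2[1, freqs == 5] / sp2[1, freqs == 7]), 4,
               tolerance = 0.4)                       # amplitude 2 -> power 4
  # denser grid does not move an on-grid tone's maximum
  fine <- channelMeanSpectra(epochSpectrum(tone, grid_step = 0.1,
                                           pad_to = 10))
  expect_equal(seq(4, 8, 0.1)[which.max(fine[1, ])], 6)
  expect_error(epochSpectrum(tone, grid_step = 0.1, pad_to = 5), "finer")
})

test_that("IRASA separates fractal background from oscillatory peaks", {
  lay2 <- makeMontage(2)
  pink <- generateNoise(100, lay2, 2.5, 256, 1, seed = 11,
                        pre_onset = 0.2)
  ir <- irasa(pink)
  resid <- mean(abs(apply(ir$oscillatory, 3, mean)))
  frac <- mean(spectralPower(ir$fractal))
  expect_lt(resid / frac, 0.10)
  tone <- embedOscillation(pink, channelNames(lay2), 6, 0, 5, seed = 2)
  irt <- irasa(tone$epochs)
  expect_lt(abs(irt$freqs[which.max(apply(irt$oscillatory, 3, mean))] - 6),
            0.21)
  white <- generateNoise(60, lay2, 2.5, 256, 0, seed = 12)
  irw <- irasa(white)
  fw <- apply(spectralPower(irw$fractal), 3, mean)
  expect_lt(abs(unname(coef(lm(log(fw) ~ log(irw$freqs)))[2])), 0.1)
  expect_error(irasa(pink, factors = numeric(0)), "empty")
})

test_that("spectral smoothing equals the brute-force windowed mean", {
  expect_equal(smoothSpectrum(rep(2, 10), 3), rep(2, 10))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(smoothSpectrum(imp, 3), c(0, 0, 1, 1, 1, 0, 0) / 3)
  set.seed(13)
  x <- runif(21)
  out <- smoothSpectrum(x, 4)
  hl <- 1; hr <- 2
  brute <- sapply(seq_along(x), function(i)
    mean(x[max(1, i - hl):min(length(x), i + hr)]))
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("peak detection follows the prominence rule with deterministic
           tie-breaks", {
  freqs <- seq(4, 8, 0.2)
  mono <- detectPeak(21:1, freqs)
  expect_true(mono$discarded)
  expect_true(is.na(mono$peak_hz))
  single <- rep(1, 21); single[11] <- 3
  expect_equal(detectPeak(single, freqs)$peak_hz, 6.0)
  # hand-computed prominences on a 21-point toy spectrum:
  # peak at 5 Hz: height 4, bases 1 (left edge region) and 2 (valley)
  #   -> prominence 4 - max(1, 2) = 2... exceeded by design below
  toy <- rep(1, 21)
  toy[6] <- 4            # 5 Hz
  toy[9] <- 2            # valley shoulder is the flanking min for both
  toy[16] <- 2.5         # 7 Hz, smaller prominence
  res <- detectPeak(toy, freqs)
  expect_equal(res$peak_hz, 5.0)
  expect_equal(res$prominence, 3)           # 4 - max(min=1, min=1)
  tie <- rep(1, 21); tie[c(6, 16)] <- 2
  expect_equal(detectPeak(tie, freqs)$peak_hz, 5.0)
  # scale invariance of the peak choice
  expect_equal(detectPeak(toy * 17.3, freqs)$peak_hz, 5.0)
  # band-edge maxima are not peaks: global max at the edge, no interior max
  edge <- c(5, 1:20)
  expect_true(detectPeak(edge, freqs)$discarded)
})

test_that("condition peak means aggregate non-discarded trials", {
  pk <- data.frame(trial = 1:4, peak_hz = c(5.8, 5.8, 5.6, 6.0),
                   prominence = 1, discarded = FALSE,
                   participant = c(1, 1, 2, 2),
                   condition = "1-back")
  cm <- conditionPeakMeans(pk)
  expect_equal(cm$mean_peak_hz, c(5.8, 5.8))
  pk$discarded[3] <- TRUE
  cm2 <- conditionPeakMeans(pk)
  expect_equal(cm2$mean_peak_hz[cm2$participant == 2], 6.0)
  expect_equal(cm2$discarded_fraction[cm2$participant == 2], 0.5)
  pk$discarded[3:4] <- TRUE
  expect_warning(cm3 <- conditionPeakMeans(pk), "discarded")
  expect_true(is.na(cm3$mean_peak_hz[cm3$participant == 2]))
})

test_that("spectral estimates are invariant to trial and channel order", {
  info <- data.frame(category = rep(c("a", "b"), 5))
  ep <- randomEpochs(10, 3, 640, rate = 256, seed = 14, info = info)
  se <- epochSpectrum(ep)
  perm <- c(7, 2, 9, 1, 10, 3, 8, 5, 4, 6)
  sePerm <- epochSpectrum(subsetEpochs(ep, trials = perm))
  expect_equal(spectralPower(sePerm), spectralPower(se)[perm, , ,
                                                        drop = FALSE])
  chPerm <- c(3, 1, 2)
  seCh <- epochSpectrum(subsetEpochs(ep, channels = chPerm))
  expect_equal(spectralPower(seCh), spectralPower(se)[, chPerm, ,
                                                      drop = FALSE])
})
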