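test_that("1/f noise generator hits the requested spectral slope", {
  lay1 <- makeMontage(1)
  white <- generateNoise(100, lay1, 2, 256, exponent = 0, seed = 1)
  expect_lt(abs(spectrumSlope(white)), 0.08)
  pink <- generateNoise(100, lay1, 2, 256, exponent = 1, seed = 2)
  expect_lt(abs(spectrumSlope(pink) + 1), 0.1)
  expect_equal(sd(epochData(pink)), 10, tolerance = 0.05)
  expect_error(generateNoise(10, lay1, -1, 256), "positive")
})

test_that("noise generation is byte-identical under a fixed seed", {
  a <- generateNoise(5, lay8, 1, 128, 1, seed = 42)
  b <- generateNoise(5, lay8, 1, 128, 1, seed = 42)
  expect_identical(epochData(a), epochData(b))
  c <- generateNoise(5, lay8, 1, 128, 1, seed = 43)
  expect_false(identical(epochData(a), epochData(c)))
})

test_that("oscillator embedding: identity at zero amplitude, pure-tone peak,
           manifest statistics", {
  ep <- generateNoise(20, lay8, 2.5, 256, 1, seed = 3, pre_onset = 0.2)
  out0 <- embedOscillation(ep, "Fz", 6, 0.4, amplitude = 0, seed = 1)
  expect_identical(epochData(out0$epochs), epochData(ep))
  # amplitude >> noise, no jitter: band spectrum peaks at 6.0 Hz
  big <- embedOscillation(ep, "Fz", 6, 0, amplitude = 100, seed = 1)
  sp <- channelMeanSpectra(epochSpectrum(big$epochs), "Fz")
  freqs <- seq(4, 8, 0.2)
  expect_true(all(freqs[apply(sp, 1, which.max)] == 6))
  expect_error(embedOscillation(ep, "NOPE", 6, 0.4, 1), "unknown channel")
})

test_that("manifest frequencies are truncated draws centred on the preset", {
  ep <- generateNoise(200, lay8, 2.5, 256, 1, seed = 4, pre_onset = 0.2)
  em <- embedOscillation(ep, "Fz", 5.85, 0.4, amplitude = 1, seed = 9)
  f <- em$manifest$freq_hz
  expect_length(f, 200)
  expect_true(all(abs(f - 5.85) <= 1))       # symmetric truncation
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 5.85), 3 * se)     # CLT check on the manifest
})

test_that("category patterns separate classes on target channels only", {
  info <- data.frame(category = rep(c("object", "scene"), 30),
                     exemplar = rep(paste0("x", 1:10), 6))
  ep <- generateNoise(60, lay16, 2.5, 256, 1, seed = 5, pre_onset = 0.2,
                      info = info)
  out0 <- embedCategoryPattern(ep, posteriorChannels(lay16, 0.6), 0,
                               seed = 2)
  expect_identical(epochData(out0$epochs), epochData(ep))
  post <- posteriorChannels(lay16, 0.6)
  strong <- embedCategoryPattern(ep, post, 100, seed = 2)
  # centroid classifier on held-out trials: channel-mean vectors per trial
  feats <- apply(epochData(strong$epochs)[,
    match(post, channelNames(ep)), epochTimes(ep) >= 0], c(1, 2), mean)
  train <- seq_len(40); test <- 41:60
  cls <- info$category
  cent <- rbind(colMeans(feats[train[cls[train] == "object"], ]),
                colMeans(feats[train[cls[train] == "scene"], ]))
  pred <- c("object", "scene")[apply(feats[test, ], 1, function(v)
    which.min(c(sum((v - cent[1, ])^2), sum((v - cent[2, ])^2))))]
  expect_equal(mean(pred == cls[test]), 1.0)
  # frontal channels untouched
  fr <- match(setdiff(frontalChannels(lay16, 0.4), post),
              channelNames(ep))
  expect_identical(epochData(strong$epochs)[, fr, ],
                   epochData(ep)[, fr, ])
  expect_error(embedCategoryPattern(
    subsetEpochs(ep, trials = cls == "object"), post, 1, 1),
    "two classes")
})

test_that("coupling embeds shared band signal with coherent targets", {
  laySmall <- makeMontage(8)
  quiet <- generateNoise(100, laySmall, 1.5, 256, 1, seed = 6, sd = 0.01)
  coupled <- embedCoupling(quiet, "Fz", c("Pz", "Oz"), c(4, 8), 1,
                           seed = 2, amplitude = 10)
  cs <- crossSpectra(coupled, "Fz", freqs = seq(4, 8, 0.5), step = 0.1)
  cm <- coherenceMap(cs, c(4, 8))
  expect_gte(min(coherenceValues(cm)[c("Pz", "Oz"), ]), 0.95)
  expect_error(embedCoupling(quiet, "Fz", c("Fz", "Pz"), c(4, 8), 0.5),
               "seed channel")
})

test_that("coherence under independence matches the 1/N bias and grows
           with coupling strength", {
  laySmall <- makeMontage(8)
  base <- generateNoise(200, laySmall, 1.5, 256, 1, seed = 7)
  indep <- embedCoupling(base, "Fz", c("Pz", "Oz"), c(4, 8), 0,
                         seed = 3, amplitude = 10)
  cs <- crossSpectra(indep, "Fz", freqs = seq(4, 8, 1), step = 0.25)
  cm <- coherenceMap(cs, c(4, 8))
  bias <- mean(coherenceValues(cm)[c("Pz", "Oz"), ])
  expect_lt(abs(bias - 1 / 200), 0.5 / 200)  # analytic independence bias
  coh <- sapply(c(0.2, 0.5, 0.8), function(s) {
    ep <- embedCoupling(base, "Fz", "Pz", c(4, 8), s, seed = 4,
                        amplitude = 10)
    cs <- crossSpectra(ep, "Fz", freqs = seq(4, 8, 1), step = 0.25)
    mean(coherenceValues(coherenceMap(cs, c(4, 8)))["Pz", ])
  })
  expect_true(all(diff(coh) > 0))
})

test_that("session layout matches the experimental plan", {
  tab <- nbackTrialTable(c("2-back" = 8L, "1-back" = 4L), seed = 1)
  counts <- table(tab$task[!duplicated(tab$block)])
  expect_equal(as.integer(counts[c("2-back", "1-back")]), c(8L, 4L))
  perBlock <- table(tab$block)
  expect_true(all(perBlock[unique(tab$block[tab$task == "1-back"])] == 37))
  expect_true(all(perBlock[unique(tab$block[tab$task == "2-back"])] == 38))
  # jitter options balanced within block (counts differ by at most one)
  for (b in unique(tab$block)) {
    jt <- table(factor(tab$jitter_s[tab$block == b],
                       levels = c(0, 0.05, 0.10, 0.15)))
    expect_lte(diff(range(jt)), 1)
  }
  dms <- rbind(dmsTrialTable(1, seed = 2), dmsTrialTable(2, seed = 3))
  expect_equal(nrow(dms), 180L)
  expect_equal(as.integer(table(dms$exemplar)), rep(12L, 15L))
})

test_that("simulated sessions are reproducible and carry ground truth", {
  cfg <- simConfig(n_channels = 8, master_seed = 5,
                   task_plan = list(dms_runs = 1L, dms_exemplars = 15L,
                                    dms_presentations = 6L,
                                    nback_blocks = c("2-back" = 1L,
                                                     "1-back" = 1L)))
  s1 <- simulateSession(cfg, participant = 1, tasks = "1-back",
                        epoch_types = "delay")
  s2 <- simulateSession(cfg, participant = 1, tasks = "1-back",
                        epoch_types = "delay")
  expect_identical(epochData(s1$epochs[["1-back"]]$delay),
                   epochData(s2$epochs[["1-back"]]$delay))
  expect_equal(nTrials(s1$epochs[["1-back"]]$delay), 37L)
  expect_true(all(!is.na(s1$manifest$trials$theta_freq_hz)))
  expect_true(all(abs(s1$manifest$trials$theta_freq_hz - 5.85) <= 1))
  expect_identical(s1$manifest$effects$frontal_channels,
                   frontalChannels(s1$layout, 0.5))
  s3 <- simulateSession(cfg, participant = 2, tasks = "1-back",
                        epoch_types = "delay")
  expect_false(identical(epochData(s1$epochs[["1-back"]]$delay),
                         epochData(s3$epochs[["1-back"]]$delay)))
})

test_that("manifest JSON-lines round trip preserves the trial records", {
  cfg <- simConfig(n_channels = 8, master_seed = 5)
  ep <- generateNoise(6, lay8, 2.5, 128, 1, seed = 1, pre_onset = 0.2)
  em <- embedOscillation(ep, "Fz", 6, 0.3, 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeManifest(em$manifest, f)
  back <- readManifest(f)
  expect_equal(back$freq_hz, em$manifest$freq_hz, tolerance = 1e-12)
  expect_equal(nrow(back), 6L)
})
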