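makeDecodeFixture <- function(n_per_class = 20, n_channels = 8,
                              n_samples = 60, rate = 100, sep = 0,
                              seed = 1, window = NULL) {
  set.seed(seed)
  n <- 2 * n_per_class
  info <- data.frame(category = rep(c("object", "scene"), n_per_class),
                     exemplar = rep(paste0("e", 1:4),
                                    length.out = n))
  dat <- array(rnorm(n * n_channels * n_samples),
               c(n, n_channels, n_samples))
  if (sep > 0) {
    pat <- rnorm(n_channels)
    pat <- pat / sqrt(sum(pat^2)) * sep
    sIdx <- if (is.null(window)) seq_len(n_samples) else window
    for (i in which(info$category == "object"))
      dat[i, , sIdx] <- dat[i, , sIdx] + pat
    for (i in which(info$category == "scene"))
      dat[i, , sIdx] <- dat[i, , sIdx] - pat
  }
  epochSet(dat, rate, channels = sprintf("E%03d", seq_len(n_channels)),
           info = info)
}

test_that("pair averaging pairs within exemplar and passes odd trials", {
  info <- data.frame(category = "object", exemplar = rep("a", 11))
  ep <- randomEpochs(11, 2, 10, seed = 2, info = info)
  out <- pairAverage(ep, seed = 1)
  expect_equal(nTrials(out$epochs), 6L)     # 5 pairs + 1 remainder
  expect_equal(sum(is.na(out$pairs$member2)), 1L)
  # identical trials average to themselves
  ep2 <- randomEpochs(2, 2, 10, seed = 3,
                      info = data.frame(exemplar = c("b", "b")))
  ep2@data[2, , ] <- ep2@data[1, , ]
  out2 <- pairAverage(ep2, seed = 1)
  expect_equal(nTrials(out2$epochs), 1L)
  expect_equal(epochData(out2$epochs)[1, , ], ep2@data[1, , ])
  # every output equals the brute-force mean of its recorded members
  info8 <- data.frame(exemplar = rep(c("a", "b"), each = 4),
                      category = "x")
  ep8 <- randomEpochs(8, 3, 12, seed = 4, info = info8)
  out8 <- pairAverage(ep8, seed = 5)
  for (i in seq_len(nrow(out8$pairs))) {
    m <- unlist(out8$pairs[i, c("member1", "member2")])
    m <- m[!is.na(m)]
    expect_equal(epochData(out8$epochs)[i, , ],
                 apply(epochData(ep8)[m, , , drop = FALSE], c(2, 3),
                       mean),
                 tolerance = 1e-12)
    expect_identical(trialInfo(out8$epochs)$exemplar[i],
                     info8$exemplar[m[1]])
  }
  expect_error(pairAverage(randomEpochs(4, 2, 5)), "exemplar")
})

test_that("decoding sits at chance without structure and at ceiling with
           separable classes", {
  accs <- sapply(1:6, function(s) {
    ep <- makeDecodeFixture(20, 8, 30, seed = 100 + s)
    mean(accuracy(crossvalDecode(ep, seed = s)))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
  sep <- makeDecodeFixture(15, 8, 20, sep = 20, seed = 7)
  expect_equal(mean(accuracy(crossvalDecode(sep, seed = 1))), 1.0)
  few <- makeDecodeFixture(4, 4, 10, seed = 8)
  expect_error(crossvalDecode(few, folds = 5), "at least")
})

test_that("accuracy approaches the analytic Bayes rate for Gaussian
           classes", {
  set.seed(30)
  p <- 6; n <- 400
  delta <- rep(0.3, p)                      # shared-covariance Gaussians
  y <- rep(c("a", "b"), n / 2)
  dat <- array(rnorm(n * p * 3), c(n, p, 3))
  for (i in which(y == "a")) dat[i, , ] <- dat[i, , ] + delta / 2
  for (i in which(y == "b")) dat[i, , ] <- dat[i, , ] - delta / 2
  ep <- epochSet(dat, 10, info = data.frame(category = y))
  acc <- mean(accuracy(crossvalDecode(ep, seed = 2)))
  bayes <- pnorm(sqrt(sum(delta^2)) / 2)
  expect_lt(abs(acc - bayes), 0.03)
})

test_that("temporal generalization matches the diagonal and localises a
           windowed pattern", {
  ep <- makeDecodeFixture(15, 6, 20, sep = 8, seed = 9, window = 6:15)
  tg <- temporalGeneralization(ep, folds = 5, repeats = 2, seed = 3)
  diagAcc <- diag(accuracy(tg))
  cv <- crossvalDecode(ep, folds = 5, repeats = 2, seed = 3)
  expect_identical(diagAcc, unname(accuracy(cv)))
  M <- accuracy(tg)
  inWin <- 6:15
  outWin <- 1:4
  expect_gt(mean(M[inWin, inWin]), 0.9)
  expect_lt(abs(mean(M[outWin, outWin]) - 0.5), 0.15)
  expect_lt(abs(mean(M[inWin, outWin]) - 0.5), 0.15)
  # a sustained pattern generalises across its whole support
  sus <- makeDecodeFixture(15, 6, 20, sep = 8, seed = 10)
  Ms <- accuracy(temporalGeneralization(sus, folds = 5, repeats = 2,
                                        seed = 4))
  expect_gt(min(Ms), 0.85)
})

test_that("searchlight decoding localises an injected posterior pattern", {
  set.seed(31)
  n <- 40
  info <- data.frame(category = rep(c("object", "scene"), n / 2),
                     exemplar = rep(paste0("e", 1:4), n / 4))
  ep <- generateNoise(n, lay16, 1.0, 128, 0, seed = 31, sd = 1,
                      info = info)
  post <- posteriorChannels(lay16, 0.45)
  strong <- embedCategoryPattern(ep, post, 3, seed = 5)
  res <- searchlightDecode(strong$epochs, adj16, c(0, 1), folds = 5,
                           repeats = 2, seed = 6)
  acc <- accuracy(res)
  expect_true(names(which.max(acc)) %in%
                unique(c(post, unlist(lapply(post, function(ch)
                  names(which(adj16[ch, ])))))))
  far <- setdiff(names(acc)[acc < quantile(acc, 0.3)], post)
  expect_lt(abs(mean(acc[far]) - 0.5), 0.1)
  # structureless noise stays at chance across the map
  res0 <- searchlightDecode(ep, adj16, c(0, 1), folds = 5, repeats = 2,
                            seed = 7)
  expect_lt(abs(mean(accuracy(res0)) - 0.5), 0.04)
})

test_that("group-level significance finds injected windows and nothing
           else", {
  times <- seq(0, 1.95, by = 0.05)
  flat <- matrix(0.5, 12, length(times))
  res0 <- decodeSignificance(flat, times, n_perm = 100, seed = 1)
  expect_equal(nrow(res0$windows), 0L)
  set.seed(32)
  acc <- matrix(0.5 + rnorm(28 * length(times), sd = 0.02), 28)
  win <- times >= 0.8 & times <= 1.2       # 400 ms elevation
  acc[, win] <- acc[, win] + 0.15
  res <- decodeSignificance(acc, times, n_perm = 200, seed = 2)
  expect_gte(nrow(res$windows), 1L)
  detected <- times >= res$windows$start[1] & times <= res$windows$end[1]
  overlap <- sum(win & detected) / sum(win)
  expect_gte(overlap, 0.8)
  res2 <- decodeSignificance(acc, times, n_perm = 200, seed = 2)
  expect_identical(res$windows, res2$windows)
  expect_error(decodeSignificance(acc[1, , drop = FALSE], times),
               "2 participants")
})

test_that("accuracy is invariant to channel reordering", {
  ep <- makeDecodeFixture(15, 6, 10, sep = 2, seed = 11)
  a1 <- accuracy(crossvalDecode(ep, seed = 5))
  perm <- c(4, 1, 6, 2, 5, 3)
  a2 <- accuracy(crossvalDecode(subsetEpochs(ep, channels = perm),
                                seed = 5))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("pair averaging does not hurt decodability of noisy patterns", {
  better <- sapply(1:8, function(s) {
    ep <- makeDecodeFixture(20, 6, 10, sep = 1.2, seed = 200 + s)
    raw <- mean(accuracy(crossvalDecode(ep, seed = s)))
    pa <- pairAverage(ep, seed = s)$epochs
    avg <- mean(accuracy(crossvalDecode(pa, seed = s)))
    avg - raw
  })
  expect_gt(mean(better), 0)
})
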