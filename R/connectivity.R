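#' Seed-based cross-spectral densities
#'
#' Computes the time-resolved Hanning decomposition (same variable-cycle
#' settings as [tfPower()]) with coefficients retained, and forms per-trial
#' cross-spectral densities CSD(seed, ch, f, t) = F_seed conj(F_ch) together
#' with the auto-spectra of every channel.
#'
#' @param epochs an [EpochSet-class].
#' @param seed_channel seed label (e.g. "Fz").
#' @param freqs,step,cycles_map decomposition settings as in [tfPower()].
#' @return list with \code{csd} (complex array trials x channels x freqs x
#'   times), \code{power} (real array, auto-spectra), \code{seed},
#'   \code{freqs}, \code{times}, \code{channels}.
#' @export
crossSpectra <- function(epochs, seed_channel = "Fz",
                         freqs = seq(2, 10, 0.5), step = 0.05,
                         cycles_map = defaultCyclesMap) {
  sIdx <- matchChannels(epochs, seed_channel)
  se <- tfPower(epochs, freqs, step, cycles_map, keep_coef = TRUE)
  cf <- spectralCoef(se)
  seedCf <- cf[, sIdx, , , drop = FALSE]
  csd <- array(NA_complex_, dim(cf))
  for (ch in seq_len(dim(cf)[2L]))
    csd[, ch, , ] <- seedCf[, 1L, , ] * Conj(cf[, ch, , ])
  list(csd = csd, power = spectralPower(se), seed = seed_channel,
       seedIdx = sIdx, freqs = spectralFreqs(se), times = spectralTimes(se),
       channels = channelNames(se))
}

#' Magnitude-squared coherence map from cross-spectra
#'
#' coh(ch, f, t) = |mean_trials CSD|^2 / (mean_trials P_seed * mean_trials
#' P_ch), averaged over the window's time bins per frequency after the
#' trial averaging.
#'
#' @param cs output of [crossSpectra()].
#' @param band frequency band c(low, high) in Hz to keep.
#' @param window time window c(start, end) in seconds averaged over.
#' @param trials optional trial subset (indices).
#' @return a [CoherenceMap-class].
#' @export
coherenceMap <- function(cs, band = c(4, 8), window = NULL, trials = NULL) {
  nTr <- dim(cs$csd)[1L]
  if (!is.null(trials)) nTr <- length(trials) else trials <- seq_len(nTr)
  if (nTr < 2L) stop("coherence needs at least 2 trials")
  fSel <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  tSel <- if (is.null(window)) seq_along(cs$times)
          else which(cs$times >= window[1] & cs$times <= window[2])
  if (!length(tSel)) stop("window contains no time bins")
  csd <- cs$csd[trials, , fSel, tSel, drop = FALSE]
  pow <- cs$power[trials, , fSel, tSel, drop = FALSE]
  pSeed <- cs$power[trials, cs$seedIdx, fSel, tSel, drop = FALSE]
  mC <- apply(csd, c(2L, 3L, 4L), mean)       # channels x freqs x times
  mP <- apply(pow, c(2L, 3L, 4L), mean)
  mS <- apply(pSeed, c(2L, 3L, 4L), mean)[1L, , ]
  coh <- Mod(mC)^2 / sweep(mP, c(2L, 3L), mS, `*`)
  cohFT <- apply(coh, c(1L, 2L), mean, na.rm = TRUE)  # average over time
  new("CoherenceMap", seed = cs$seed, coherence = pmin(cohFT, 1),
      channels = cs$channels, freqs = cs$freqs[fSel], nTrials = nTr,
      nSubsamples = 1, band = band,
      window = if (is.null(window))
        range(cs$times[tSel]) else as.numeric(window))
}

#' Trial-count-matched subsampled coherence
#'
#' Draws \code{k} random without-replacement subsets of
#' \code{target_n_trials} trials, computes a coherence map per draw, and
#' returns the arithmetic mean map. Used to compare a high-trial-count
#' condition against a lower one without a trial-count bias.
#'
#' @param cs output of [crossSpectra()] for the larger condition.
#' @param target_n_trials trials per draw (<= available).
#' @param k number of draws (default 10).
#' @param band,window as in [coherenceMap()].
#' @param seed integer seed.
#' @return a [CoherenceMap-class] (nSubsamples = k).
#' @export
subsampleCoherence <- function(cs, target_n_trials, k = 10L, band = c(4, 8),
                               window = NULL, seed = 1L) {
  nAvail <- dim(cs$csd)[1L]
  if (target_n_trials > nAvail)
    stop("target_n_trials exceeds the available trials")
  draws <- withSeed(seed, lapply(seq_len(k), function(i)
    sample.int(nAvail, target_n_trials)))
  maps <- lapply(draws, function(tr) coherenceMap(cs, band, window, tr))
  mean_ <- Reduce(`+`, lapply(maps, function(m) m@coherence)) / k
  out <- maps[[1L]]
  out@coherence <- mean_
  out@nSubsamples <- k
  out@nTrials <- target_n_trials
  out
}

#' Cluster contrast of per-participant coherence maps
#'
#' Paired cluster-based permutation contrast of condition A vs condition B
#' coherence over channels x frequencies (delegating to
#' [clusterPermutationTest()]), plus the overlap of the significant channel
#' set with a supplied searchlight-significant channel set.
#'
#' @param mapsA,mapsB lists of [CoherenceMap-class], one per participant,
#'   same channel/frequency axes.
#' @param adjacency channel adjacency matrix.
#' @param n_perm,alpha,seed as in [clusterPermutationTest()].
#' @param searchlight_channels optional character vector of channels found
#'   informative by searchlight decoding.
#' @return list(result = [ClusterTestResult-class], channels = significant
#'   channel labels, overlap = intersection with
#'   \code{searchlight_channels}, overlap_fraction).
#' @export
coherenceContrast <- function(mapsA, mapsB, adjacency, n_perm = 500L,
                              alpha = 0.05, seed = 1L,
                              searchlight_channels = NULL) {
  if (length(mapsA) != length(mapsB))
    stop("need one map per participant in both conditions")
  stack <- function(maps) {
    arr <- array(0, c(length(maps), dim(maps[[1L]]@coherence)))
    for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]@coherence
    arr
  }
  A <- stack(mapsA)
  B <- stack(mapsB)
  res <- clusterPermutationTest(A, B, adjacency, n_perm = n_perm,
                                alpha = alpha, seed = seed)
  sigCh <- significantChannels(res)
  overlap <- if (is.null(searchlight_channels)) character(0)
             else intersect(sigCh, searchlight_channels)
  list(result = res, channels = sigCh, overlap = overlap,
       overlap_fraction = if (length(searchlight_channels))
         length(overlap) / length(searchlight_channels) else NA_real_)
}

#' Write a coherence map as TSV
#' @param map a [CoherenceMap-class].
#' @param path file path.
#' @export
writeCoherenceMap <- function(map, path) {
  df <- expand.grid(channel = map@channels, freq = map@freqs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$coherence <- as.vector(map@coherence)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
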