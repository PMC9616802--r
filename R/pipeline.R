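#' Analysis configuration
#'
#' Aggregates the pipeline's stated parameters: 2-10 Hz (0.5 Hz) variable-
#' cycle decomposition at 50 ms steps, theta band 4-8 Hz, peak grid 4-8 Hz
#' at 0.2 Hz, 5-fold x 5-repeat decoding, 500-permutation cluster tests with
#' alpha 0.05 and a 3-channel minimum extent, an Fz coherence seed with 10
#' subsample draws, and IRASA factors 1.1-1.9. Every stochastic stage
#' receives a seed derived from \code{master_seed}.
#'
#' @param ... overrides for any listed field.
#' @return list of class "AnalysisConfig".
#' @export
analysisConfig <- function(...) {
  cfg <- list(tf_freqs = seq(2, 10, 0.5), tf_step = 0.05,
              theta_band = c(4, 8), peak_band = c(4, 8),
              peak_grid_step = 0.2, pad_to = 5,
              folds = 5L, repeats = 5L,
              n_perm = 500L, alpha = 0.05, min_channel_extent = 3L,
              coherence_seed = "Fz", subsample_k = 10L,
              irasa_factors = seq(1.1, 1.9, by = 0.05),
              neighbour_target_degree = 5.7,
              decode_rate = 200, smooth_ms = 100,
              baseline_window = c(-0.2, 0),
              master_seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "AnalysisConfig"
  cfg
}

# per-participant delay-averaged channels x freqs power
delayPowerMap <- function(epochs, cfg) {
  se <- tfPower(epochs, cfg$tf_freqs, cfg$tf_step)
  pow <- spectralPower(se)
  t <- spectralTimes(se)
  sel <- t >= 0
  apply(pow[, , , sel, drop = FALSE], c(2L, 3L), mean, na.rm = TRUE)
}

#' Spectral power contrast between two conditions
#'
#' Per participant, delay-averaged channel x frequency power maps from the
#' variable-cycle decomposition are contrasted with the cluster-based
#' permutation test; the significant channel set, the theta-band summed
#' topography of the difference, and the paired effect size over the
#' significant channels are reported.
#'
#' @param config an [analysisConfig()].
#' @param epochsA,epochsB lists of delay [EpochSet-class], one per
#'   participant (condition A minus B is tested).
#' @param adjacency channel adjacency matrix.
#' @return list(result, channels, theta_topography, effect).
#' @export
runPowerContrast <- function(config, epochsA, epochsB, adjacency) {
  if (length(epochsA) != length(epochsB))
    stop("both conditions must be present for every participant")
  mapsA <- lapply(epochsA, delayPowerMap, cfg = config)
  mapsB <- lapply(epochsB, delayPowerMap, cfg = config)
  n <- length(mapsA)
  dims <- dim(mapsA[[1L]])
  A <- array(unlist(mapsA), c(dims, n))
  A <- aperm(A, c(3L, 1L, 2L))
  B <- aperm(array(unlist(mapsB), c(dims, n)), c(3L, 1L, 2L))
  res <- clusterPermutationTest(A, B, adjacency, n_perm = config$n_perm,
                                alpha = config$alpha,
                                min_channel_extent =
                                  config$min_channel_extent,
                                seed = deriveSeed(config$master_seed, 101))
  sigCh <- significantChannels(res, "pos")
  fSel <- config$tf_freqs >= config$theta_band[1] &
    config$tf_freqs <= config$theta_band[2]
  topo <- apply(A[, , fSel, drop = FALSE] - B[, , fSel, drop = FALSE],
                2L, mean)
  names(topo) <- rownames(adjacency)
  effect <- if (length(sigCh)) {
    chIdx <- match(sigCh, rownames(adjacency))
    pairedT(apply(A[, chIdx, fSel, drop = FALSE], 1L, mean),
            apply(B[, chIdx, fSel, drop = FALSE], 1L, mean))
  } else NULL
  list(result = res, channels = sigCh, theta_topography = topo,
       effect = effect)
}

#' Category decoding: timecourse, significant window, searchlight
#'
#' Runs the full decoding chain per participant on delay epochs, tests the
#' group timecourse against chance with the temporal cluster test, and runs
#' the channel searchlight inside the significant window (fallback: the
#' whole delay). Optionally adds the stimulus-to-delay generalization
#' timecourse when stimulus epochs are supplied.
#'
#' @param config an [analysisConfig()].
#' @param epochs_delay list of delay [EpochSet-class] per participant.
#' @param adjacency channel adjacency matrix.
#' @param epochs_stimulus optional list of stimulus epochs per participant
#'   (enables generalization).
#' @return list(timecourse matrix, times, significance, window, searchlight
#'   matrix, generalization).
#' @export
runDecoding <- function(config, epochs_delay, adjacency,
                        epochs_stimulus = NULL) {
  n <- length(epochs_delay)
  ms <- config$master_seed
  accs <- NULL
  times <- NULL
  processed <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- decodingChain(epochs_delay[[i]], config$decode_rate,
                        config$smooth_ms, config$baseline_window,
                        seed = deriveSeed(ms, 201, i))
    processed[[i]] <- ch$epochs
    dr <- crossvalDecode(ch$epochs, folds = config$folds,
                         repeats = config$repeats,
                         seed = deriveSeed(ms, 202, i))
    if (is.null(accs)) {
      times <- dr@times
      sel <- times >= 0
      times <- times[sel]
      accs <- matrix(NA_real_, n, sum(sel))
    }
    accs[i, ] <- dr@accuracy[sel]
  }
  sig <- decodeSignificance(accs, times, n_perm = config$n_perm,
                            alpha = config$alpha,
                            seed = deriveSeed(ms, 203))
  window <- if (nrow(sig$windows)) {
    best <- which.max(sig$windows$end - sig$windows$start)
    as.numeric(sig$windows[best, ])
  } else c(0, max(times))
  sl <- matrix(NA_real_, n, nrow(adjacency))
  for (i in seq_len(n)) {
    res <- searchlightDecode(processed[[i]], adjacency, window,
                             folds = config$folds,
                             repeats = config$repeats,
                             seed = deriveSeed(ms, 204, i))
    sl[i, ] <- res@accuracy
  }
  colnames(sl) <- rownames(adjacency)
  gen <- NULL
  if (!is.null(epochs_stimulus)) {
    gen <- vector("list", n)
    for (i in seq_len(n)) {
      both <- decodingChain(epochs_stimulus[[i]], config$decode_rate,
                            config$smooth_ms, config$baseline_window,
                            seed = deriveSeed(ms, 205, i))
      gen[[i]] <- both
    }
  }
  list(timecourse = accs, times = times, significance = sig,
       window = window, searchlight = sl, generalization = gen)
}

#' Seed-based coherence contrast with searchlight overlap
#'
#' Per participant: theta-band Fz-seeded coherence in the analysis window
#' for condition A, and subsampled (trial-count-matched) coherence for
#' condition B; the maps are contrasted with the cluster machinery and the
#' significant channels are intersected with the searchlight-informative
#' set. Decoding restricted to the coherence-cluster channels is re-run on
#' the supplied processed epochs when given.
#'
#' @param config an [analysisConfig()].
#' @param epochsA,epochsB lists of delay [EpochSet-class] per participant
#'   (B is the higher-trial-count condition that gets subsampled to A's
#'   count).
#' @param adjacency channel adjacency matrix.
#' @param window analysis window (s) within the delay.
#' @param searchlight_channels channels informative in searchlight decoding.
#' @param decode_epochs optional list of processed epochs for the
#'   decode-on-coherent-channels follow-up.
#' @return list(contrast, maps, decode_on_cluster).
#' @export
runCoherence <- function(config, epochsA, epochsB, adjacency, window,
                         searchlight_channels = NULL,
                         decode_epochs = NULL) {
  n <- length(epochsA)
  ms <- config$master_seed
  mapsA <- vector("list", n)
  mapsB <- vector("list", n)
  for (i in seq_len(n)) {
    csA <- crossSpectra(epochsA[[i]], config$coherence_seed,
                        config$tf_freqs, config$tf_step)
    mapsA[[i]] <- coherenceMap(csA, config$theta_band, window)
    csB <- crossSpectra(epochsB[[i]], config$coherence_seed,
                        config$tf_freqs, config$tf_step)
    mapsB[[i]] <- subsampleCoherence(csB, dim(csA$csd)[1L],
                                     config$subsample_k, config$theta_band,
                                     window,
                                     seed = deriveSeed(ms, 301, i))
  }
  contrast <- coherenceContrast(mapsA, mapsB, adjacency,
                                n_perm = config$n_perm,
                                alpha = config$alpha,
                                seed = deriveSeed(ms, 302),
                                searchlight_channels =
                                  searchlight_channels)
  dec <- NULL
  if (!is.null(decode_epochs) && length(contrast$channels)) {
    acc <- vapply(seq_along(decode_epochs), function(i) {
      ep <- subsetEpochs(decode_epochs[[i]],
                         channels = contrast$channels)
      t <- epochTimes(ep)
      sel <- t[t >= window[1] & t <= window[2]]
      mean(crossvalDecode(ep, folds = config$folds,
                          repeats = config$repeats,
                          seed = deriveSeed(ms, 303, i),
                          times = sel)@accuracy)
    }, numeric(1))
    dec <- list(accuracy = acc, mean = mean(acc))
  }
  list(contrast = contrast, mapsA = mapsA, mapsB = mapsB,
       decode_on_cluster = dec)
}

# per-participant condition peak means for a list of epochs and a variant
peakMeansOf <- function(epochsList, frontal, cfg, variant = "raw",
                        smooth_elements = NULL) {
  vapply(seq_along(epochsList), function(i) {
    ep <- subsetEpochs(epochsList[[i]], channels = frontal)
    spectra <- switch(variant,
      raw = channelMeanSpectra(
        epochSpectrum(ep, cfg$peak_band, cfg$peak_grid_step, cfg$pad_to)),
      irasa = {
        ir <- irasa(ep, cfg$irasa_factors, cfg$peak_band,
                    cfg$peak_grid_step, cfg$pad_to)
        apply(ir$oscillatory, c(1L, 3L), mean)
      })
    if (!is.null(smooth_elements))
      spectra <- smoothSpectrum(spectra, smooth_elements)
    freqs <- seq(cfg$peak_band[1], cfg$peak_band[2],
                 by = cfg$peak_grid_step)
    pk <- peakTable(spectra, freqs)
    mean(pk$peak_hz[!pk$discarded])
  }, numeric(1))
}

#' Theta peak-frequency slowing analysis
#'
#' For each participant and load condition: whole-epoch spectra over the
#' frontal channel set (channel-mean first), per-trial most-prominent-peak
#' detection on the 4-8 Hz / 0.2 Hz grid, condition means, and the paired
#' slowing test. Robustness variants repeat the test on IRASA oscillatory
#' residuals and on spectra smoothed with 2-5 grid elements. Follow-ups:
#' per-frequency (0.5 Hz grid) paired t with Holm correction, and the
#' load x frequency repeated-measures ANOVA on delay-averaged power.
#'
#' @param config an [analysisConfig()].
#' @param epochs1,epochs2 lists of delay [EpochSet-class] per participant
#'   (load 1, load 2).
#' @param frontal_channels frontal cluster channel set (e.g. from
#'   [runPowerContrast()]; a configured fallback list otherwise).
#' @param run_irasa,run_smoothing include the robustness variants.
#' @return list(peak_means data.frame, slowing test, robustness, per_freq,
#'   anova).
#' @export
runSlowing <- function(config, epochs1, epochs2, frontal_channels,
                       run_irasa = TRUE, run_smoothing = TRUE) {
  n <- length(epochs1)
  m1 <- peakMeansOf(epochs1, frontal_channels, config)
  m2 <- peakMeansOf(epochs2, frontal_channels, config)
  slowing <- pairedT(m1, m2)
  robustness <- list()
  if (run_irasa) {
    i1 <- peakMeansOf(epochs1, frontal_channels, config, "irasa")
    i2 <- peakMeansOf(epochs2, frontal_channels, config, "irasa")
    robustness$irasa <- c(list(mean1 = mean(i1), mean2 = mean(i2)),
                          pairedT(i1, i2))
  }
  if (run_smoothing) {
    for (w in 2:5) {
      s1 <- peakMeansOf(epochs1, frontal_channels, config,
                        smooth_elements = w)
      s2 <- peakMeansOf(epochs2, frontal_channels, config,
                        smooth_elements = w)
      robustness[[paste0("smooth", w)]] <- pairedT(s1, s2)
    }
  }
  # delay-averaged power at 0.5 Hz steps over the frontal set
  freqs05 <- seq(config$theta_band[1], config$theta_band[2], 0.5)
  powArr <- array(NA_real_, c(n, 2L, length(freqs05)))
  for (i in seq_len(n)) {
    for (ci in 1:2) {
      ep <- subsetEpochs(if (ci == 1L) epochs1[[i]] else epochs2[[i]],
                         channels = frontal_channels)
      se <- tfPower(ep, freqs05, config$tf_step)
      powArr[i, ci, ] <- apply(spectralPower(se), 3L, mean, na.rm = TRUE)
    }
  }
  perFreq <- do.call(rbind, lapply(seq_along(freqs05), function(k) {
    tt <- pairedT(powArr[, 2L, k], powArr[, 1L, k])
    data.frame(freq = freqs05[k], t = tt$t, p = tt$p, d = tt$d)
  }))
  perFreq$p_holm <- holm(perFreq$p)
  anova <- rmAnova2(powArr)
  list(peak_means = data.frame(participant = seq_len(n), load1 = m1,
                               load2 = m2),
       slowing = slowing, robustness = robustness, per_freq = perFreq,
       anova = anova)
}
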