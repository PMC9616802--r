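#' Default cycles-per-frequency map of the time-resolved decomposition
#'
#' Window length at frequency f is cycles(f)/f seconds: 2 cycles for
#' 2-3.5 Hz, 3 for 4-4.5 Hz, 4 for 5-5.5 Hz, 5 for 6-10 Hz.
#'
#' @param f frequencies in Hz.
#' @return integer cycle counts.
#' @export
defaultCyclesMap <- function(f) {
  ifelse(f < 4, 2L, ifelse(f < 5, 3L, ifelse(f < 6, 4L, 5L)))
}

hanningTaper <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Time-resolved spectral power (sliding Hanning windows, variable cycles)
#'
#' Sliding-window Fourier decomposition: at each frequency the signal is
#' convolved with a Hanning-tapered complex exponential whose length is
#' cycles(f)/f seconds, evaluated at window centres spaced \code{step}
#' seconds apart. Coefficients are scaled by 2/sum(taper) so that a unit
#' sinusoid yields power approximately 1 at its own frequency. Window centres
#' where the window would extend beyond the stored epoch are returned as NA.
#'
#' @param epochs an [EpochSet-class].
#' @param freqs analysis frequencies (Hz); default 2-10 Hz in 0.5 Hz steps.
#' @param step window-centre spacing in seconds (default 0.05).
#' @param cycles_map function mapping frequency to cycle count.
#' @param keep_coef retain complex coefficients (needed for cross-spectra).
#' @return a [SpectralEstimate-class] with 4-D power
#'   (trials x channels x freqs x times).
#' @export
tfPower <- function(epochs, freqs = seq(2, 10, 0.5), step = 0.05,
                    cycles_map = defaultCyclesMap, keep_coef = FALSE) {
  rate <- samplingRate(epochs)
  t <- epochTimes(epochs)
  ns <- length(t)
  cyc <- cycles_map(freqs)
  winLen <- round(cyc / freqs * rate)
  if (any(winLen > ns))
    stop(sprintf("epoch too short for the %g Hz window (%d cycles = %.2f s)",
                 freqs[which.max(winLen)][1], cyc[which.max(winLen)][1],
                 max(winLen) / rate))
  outTimes <- seq(t[1L], t[ns], by = step)
  dat <- flattenTC(epochs@data)
  d <- dim(epochs@data)
  nf <- length(freqs)
  nt <- length(outTimes)
  pow <- array(NA_real_, c(d[1L], d[2L], nf, nt))
  cf <- if (keep_coef) array(NA_complex_, c(d[1L], d[2L], nf, nt)) else NULL
  for (k in seq_len(nf)) {
    L <- winLen[k]
    hw <- hanningTaper(L)
    tau <- (seq_len(L) - (L + 1) / 2) / rate
    kern <- hw * exp(-2i * pi * freqs[k] * tau) * (2 / sum(hw))
    centreIdx <- round((outTimes - t[1L]) * rate) + 1L
    lo <- centreIdx - floor((L - 1) / 2)
    hi <- lo + L - 1L
    valid <- which(lo >= 1L & hi <= ns)
    if (!length(valid)) next
    W <- matrix(0 + 0i, ns, length(valid))
    for (j in seq_along(valid))
      W[lo[valid[j]]:hi[valid[j]], j] <- kern
    co <- dat %*% W
    p <- Mod(co)^2
    pow[, , k, valid] <- array(p, c(d[1L], d[2L], length(valid)))
    if (keep_coef) cf[, , k, valid] <- array(co, c(d[1L], d[2L],
                                                   length(valid)))
  }
  new("SpectralEstimate", power = pow,
      coef = if (keep_coef) cf else array(complex(0), c(0, 0, 0)),
      freqs = freqs, times = outTimes, channels = epochs@channels,
      method = list(taper = "hanning", cycles = cyc, step = step,
                    window_len_s = winLen / rate))
}

#' Whole-epoch spectrum on a fine frequency grid
#'
#' Single Hanning-tapered Fourier estimate over the analysis window
#' (default: the whole epoch from onset), evaluated on a frequency grid finer
#' than the native resolution by zero-padding to \code{pad_to} seconds
#' (implemented as direct DTFT evaluation at the padded-grid frequencies,
#' which is numerically identical to zero-padded FFT bins). Coefficients are
#' scaled by 2/sum(taper).
#'
#' @param epochs an [EpochSet-class].
#' @param band c(low, high) in Hz.
#' @param grid_step frequency grid step (Hz); must not be finer than
#'   1/pad_to.
#' @param pad_to equivalent zero-padded length in seconds (default 5, i.e. a
#'   0.2 Hz grid).
#' @param window analysis window [start, end) in seconds; default from onset
#'   to the end of the epoch.
#' @param demean remove the window mean before tapering.
#' @return a [SpectralEstimate-class] with 3-D power
#'   (trials x channels x freqs) and \code{times} empty.
#' @export
epochSpectrum <- function(epochs, band = c(4, 8), grid_step = 0.2,
                          pad_to = 5, window = c(0, Inf), demean = TRUE) {
  if (grid_step < 1 / pad_to - 1e-12)
    stop("grid_step finer than the padded resolution 1/pad_to")
  ep <- cropEpochs(epochs, window)
  t <- epochTimes(ep)
  if (t[length(t)] - t[1L] < 1 - 1e-9)
    stop("epoch must be at least 1 s long")
  freqs <- seq(band[1], band[2], by = grid_step)
  dat <- flattenTC(ep@data)
  if (demean) dat <- dat - rowMeans(dat)
  hw <- hanningTaper(ncol(dat))
  E <- exp(-2i * pi * outer(t - t[1L], freqs)) * hw * (2 / sum(hw))
  co <- dat %*% E
  d <- dim(ep@data)
  pow <- array(Mod(co)^2, c(d[1L], d[2L], length(freqs)))
  new("SpectralEstimate", power = pow, coef = array(complex(0), c(0, 0, 0)),
      freqs = freqs, times = numeric(0), channels = ep@channels,
      method = list(taper = "hanning", pad_to = pad_to,
                    grid_step = grid_step, window = window,
                    demean = demean))
}

#' Channel-mean spectra
#'
#' Averages a whole-epoch [SpectralEstimate-class] across (a subset of)
#' channels, yielding one spectrum per trial.
#'
#' @param spectrum a 3-D [SpectralEstimate-class].
#' @param channels labels to average over (default: all).
#' @return numeric matrix trials x freqs.
#' @export
channelMeanSpectra <- function(spectrum, channels = NULL) {
  pow <- spectrum@power
  idx <- if (is.null(channels)) seq_along(spectrum@channels)
         else {
           i <- match(channels, spectrum@channels)
           if (anyNA(i)) stop("unknown channel label(s)")
           i
         }
  out <- apply(pow[, idx, , drop = FALSE], c(1L, 3L), mean)
  colnames(out) <- spectrum@freqs
  out
}

#' IRASA separation of fractal and oscillatory spectral components
#'
#' Irregular-resampling auto-spectral analysis: for each resampling factor h
#' the signal is resampled up by h and down by h (cubic-free linear
#' interpolation on the stretched/compressed time grids), the Hanning
#' spectrum of each is taken on the analysis grid at the nominal rate, and
#' the geometric mean of the h-up/h-down pair is formed. A narrowband
#' oscillation lands at different frequencies in the two members and is
#' annihilated by the geometric mean, while a self-similar 1/f^chi component
#' survives it unchanged. The fractal spectrum is the median of the pair
#' spectra across factors; the oscillatory residual is the original spectrum
#' minus the fractal component (and may be negative off-peak).
#'
#' The raw single-taper spectra entering the geometric mean are chi-squared
#' distributed with two degrees of freedom, and the square root of their
#' product is therefore biased low (Jensen's inequality); the resampled
#' auxiliary spectra are smoothed along frequency (\code{smooth_bins} grid
#' points) before the geometric mean, which removes this small-sample bias
#' while leaving the (by definition smooth) fractal component intact. The
#' original spectrum is never smoothed.
#'
#' @param epochs an [EpochSet-class].
#' @param factors resampling factors h > 1; each is paired with 1/h.
#'   Default 1.1 to 1.9 in steps of 0.05.
#' @param band,grid_step,pad_to,window as in [epochSpectrum()].
#' @param smooth_bins frequency-smoothing window (grid points) applied to
#'   the auxiliary up/down spectra before the geometric mean.
#' @return list with \code{fractal} (a [SpectralEstimate-class]),
#'   \code{oscillatory} (array trials x channels x freqs; signed),
#'   \code{original} (a [SpectralEstimate-class]) and \code{freqs}.
#' @export
irasa <- function(epochs, factors = seq(1.1, 1.9, by = 0.05), band = c(4, 8),
                  grid_step = 0.2, pad_to = 5, window = c(0, Inf),
                  smooth_bins = 13L) {
  if (!length(factors)) stop("factor set must not be empty")
  if (any(factors <= 1)) stop("all factors must exceed 1")
  orig <- epochSpectrum(epochs, band, grid_step, pad_to, window)
  ep <- cropEpochs(epochs, window)
  t <- epochTimes(ep)
  ns <- length(t)
  rate <- samplingRate(ep)
  dat <- flattenTC(ep@data)
  dat <- dat - rowMeans(dat)
  freqs <- orig@freqs
  # auxiliary spectra are computed on a grid extended by the smoothing
  # half-width so that edge bins are smoothed over full windows
  hwBins <- (as.integer(smooth_bins) - 1L) %/% 2L
  padLow <- min(hwBins, floor((band[1] - grid_step) / grid_step))
  freqsExt <- seq(band[1] - padLow * grid_step,
                  band[2] + hwBins * grid_step, by = grid_step)
  cropIdx <- match(round(freqs / grid_step), round(freqsExt / grid_step))
  spectrumOf <- function(m) {
    hw <- hanningTaper(ncol(m))
    tt <- (seq_len(ncol(m)) - 1L) / rate
    E <- exp(-2i * pi * outer(tt, freqsExt)) * hw * (2 / sum(hw))
    Mod(m %*% E)^2
  }
  resampleAt <- function(pos) {              # linear interp, vectorised rows
    lo <- pmin(floor(pos) + 1L, ns)
    hi <- pmin(lo + 1L, ns)
    w <- pos - (lo - 1L)
    dat[, lo, drop = FALSE] * (1 - w)[col(dat[, lo, drop = FALSE])] +
      dat[, hi, drop = FALSE] * rep(w, each = nrow(dat))
  }
  pairSpectra <- vector("list", length(factors))
  for (k in seq_along(factors)) {
    h <- factors[k]
    posUp <- seq(0, ns - 1, by = 1 / h)      # x(j/(h fs)): freq scaled f -> f/h
    posDn <- seq(0, ns - 1, by = h)          # x(j h/fs): freq scaled f -> f h
    pUp <- smoothSpectrum(spectrumOf(resampleAt(posUp)), smooth_bins)
    pDn <- smoothSpectrum(spectrumOf(resampleAt(posDn)), smooth_bins)
    pairSpectra[[k]] <- sqrt(pUp * pDn)[, cropIdx, drop = FALSE]
  }
  flat <- array(unlist(pairSpectra),
                c(nrow(dat), length(freqs), length(factors)))
  fracFlat <- apply(flat, c(1L, 2L), stats::median)
  d <- dim(ep@data)
  frac <- array(fracFlat, c(d[1L], d[2L], length(freqs)))
  fractal <- new("SpectralEstimate", power = frac,
                 coef = array(complex(0), c(0, 0, 0)), freqs = freqs,
                 times = numeric(0), channels = ep@channels,
                 method = list(method = "irasa", factors = factors,
                               taper = "hanning", pad_to = pad_to))
  list(fractal = fractal, oscillatory = orig@power - frac, original = orig,
       freqs = freqs)
}

#' Sliding-mean smoothing along the frequency axis
#'
#' Running mean over \code{window_elements} grid points (2-5 elements is
#' roughly a 0.2-1.0 Hz window on a 0.2 Hz grid), truncated at the band
#' edges; shape preserved.
#'
#' @param spectrum a [SpectralEstimate-class], or a trials x freqs matrix, or
#'   a single spectrum vector.
#' @param window_elements window length in grid points (>= 2).
#' @return object of the same kind as the input.
#' @export
smoothSpectrum <- function(spectrum, window_elements) {
  w <- as.integer(window_elements)
  sm <- function(m) {
    ns <- ncol(m)
    if (w > ns) stop("window exceeds the number of grid points")
    hl <- floor((w - 1L) / 2L)
    as.matrix(m %*% slidingMeanMatrix(ns, hl, w - 1L - hl))
  }
  if (is(spectrum, "SpectralEstimate")) {
    d <- dim(spectrum@power)
    if (length(d) != 3L) stop("smoothing expects whole-epoch spectra")
    m <- matrix(aperm(spectrum@power, c(3L, 1L, 2L)), nrow = d[3L])
    out <- t(sm(t(m)))
    spectrum@power <- aperm(array(out, c(d[3L], d[1L], d[2L])),
                            c(2L, 3L, 1L))
    spectrum
  } else if (is.matrix(spectrum)) {
    sm(spectrum)
  } else {
    drop(sm(matrix(spectrum, nrow = 1L)))
  }
}

#' Most-prominent-peak detection in a spectrum
#'
#' Local maxima are strict interior maxima (both neighbours lower). The
#' prominence of a peak is its height above the higher of its two bases,
#' where each base is the minimum of the spectrum between the peak and the
#' nearest higher point (or the band edge) on that side. The frequency of
#' the maximum-prominence peak is returned; ties go to the lower frequency.
#' A spectrum with no interior local maximum (e.g. a monotone 1/f shape) is
#' flagged as discarded rather than raising an error.
#'
#' @param spectrum numeric vector on the band grid.
#' @param freqs grid frequencies (Hz).
#' @return list(peak_hz, prominence, discarded).
#' @export
detectPeak <- function(spectrum, freqs) {
  n <- length(spectrum)
  stopifnot(length(freqs) == n)
  if (n < 3L) return(list(peak_hz = NA_real_, prominence = NA_real_,
                          discarded = TRUE))
  i <- 2:(n - 1L)
  isPeak <- spectrum[i] > spectrum[i - 1L] & spectrum[i] > spectrum[i + 1L]
  peaks <- i[isPeak]
  if (!length(peaks)) return(list(peak_hz = NA_real_,
                                  prominence = NA_real_, discarded = TRUE))
  prom <- vapply(peaks, function(p) {
    h <- spectrum[p]
    left <- spectrum[seq_len(p - 1L)]
    higher <- which(left > h)
    lbase <- min(left[seq(if (length(higher)) max(higher) + 1L else 1L,
                          p - 1L)])
    right <- spectrum[(p + 1L):n]
    higher <- which(right > h)
    rbase <- min(right[seq_len(if (length(higher)) min(higher) - 1L
                               else length(right))])
    h - max(lbase, rbase)
  }, numeric(1))
  best <- peaks[which.max(prom)]              # first max: lower freq on ties
  list(peak_hz = freqs[best], prominence = max(prom), discarded = FALSE)
}

#' Per-trial peak table from channel-mean spectra
#'
#' Applies [detectPeak()] to every row of a trials x freqs spectrum matrix.
#'
#' @param spectra numeric matrix trials x freqs (channel-mean power), or a
#'   signed oscillatory-residual matrix from [irasa()].
#' @param freqs grid frequencies.
#' @param info optional per-trial metadata bound to the result.
#' @return data.frame with columns trial, peak_hz, prominence, discarded
#'   (plus the info columns).
#' @export
peakTable <- function(spectra, freqs, info = NULL) {
  rows <- lapply(seq_len(nrow(spectra)), function(i)
    detectPeak(spectra[i, ], freqs))
  out <- data.frame(trial = seq_len(nrow(spectra)),
                    peak_hz = vapply(rows, `[[`, numeric(1), "peak_hz"),
                    prominence = vapply(rows, `[[`, numeric(1),
                                        "prominence"),
                    discarded = vapply(rows, `[[`, logical(1), "discarded"))
  if (!is.null(info)) out <- cbind(out, info)
  out
}

#' Condition means of the per-trial peak statistic
#'
#' Averages non-discarded peak frequencies within participant x condition
#' cells and reports the discarded fraction. A cell whose trials were all
#' discarded yields NA with a warning.
#'
#' @param peaks a data.frame from [peakTable()] with \code{participant} and
#'   \code{condition} columns (pass them via \code{info}).
#' @return data.frame: participant, condition, mean_peak_hz, n_trials,
#'   n_discarded, discarded_fraction.
#' @export
conditionPeakMeans <- function(peaks) {
  stopifnot(all(c("participant", "condition") %in% names(peaks)))
  cells <- split(peaks, list(peaks$participant, peaks$condition),
                 drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(df) {
    ok <- !df$discarded
    if (!any(ok))
      warning("all trials discarded for participant ", df$participant[1L],
              ", condition ", df$condition[1L])
    data.frame(participant = df$participant[1L],
               condition = df$condition[1L],
               mean_peak_hz = if (any(ok)) mean(df$peak_hz[ok]) else
                 NA_real_,
               n_trials = nrow(df), n_discarded = sum(!ok),
               discarded_fraction = mean(!ok))
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$participant), ]
}

#' Write a peak table as TSV
#' @param peaks data.frame from [peakTable()].
#' @param path file path.
#' @export
writePeakTable <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
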