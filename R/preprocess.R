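## Deterministic signal conditioning applied before the analysis stages.
## All operations preserve trial count, channel set and metadata; only the
## voltages (and, for resampling, the time axis) change.

# trials x channels x samples <-> (trials*channels) x samples
flattenTC <- function(dat) {
  d <- dim(dat)
  dim(dat) <- c(d[1L] * d[2L], d[3L])
  dat
}
unflattenTC <- function(mat, d1, d2) {
  dim(mat) <- c(d1, d2, ncol(mat))
  mat
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts, at every sample of every trial, the mean of the listed
#' reference channels from every channel (e.g. the average of two mastoid
#' channels).
#'
#' @param epochs an [EpochSet-class].
#' @param reference_channels labels of the reference channels.
#' @return the re-referenced [EpochSet-class].
#' @export
rereference <- function(epochs, reference_channels) {
  idx <- matchChannels(epochs, reference_channels)
  dat <- epochs@data
  ref <- if (length(idx) == 1L) dat[, idx, , drop = TRUE]
         else apply(dat[, idx, , drop = FALSE], c(1L, 3L), mean)
  if (is.null(dim(ref))) ref <- matrix(ref, dim(dat)[1L])
  for (ci in seq_len(dim(dat)[2L])) dat[, ci, ] <- dat[, ci, ] - ref
  epochs@data <- dat
  epochs
}

#' Zero-phase high-pass filter
#'
#' Forward-backward (zero-phase) Butterworth high-pass applied per trial and
#' channel. The default order-2 section, applied twice by filtfilt, gives an
#' effective 4th-order response; at typical EEG cutoffs (0.3 Hz) this
#' attenuates DC by far more than 20 dB while leaving frequencies at twice
#' the cutoff and above within a few percent of unity gain.
#'
#' @param epochs an [EpochSet-class].
#' @param cutoff -3 dB cutoff in Hz; must lie in (0, rate/2).
#' @param order Butterworth section order (the zero-phase application doubles
#'   the effective order).
#' @return the filtered [EpochSet-class].
#' @export
highpass <- function(epochs, cutoff, order = 2L) {
  rate <- samplingRate(epochs)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "high")
  dat <- epochs@data
  d <- dim(dat)
  ns <- d[3L]
  # odd-reflection padding suppresses the forward-backward edge transient,
  # which is substantial at cutoffs far below the sampling rate
  pad <- min(ns - 1L, ceiling(rate / cutoff))
  m <- flattenTC(dat)
  for (r in seq_len(nrow(m))) {
    x <- m[r, ] - mean(m[r, ])               # DC removed exactly
    ext <- c(2 * x[1L] - x[(pad + 1L):2L], x,
             2 * x[ns] - x[(ns - 1L):(ns - pad)])
    y <- signal::filtfilt(bf, ext)
    m[r, ] <- y[(pad + 1L):(pad + ns)]
  }
  epochs@data <- unflattenTC(m, d[1L], d[2L])
  epochs
}

#' Resample epochs to a lower rate
#'
#' Fourier-domain resampling: the spectrum of each trial/channel trace is
#' truncated at the new Nyquist frequency and inverted on the coarser grid,
#' which is simultaneously anti-aliasing and amplitude-preserving for
#' band-limited signals. Only downsampling is supported (the pipeline never
#' upsamples). The time axis is regenerated starting at the original first
#' sample.
#'
#' @param epochs an [EpochSet-class].
#' @param new_rate target rate in Hz, < current rate.
#' @return the resampled [EpochSet-class].
#' @export
resampleEpochs <- function(epochs, new_rate) {
  rate <- samplingRate(epochs)
  if (new_rate >= rate) stop("only downsampling is supported")
  dat <- epochs@data
  d <- dim(dat)
  ns <- d[3L]
  nNew <- floor(ns * new_rate / rate)
  m <- t(flattenTC(dat))                      # samples x (trials*channels)
  W <- stats::mvfft(m)
  keep <- floor(nNew / 2)
  Wnew <- matrix(0 + 0i, nNew, ncol(W))
  Wnew[seq_len(keep + 1L), ] <- W[seq_len(keep + 1L), ]
  if (keep >= 1)
    Wnew[nNew - seq_len(keep) + 1L, ] <- W[ns - seq_len(keep) + 1L, ]
  if (nNew %% 2L == 0L && keep >= 1)          # split the shared Nyquist bin
    Wnew[keep + 1L, ] <- Re(Wnew[keep + 1L, ])
  y <- Re(stats::mvfft(Wnew, inverse = TRUE)) / ns
  out <- unflattenTC(t(y), d[1L], d[2L])
  epochs@data <- out
  epochs@rate <- new_rate
  epochs@times <- epochs@times[1L] + (seq_len(nNew) - 1L) / new_rate
  epochs
}

#' Centered sliding-average smoothing
#'
#' Running mean over a centred window; at the edges the window is truncated
#' to the available samples, so output length equals input length.
#'
#' @param epochs an [EpochSet-class].
#' @param window window length in milliseconds (>= 2 samples, <= epoch).
#' @return the smoothed [EpochSet-class].
#' @export
slidingAverage <- function(epochs, window) {
  rate <- samplingRate(epochs)
  w <- round(window / 1000 * rate)
  ns <- dim(epochs@data)[3L]
  if (w < 2L) stop("window must span at least 2 samples")
  if (w > ns) stop("window longer than the epoch")
  hl <- floor((w - 1L) / 2L)
  hr <- w - 1L - hl
  dat <- epochs@data
  d <- dim(dat)
  m <- flattenTC(dat)
  sm <- slidingMeanMatrix(ns, hl, hr)
  epochs@data <- unflattenTC(as.matrix(m %*% sm), d[1L], d[2L])
  epochs
}

# column i averages samples [i-hl, i+hr] intersected with the valid range
slidingMeanMatrix <- function(ns, hl, hr) {
  i <- rep(seq_len(ns), each = hl + hr + 1L)
  j <- i + rep(seq(-hl, hr), ns)
  ok <- j >= 1L & j <= ns
  i <- i[ok]; j <- j[ok]
  cnt <- tabulate(i, ns)
  Matrix::sparseMatrix(i = j, j = i, x = 1 / cnt[i], dims = c(ns, ns))
}

#' Baseline correction
#'
#' Per trial and channel, subtracts the mean voltage over the half-open
#' baseline window [start, end) (seconds, relative to epoch onset; e.g.
#' \code{c(-0.2, 0)} for the 200 ms preceding onset).
#'
#' @param epochs an [EpochSet-class].
#' @param baseline_window numeric length 2.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, baseline_window = c(-0.2, 0)) {
  t <- epochTimes(epochs)
  sel <- which(t >= baseline_window[1] & t < baseline_window[2])
  if (!length(sel)) stop("baseline window outside the stored epoch")
  dat <- epochs@data
  bl <- apply(dat[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs@data <- dat - as.vector(bl)           # recycles over samples
  epochs
}

#' Select trials or channels
#'
#' @param epochs an [EpochSet-class].
#' @param trials integer or logical index over trials.
#' @param channels labels (or index) of channels to keep.
#' @return the subset [EpochSet-class].
#' @export
subsetEpochs <- function(epochs, trials = NULL, channels = NULL) {
  dat <- epochs@data
  info <- epochs@info
  ch <- epochs@channels
  if (!is.null(trials)) {
    dat <- dat[trials, , , drop = FALSE]
    if (nrow(info)) info <- info[trials, , drop = FALSE]
  }
  if (!is.null(channels)) {
    idx <- if (is.character(channels)) matchChannels(epochs, channels)
           else channels
    dat <- dat[, idx, , drop = FALSE]
    ch <- ch[idx]
  }
  new("EpochSet", data = dat, rate = epochs@rate, times = epochs@times,
      channels = ch, info = info)
}

#' Crop the time axis
#'
#' @param epochs an [EpochSet-class].
#' @param window half-open window [start, end) in seconds.
#' @return the cropped [EpochSet-class].
#' @export
cropEpochs <- function(epochs, window) {
  t <- epochTimes(epochs)
  sel <- which(t >= window[1] & t < window[2])
  if (!length(sel)) stop("window outside the stored epoch")
  epochs@data <- epochs@data[, , sel, drop = FALSE]
  epochs@times <- t[sel]
  epochs
}
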