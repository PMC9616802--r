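#' @import methods
NULL

#' Channel montage with 3-D sensor positions
#'
#' Holds unique channel labels and their positions on (or near) the scalp
#' sphere, in head-radius units. The neighbour graph used by cluster-based
#' statistics and searchlight decoding is derived from these positions with
#' [channelNeighbours()].
#'
#' @slot labels character vector of unique channel labels.
#' @slot positions numeric matrix (channels x 3), columns x (right),
#'   y (anterior), z (superior); rownames are the labels.
#' @slot headRadius numeric scalar, radius of the idealised head sphere in the
#'   same (arbitrary) unit as the positions.
#' @exportClass ChannelLayout
setClass("ChannelLayout",
  representation(labels = "character", positions = "matrix",
                 headRadius = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@labels))
      msg <- c(msg, "channel labels must be unique")
    if (nrow(object@positions) != length(object@labels))
      msg <- c(msg, "positions must have one row per label")
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "positions must have 3 columns (x, y, z)")
    if (length(object@headRadius) != 1L || object@headRadius <= 0)
      msg <- c(msg, "headRadius must be a positive scalar")
    if (is.null(msg)) TRUE else msg
  })

#' Epoched multichannel EEG
#'
#' The lingua franca of every analysis stage: a trials x channels x samples
#' voltage array (microvolt) with a uniform time axis and one metadata row per
#' trial. Epochs are stored with 200 ms of pre-onset padding by default so that
#' per-epoch baseline correction needs no cross-epoch stitching; time 0 is
#' epoch onset.
#'
#' @slot data numeric array, trials x channels x samples (microvolt).
#' @slot rate sampling rate in Hz.
#' @slot times numeric vector of sample times in seconds relative to epoch
#'   onset; strictly increasing, uniform spacing 1/rate.
#' @slot channels character vector of unique channel labels.
#' @slot info data.frame, one row per trial (task, epoch, category, exemplar,
#'   correct, rt, block, trial, ... as available).
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", rate = "numeric", times = "numeric",
                 channels = "character", info = "data.frame"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L)
      msg <- c(msg, "data must be a 3-D array (trials x channels x samples)")
    else {
      if (d[2L] != length(object@channels))
        msg <- c(msg, "dim(data)[2] must equal length(channels)")
      if (d[3L] != length(object@times))
        msg <- c(msg, "dim(data)[3] must equal length(times)")
      if (nrow(object@info) > 0L && nrow(object@info) != d[1L])
        msg <- c(msg, "info must have one row per trial")
    }
    if (anyDuplicated(object@channels))
      msg <- c(msg, "channel labels must be unique")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a positive scalar")
    if (length(object@times) > 1L) {
      dt <- diff(object@times)
      if (any(dt <= 0))
        msg <- c(msg, "times must be strictly increasing")
      else if (max(abs(dt - 1 / object@rate)) > 1e-6 / object@rate)
        msg <- c(msg, "times must be uniformly spaced at 1/rate")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Spectral power (and optionally complex coefficients)
#'
#' Power over trials x channels x frequencies, with an optional fourth time
#' dimension for time-resolved estimates, plus the complex Fourier
#' coefficients when cross-spectra are needed downstream.
#'
#' @slot power numeric array, trials x channels x freqs (x times), microvolt^2.
#' @slot coef complex array of the same shape, or a zero-length array when
#'   coefficients were not retained.
#' @slot freqs frequencies in Hz, strictly increasing.
#' @slot times window-centre times in seconds, or numeric(0) for whole-epoch
#'   spectra.
#' @slot channels channel labels.
#' @slot method list of estimation metadata (taper, cycles map, step, padding).
#' @exportClass SpectralEstimate
setClass("SpectralEstimate",
  representation(power = "array", coef = "array", freqs = "numeric",
                 times = "numeric", channels = "character", method = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@power)
    nd <- length(d)
    if (!nd %in% c(3L, 4L))
      msg <- c(msg, "power must be 3-D or 4-D")
    else {
      if (d[3L] != length(object@freqs))
        msg <- c(msg, "dim(power)[3] must equal length(freqs)")
      if (nd == 4L && d[4L] != length(object@times))
        msg <- c(msg, "dim(power)[4] must equal length(times)")
      if (d[2L] != length(object@channels))
        msg <- c(msg, "dim(power)[2] must equal length(channels)")
    }
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "freqs must be strictly increasing")
    if (min(object@power, na.rm = TRUE) < -1e-12)
      msg <- c(msg, "power must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Cluster-based permutation test result
#'
#' @slot clusters list; each element a data.frame of member bins with columns
#'   channel, freq, time (indices; time NA for 2-D tests) plus channel labels.
#' @slot mass numeric, signed sum of t-values per cluster.
#' @slot pvalues numeric, permutation p-value per cluster (add-one estimator,
#'   never exactly 0).
#' @slot sigMask logical array over the tested bins (channels x freqs
#'   (x times)); TRUE where a significant cluster lives.
#' @slot tmap numeric array of observed per-bin t-values, same shape.
#' @slot nPerm number of permutations drawn.
#' @slot alpha nominal two-tailed alpha; each tail tested at alpha/2.
#' @slot seed integer seed that generated the permutation draws.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(clusters = "list", mass = "numeric", pvalues = "numeric",
                 sigMask = "array", tmap = "array", nPerm = "numeric",
                 alpha = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@mass) != length(object@clusters))
      msg <- c(msg, "one mass per cluster required")
    if (length(object@pvalues) != length(object@clusters))
      msg <- c(msg, "one p-value per cluster required")
    if (length(object@pvalues) &&
        (any(object@pvalues <= 0) || any(object@pvalues > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Cross-validated decoding result
#'
#' @slot accuracy numeric; a testing-time vector ("timecourse"), a training x
#'   testing time matrix ("generalization"), or a per-channel map
#'   ("searchlight"). Fractions correct in [0, 1].
#' @slot type one of "timecourse", "generalization", "searchlight".
#' @slot times testing times (s) for timecourse results.
#' @slot trainTimes,testTimes time axes (s) for generalization results.
#' @slot channels centre-channel labels for searchlight results.
#' @slot folds,repeats cross-validation structure.
#' @slot window analysis window (s) for searchlight results.
#' @slot seed integer seed governing fold assignment.
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(accuracy = "numeric", type = "character", times = "numeric",
                 trainTimes = "numeric", testTimes = "numeric",
                 channels = "character", folds = "numeric",
                 repeats = "numeric", window = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@type %in% c("timecourse", "generalization", "searchlight"))
      msg <- c(msg, "unknown result type")
    a <- object@accuracy
    if (length(a) && (min(a, na.rm = TRUE) < 0 || max(a, na.rm = TRUE) > 1))
      msg <- c(msg, "accuracy must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Seed-based coherence map
#'
#' Magnitude-squared coherence between a seed channel and every channel, per
#' frequency, averaged over an analysis time window.
#'
#' @slot seed seed-channel label.
#' @slot coherence numeric matrix, channels x freqs, values in [0, 1];
#'   the seed row is identically 1.
#' @slot channels,freqs axes.
#' @slot nTrials number of trials entering each estimate.
#' @slot nSubsamples number of subsample draws averaged (1 = none).
#' @slot band analysed band (Hz, length 2).
#' @slot window time window (s, length 2) averaged over.
#' @exportClass CoherenceMap
setClass("CoherenceMap",
  representation(seed = "character", coherence = "matrix",
                 channels = "character", freqs = "numeric",
                 nTrials = "numeric", nSubsamples = "numeric",
                 band = "numeric", window = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@coherence) != length(object@channels) ||
        ncol(object@coherence) != length(object@freqs))
      msg <- c(msg, "coherence must be channels x freqs")
    v <- object@coherence
    if (length(v) && (min(v, na.rm = TRUE) < -1e-9 ||
                      max(v, na.rm = TRUE) > 1 + 1e-9))
      msg <- c(msg, "coherence must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })
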