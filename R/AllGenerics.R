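#' Accessors for the wmtheta S4 containers
#'
#' Small, read-only accessors so that user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("spectralPower", function(x) standardGeneric("spectralPower"))
#' @rdname accessors
#' @export
setGeneric("spectralCoef", function(x) standardGeneric("spectralCoef"))
#' @rdname accessors
#' @export
setGeneric("spectralFreqs", function(x) standardGeneric("spectralFreqs"))
#' @rdname accessors
#' @export
setGeneric("spectralTimes", function(x) standardGeneric("spectralTimes"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("coherenceValues", function(x) standardGeneric("coherenceValues"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("clusterPvalues", function(x) standardGeneric("clusterPvalues"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2L])
#' @rdname accessors
setMethod("nChannels", "ChannelLayout", function(x) length(x@labels))
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname accessors
setMethod("channelNames", "ChannelLayout", function(x) x@labels)
#' @rdname accessors
setMethod("channelNames", "SpectralEstimate", function(x) x@channels)
#' @rdname accessors
setMethod("channelNames", "CoherenceMap", function(x) x@channels)
#' @rdname accessors
setMethod("channelPositions", "ChannelLayout", function(x) x@positions)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
setMethod("trialInfo", "EpochSet", function(x) x@info)
#' @rdname accessors
setMethod("spectralPower", "SpectralEstimate", function(x) x@power)
#' @rdname accessors
setMethod("spectralCoef", "SpectralEstimate", function(x) x@coef)
#' @rdname accessors
setMethod("spectralFreqs", "SpectralEstimate", function(x) x@freqs)
#' @rdname accessors
setMethod("spectralTimes", "SpectralEstimate", function(x) x@times)
#' @rdname accessors
setMethod("accuracy", "DecodingResult", function(x) {
  a <- x@accuracy
  if (x@type == "generalization")
    a <- matrix(a, length(x@trainTimes), length(x@testTimes),
                dimnames = list(NULL, NULL))
  else if (x@type == "searchlight")
    names(a) <- x@channels
  a
})
#' @rdname accessors
setMethod("coherenceValues", "CoherenceMap", function(x) {
  structure(x@coherence, dimnames = list(x@channels, x@freqs))
})
#' @rdname accessors
setMethod("clusters", "ClusterTestResult", function(x) x@clusters)
#' @rdname accessors
setMethod("clusterPvalues", "ClusterTestResult", function(x) x@pvalues)
#' @rdname accessors
setMethod("significanceMask", "ClusterTestResult", function(x) x@sigMask)

setMethod("show", "ChannelLayout", function(object) {
  cat("ChannelLayout:", length(object@labels), "channels, head radius",
      object@headRadius, "\n")
  cat("  labels:", paste(utils::head(object@labels, 6L), collapse = " "),
      if (length(object@labels) > 6L) "...", "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@rate))
  cat(sprintf("  time %.3f .. %.3f s\n", object@times[1L],
              object@times[length(object@times)]))
  if (nrow(object@info)) {
    cols <- intersect(c("task", "epoch", "category"), names(object@info))
    for (cl in cols) {
      tb <- table(object@info[[cl]])
      cat("  ", cl, ": ", paste(names(tb), tb, sep = "=", collapse = " "),
          "\n", sep = "")
    }
  }
})

setMethod("show", "SpectralEstimate", function(object) {
  d <- dim(object@power)
  cat("SpectralEstimate:", paste(d, collapse = " x "),
      if (length(d) == 4L) "(trials x channels x freqs x times)"
      else "(trials x channels x freqs)", "\n")
  cat(sprintf("  freqs %.2f .. %.2f Hz (%d points)\n", object@freqs[1L],
              object@freqs[length(object@freqs)], length(object@freqs)))
})

setMethod("show", "ClusterTestResult", function(object) {
  k <- length(object@clusters)
  cat(sprintf("ClusterTestResult: %d cluster(s), %d permutations, alpha %.3f\n",
              k, object@nPerm, object@alpha))
  if (k) {
    sig <- object@pvalues <= object@alpha / 2
    for (i in seq_len(k))
      cat(sprintf("  cluster %d: mass %.2f, p = %.4g%s (%d bins, %d channels)\n",
                  i, object@mass[i], object@pvalues[i],
                  if (sig[i]) " *" else "",
                  nrow(object@clusters[[i]]),
                  length(unique(object@clusters[[i]]$channel))))
  }
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s): mean accuracy %.3f\n", object@type,
              mean(object@accuracy, na.rm = TRUE)))
  cat(sprintf("  %d folds x %d repeats\n", object@folds, object@repeats))
})

setMethod("show", "CoherenceMap", function(object) {
  cat(sprintf(
    "CoherenceMap: seed %s, %d channels x %d freqs, %d trials%s\n",
    object@seed, length(object@channels), length(object@freqs),
    object@nTrials,
    if (object@nSubsamples > 1L)
      sprintf(" (mean of %d subsamples)", object@nSubsamples) else ""))
})
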