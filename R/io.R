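#' Read / write epoched EEG as a plain-text container
#'
#' Serializes an [EpochSet-class] to a directory holding \code{meta.json}
#' (rate, times, channel labels), \code{metadata.tsv} (per-trial table) and
#' \code{data.tsv.gz} (one row per trial x channel, samples as columns,
#' full-precision numbers). The round trip is lossless to the last
#' representable digit.
#'
#' @param epochs an [EpochSet-class].
#' @param path directory path (created if missing).
#' @return \code{readEpochs} returns the [EpochSet-class];
#'   \code{writeEpochs} returns \code{path} invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(rate = epochs@rate, t0 = epochs@times[1L],
               n_trials = nTrials(epochs), n_channels = nChannels(epochs),
               n_samples = length(epochs@times), channels = epochs@channels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(epochs@info))
    utils::write.table(epochs@info, file.path(path, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  m <- flattenTC(aperm(epochs@data, c(2L, 1L, 3L)))  # channel-major rows
  con <- gzfile(file.path(path, "data.tsv.gz"), "w")
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  mfile <- file.path(path, "metadata.tsv")
  info <- if (file.exists(mfile))
    utils::read.table(mfile, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else data.frame()
  m <- as.matrix(utils::read.table(gzfile(file.path(path, "data.tsv.gz")),
                                   sep = "\t"))
  dimnames(m) <- NULL
  arr <- aperm(array(m, c(meta$n_channels, meta$n_trials, meta$n_samples)),
               c(2L, 1L, 3L))
  epochSet(arr, meta$rate, channels = meta$channels, info = info,
           t0 = meta$t0)
}
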