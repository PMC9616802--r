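## Cross-validated linear discriminant decoding of stimulus category.
## Features are channel voltages at each time point; the covariance is
## shrunk toward a scaled identity with an analytically chosen
## (Ledoit-Wolf-style) coefficient, which keeps the classifier stable when
## the feature count approaches the trial count.

# train a two-class shrinkage LDA; returns list(w, b, classes)
trainShrinkageLDA <- function(X, y) {
  classes <- sort(unique(y))
  i1 <- y == classes[1L]
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  Z <- X
  Z[i1, ] <- sweep(X[i1, , drop = FALSE], 2L, m1)
  Z[!i1, ] <- sweep(X[!i1, , drop = FALSE], 2L, m2)
  n <- nrow(Z)
  S <- crossprod(Z) / n
  p <- ncol(S)
  nu <- sum(diag(S)) / p
  normS2 <- sum(S^2)
  zSz <- rowSums((Z %*% S) * Z)
  z2 <- rowSums(Z^2)
  b2 <- sum(z2^2 - 2 * zSz + normS2) / n^2
  d2 <- normS2 - nu^2 * p
  lambda <- if (d2 <= 0) 1 else min(1, max(0, b2 / d2))
  Sigma <- (1 - lambda) * S
  diag(Sigma) <- diag(Sigma) + lambda * nu
  w <- solve(Sigma, m1 - m2)
  list(w = w, b = sum(w * (m1 + m2)) / 2, classes = classes,
       lambda = lambda)
}

predictLDAcorrect <- function(model, X, y) {
  (as.vector(X %*% model$w) > model$b) == (y == model$classes[1L])
}

# stratified fold assignments, one integer vector per repeat
makeFolds <- function(y, folds, repeats, seed) {
  classes <- unique(y)
  cnt <- table(y)
  if (any(cnt < folds))
    stop("every class needs at least `folds` trials")
  withSeed(seed, lapply(seq_len(repeats), function(r) {
    assign <- integer(length(y))
    for (cl in classes) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  }))
}

# core engine: accuracy over train x test time pairs, averaged over folds
# then repeats. diagonal_only restricts to train == test.
cvEngine <- function(dat, y, folds, repeats, seed, trainIdx, testIdx,
                     diagonal_only = FALSE) {
  foldSets <- makeFolds(y, folds, repeats, seed)
  nTr <- length(trainIdx)
  nTe <- length(testIdx)
  p <- dim(dat)[2L]
  acc <- matrix(0, nTr, if (diagonal_only) 1L else nTe)
  for (r in seq_len(repeats)) {
    fa <- foldSets[[r]]
    accR <- matrix(0, nTr, ncol(acc))
    for (f in seq_len(folds)) {
      tr <- fa != f
      te <- !tr
      yTr <- y[tr]; yTe <- y[te]
      Xte <- dat[te, , , drop = FALSE]
      for (ti in seq_len(nTr)) {
        model <- trainShrinkageLDA(
          matrix(dat[tr, , trainIdx[ti]], ncol = p), yTr)
        if (diagonal_only) {
          ok <- predictLDAcorrect(
            model, matrix(Xte[, , trainIdx[ti]], ncol = p), yTe)
          accR[ti, 1L] <- accR[ti, 1L] + mean(ok)
        } else {
          # (trials*testTimes) scores via one multiply
          sc <- matrix(matrix(aperm(Xte[, , testIdx, drop = FALSE],
                                    c(1L, 3L, 2L)),
                              ncol = p) %*% model$w,
                       nrow = sum(te))
          corr <- (sc > model$b) == (yTe == model$classes[1L])
          accR[ti, ] <- accR[ti, ] + colMeans(corr)
        }
      }
    }
    acc <- acc + accR / folds
  }
  acc / repeats
}

asLabels <- function(epochs, labels) {
  if (is.null(labels)) {
    info <- trialInfo(epochs)
    if (!"category" %in% names(info))
      stop("no labels given and trialInfo has no 'category' column")
    labels <- as.character(info$category)
  }
  if (length(unique(labels)) != 2L)
    stop("exactly two classes required")
  labels
}

#' Average trials within exemplar pairs
#'
#' Within each exemplar, trials are randomly assigned to pairs and each pair
#' is replaced by its mean; an odd remainder trial passes through
#' unaveraged. Metadata (exemplar, category, ...) is inherited from the
#' first member of each pair. Pair averaging roughly doubles the
#' signal-to-noise ratio of the class patterns at half the trial count.
#'
#' @param epochs an [EpochSet-class] whose \code{trialInfo} has an
#'   \code{exemplar} column.
#' @param seed integer seed for the random pairing.
#' @return list(epochs, pairs) where \code{pairs} records the source trials
#'   (columns out_trial, member1, member2; member2 NA for pass-through).
#' @export
pairAverage <- function(epochs, seed = 1L) {
  info <- trialInfo(epochs)
  if (!"exemplar" %in% names(info))
    stop("trialInfo must contain an 'exemplar' column")
  groups <- split(seq_len(nTrials(epochs)), info$exemplar)
  pairs <- withSeed(seed, {
    out <- list()
    for (g in groups) {
      g <- if (length(g) > 1L) sample(g) else g
      np <- length(g) %/% 2L
      if (np) out[[length(out) + 1L]] <-
          cbind(g[seq_len(np) * 2L - 1L], g[seq_len(np) * 2L])
      if (length(g) %% 2L)
        out[[length(out) + 1L]] <- cbind(g[length(g)], NA_integer_)
    }
    do.call(rbind, out)
  })
  dat <- epochs@data
  nOut <- nrow(pairs)
  newDat <- array(0, c(nOut, dim(dat)[2L], dim(dat)[3L]))
  for (i in seq_len(nOut)) {
    newDat[i, , ] <- if (is.na(pairs[i, 2L])) dat[pairs[i, 1L], , ]
      else (dat[pairs[i, 1L], , ] + dat[pairs[i, 2L], , ]) / 2
  }
  newInfo <- info[pairs[, 1L], , drop = FALSE]
  rownames(newInfo) <- NULL
  out <- new("EpochSet", data = newDat, rate = epochs@rate,
             times = epochs@times, channels = epochs@channels,
             info = newInfo)
  list(epochs = out,
       pairs = data.frame(out_trial = seq_len(nOut),
                          member1 = pairs[, 1L], member2 = pairs[, 2L]))
}

#' Standard decoding preprocessing chain
#'
#' Resample to 200 Hz, smooth with a 100 ms sliding average, baseline-correct
#' to the 200 ms preceding epoch onset, then pair-average within exemplars.
#'
#' @param epochs an [EpochSet-class] (stored with >= 200 ms pre-onset
#'   padding).
#' @param new_rate resampling target (Hz).
#' @param smooth_ms sliding-average window (ms).
#' @param baseline_window baseline window (s).
#' @param pair if TRUE, apply [pairAverage()].
#' @param seed seed for the pairing.
#' @return list(epochs, pairs).
#' @export
decodingChain <- function(epochs, new_rate = 200, smooth_ms = 100,
                          baseline_window = c(-0.2, 0), pair = TRUE,
                          seed = 1L) {
  ep <- resampleEpochs(epochs, new_rate)
  ep <- slidingAverage(ep, smooth_ms)
  ep <- baselineCorrect(ep, baseline_window)
  if (pair) pairAverage(ep, seed) else list(epochs = ep, pairs = NULL)
}

#' Cross-validated LDA decoding accuracy over time
#'
#' At every time point the channel voltages are the features of a two-class
#' shrinkage LDA, evaluated with stratified k-fold cross-validation repeated
#' with reshuffled folds; accuracies are averaged over folds, then repeats.
#'
#' @param epochs an [EpochSet-class] (typically after [decodingChain()]).
#' @param labels class labels (default: the \code{category} metadata).
#' @param folds,repeats cross-validation structure (defaults 5 x 5).
#' @param seed integer seed for fold assignment.
#' @param times restrict to these times (s); default all.
#' @return a [DecodingResult-class] of type "timecourse".
#' @export
crossvalDecode <- function(epochs, labels = NULL, folds = 5L, repeats = 5L,
                           seed = 1L, times = NULL) {
  y <- asLabels(epochs, labels)
  t <- epochTimes(epochs)
  idx <- if (is.null(times)) seq_along(t)
         else vapply(times, function(x) which.min(abs(t - x)), integer(1))
  acc <- cvEngine(epochs@data, y, folds, repeats, seed, idx, idx,
                  diagonal_only = TRUE)
  new("DecodingResult", accuracy = as.vector(acc), type = "timecourse",
      times = t[idx], trainTimes = numeric(0), testTimes = numeric(0),
      channels = character(0), folds = folds, repeats = repeats,
      window = numeric(0), seed = as.numeric(seed))
}

#' Temporal generalization matrix
#'
#' Trains a classifier at every training time and tests it at every testing
#' time. With the same seed, folds and times, the diagonal reproduces
#' [crossvalDecode()] exactly.
#'
#' @param epochs an [EpochSet-class].
#' @param labels class labels (default: category metadata).
#' @param train_times,test_times time grids (s); default: all sample times.
#' @param folds,repeats,seed as in [crossvalDecode()].
#' @return a [DecodingResult-class] of type "generalization".
#' @export
temporalGeneralization <- function(epochs, labels = NULL,
                                   train_times = NULL, test_times = NULL,
                                   folds = 5L, repeats = 5L, seed = 1L) {
  y <- asLabels(epochs, labels)
  t <- epochTimes(epochs)
  pick <- function(x) if (is.null(x)) seq_along(t)
    else vapply(x, function(v) which.min(abs(t - v)), integer(1))
  trIdx <- pick(train_times)
  teIdx <- pick(test_times)
  acc <- cvEngine(epochs@data, y, folds, repeats, seed, trIdx, teIdx,
                  diagonal_only = FALSE)
  new("DecodingResult", accuracy = as.vector(acc), type = "generalization",
      times = numeric(0), trainTimes = t[trIdx], testTimes = t[teIdx],
      channels = character(0), folds = folds, repeats = repeats,
      window = numeric(0), seed = as.numeric(seed))
}

#' Average stimulus-trained rows of a generalization matrix
#'
#' Collapses the training-time dimension of a temporal generalization result
#' over a training window (e.g. the 0-0.75 s stimulus period), yielding a
#' testing-time series of stimulus-to-delay generalization accuracy.
#'
#' @param result a generalization [DecodingResult-class].
#' @param train_window training-time window (s).
#' @return numeric vector over testing times (named by time).
#' @export
generalizationTimecourse <- function(result, train_window = c(0, 0.75)) {
  stopifnot(result@type == "generalization")
  M <- accuracy(result)
  sel <- result@trainTimes >= train_window[1] &
    result@trainTimes <= train_window[2]
  out <- colMeans(M[sel, , drop = FALSE])
  names(out) <- result@testTimes
  out
}

#' Channel searchlight decoding
#'
#' For every centre channel, the features are the centre plus its graph
#' neighbours; per-timepoint LDA accuracies inside the analysis window are
#' averaged (over timepoints, folds and repeats) and assigned to the centre.
#'
#' @param epochs an [EpochSet-class].
#' @param adjacency channel adjacency matrix over the epoch's channels.
#' @param window analysis window [start, end] in seconds.
#' @param labels,folds,repeats,seed as in [crossvalDecode()].
#' @return a [DecodingResult-class] of type "searchlight" (one accuracy per
#'   channel).
#' @export
searchlightDecode <- function(epochs, adjacency, window, labels = NULL,
                              folds = 5L, repeats = 5L, seed = 1L) {
  y <- asLabels(epochs, labels)
  if (nrow(adjacency) != nChannels(epochs))
    stop("adjacency must cover all channels of the epochs")
  t <- epochTimes(epochs)
  tIdx <- which(t >= window[1] & t <= window[2])
  if (!length(tIdx)) stop("window contains no samples")
  nCh <- nChannels(epochs)
  acc <- numeric(nCh)
  for (ch in seq_len(nCh)) {
    feats <- c(ch, which(adjacency[ch, ]))
    sub <- epochs@data[, feats, , drop = FALSE]
    a <- cvEngine(sub, y, folds, repeats, seed, tIdx, tIdx,
                  diagonal_only = TRUE)
    acc[ch] <- mean(a)
  }
  new("DecodingResult", accuracy = acc, type = "searchlight",
      times = numeric(0), trainTimes = numeric(0), testTimes = numeric(0),
      channels = channelNames(epochs), folds = folds, repeats = repeats,
      window = window, seed = as.numeric(seed))
}

#' Significance of group-level decoding accuracy against chance
#'
#' Per-timepoint t-test of the participants' accuracy series against chance,
#' clustered over adjacent timepoints, with a max-sum permutation null built
#' from random per-participant sign flips of (accuracy - chance).
#'
#' @param accuracies numeric matrix participants x timepoints.
#' @param times timepoint axis in seconds.
#' @param chance chance level (0.5 for two balanced classes).
#' @param n_perm,alpha,seed as in [clusterPermutationTest()].
#' @return list(result = [ClusterTestResult-class], windows = data.frame
#'   with columns start, end in seconds).
#' @export
decodeSignificance <- function(accuracies, times, chance = 0.5,
                               n_perm = 500L, alpha = 0.05, seed = 1L) {
  if (nrow(accuracies) < 2L) stop("need at least 2 participants")
  nT <- ncol(accuracies)
  condA <- array(accuracies, c(nrow(accuracies), 1L, nT))
  condB <- array(chance, c(nrow(accuracies), 1L, nT))
  adj <- matrix(FALSE, 1L, 1L, dimnames = list("acc", "acc"))
  res <- clusterPermutationTest(condA, condB, adj, n_perm = n_perm,
                                alpha = alpha, min_channel_extent = 1L,
                                seed = seed)
  mask <- as.vector(significanceMask(res))
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  windows <- data.frame(start = times[starts[sel]], end = times[ends[sel]])
  list(result = res, windows = windows)
}
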