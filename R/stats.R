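#' Paired t-test with Cohen's d
#'
#' Two-tailed paired t on the per-unit differences, with the paired-design
#' effect size d = mean(diff) / sd(diff).
#'
#' @param x,y numeric vectors of equal length (>= 2), one value per unit.
#' @return list(t, df, p, d).
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1, d = 0))
    stop("zero variance with nonzero mean difference")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / stats::sd(d))
}

#' Holm step-down correction (uncapped)
#'
#' Step-down Holm: sort p ascending, multiply the i-th by (m - i + 1),
#' enforce monotonicity by a running maximum, and map back to input order.
#' By default values are NOT truncated at 1, reproducing the convention of
#' reporting adjusted values above 1 (e.g. p_Holm = 1.06); set
#' \code{cap = TRUE} for the usual truncation.
#'
#' @param p raw p-values in [0, 1].
#' @param cap truncate adjusted values at 1.
#' @return adjusted p-values in input order.
#' @export
holm <- function(p, cap = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1L)
  adj <- cummax(adj)
  if (cap) adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Power of the two-tailed paired t-test
#'
#' Exact power from the noncentral t distribution with df = n - 1 and
#' noncentrality d * sqrt(n).
#'
#' @param n number of pairs (>= 2).
#' @param d Cohen's d for paired designs.
#' @param alpha two-tailed alpha in (0, 1).
#' @return power in [0, 1].
#' @export
powerPairedT <- function(n, d, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp)
}

#' Tukey-fence outlier rule
#'
#' Flags values more than 1.5 inter-quartile ranges below the lower quartile
#' or above the upper quartile. Quartiles use the linear-interpolation
#' convention (type 7).
#'
#' @param values numeric vector (>= 4 values).
#' @param k fence multiplier (1.5).
#' @return logical mask, TRUE = outlier.
#' @export
iqrOutliers <- function(values, k = 1.5) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - k * iqr | values > q[2L] + k * iqr
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor decomposition on a complete balanced
#' design, fitted with \code{stats::aov} using the Error(unit/(A*B))
#' stratification; partial eta squared is SS_effect / (SS_effect +
#' SS_error_effect). No sphericity correction is applied by default (the
#' reported df are the uncorrected (a-1)(b-1), (a-1)(b-1)(n-1) etc.);
#' \code{gg = TRUE} applies the Greenhouse-Geisser epsilon to df and p.
#'
#' @param data numeric array units x levels(A) x levels(B); no missing
#'   cells.
#' @param gg apply Greenhouse-Geisser correction.
#' @return data.frame with rows A, B, A:B and columns F, df_num, df_den, p,
#'   partial_eta_sq.
#' @export
rmAnova2 <- function(data, gg = FALSE) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be units x A-levels x B-levels")
  if (anyNA(data)) stop("missing cells not allowed")
  n <- d[1L]; a <- d[2L]; b <- d[3L]
  df <- data.frame(y = as.vector(data),
                   unit = factor(rep(seq_len(n), a * b)),
                   A = factor(rep(rep(seq_len(a), each = n), b)),
                   B = factor(rep(seq_len(b), each = n * a)))
  fit <- stats::aov(y ~ A * B + Error(unit / (A * B)), data = df)
  sm <- summary(fit)
  ssTot <- sum((data - mean(data))^2)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    eff <- tab[match(term, rn), ]
    err <- tab[match("Residuals", rn), ]
    gghat <- 1
    if (gg) gghat <- ggEpsilon(data, term)
    Fv <- eff[["F value"]]
    eta <- eff[["Sum Sq"]] / (eff[["Sum Sq"]] + err[["Sum Sq"]])
    # guard against 0/0 ratios of numerical noise in degenerate data
    if (!is.finite(Fv) ||
        eff[["Sum Sq"]] <= 1e-12 * (sum(data^2) + 1)) {
      Fv <- 0
      eta <- 0
    }
    dfn <- eff[["Df"]] * gghat
    dfd <- err[["Df"]] * gghat
    data.frame(effect = term, F = Fv, df_num = dfn, df_den = dfd,
               p = stats::pf(Fv, dfn, dfd, lower.tail = FALSE),
               partial_eta_sq = eta)
  }
  out <- rbind(pull("Error: unit:A", "A"),
               pull("Error: unit:B", "B"),
               pull("Error: unit:A:B", "A:B"))
  rownames(out) <- NULL
  out
}

# Greenhouse-Geisser epsilon for one within-subject effect
ggEpsilon <- function(data, term) {
  n <- dim(data)[1L]
  cellMeans <- switch(term,
    "A" = apply(data, c(1L, 2L), mean),
    "B" = apply(data, c(1L, 3L), mean),
    "A:B" = {
      d <- dim(data)
      m <- matrix(data, n)
      # double-centre across A and B to isolate the interaction
      arr <- array(data, d)
      am <- apply(arr, c(1L, 2L), mean)
      bm <- apply(arr, c(1L, 3L), mean)
      gm <- apply(arr, 1L, mean)
      res <- arr
      for (i in seq_len(d[2L])) for (j in seq_len(d[3L]))
        res[, i, j] <- arr[, i, j] - am[, i] - bm[, j] + gm
      matrix(res, n)
    })
  S <- stats::cov(cellMeans)
  k <- ncol(S)
  # classic Greenhouse-Geisser epsilon on the double-centred covariance
  M <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  min(1, max(eps, 1 / (k - 1)))
}

## ---- cluster-based permutation machinery -------------------------------

# column-wise paired t-values of a units x bins difference matrix
colPairedT <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  sd <- sqrt((colSums(D^2) - n * mu^2) / (n - 1))
  tv <- mu / (sd / sqrt(n))
  tv[sd == 0 & mu == 0] <- 0
  tv
}

# connected components of suprathreshold bins over channel x freq x time
# grids; bins of opposite sign never join. Returns a list of integer vectors
# (bin indices).
binComponents <- function(bins, sign, nCh, nF, nT, nbrList) {
  if (!length(bins)) return(list())
  inSet <- integer(nCh * nF * nT)
  inSet[bins] <- seq_along(bins)
  sgn <- integer(nCh * nF * nT)
  sgn[bins] <- sign
  comp <- integer(length(bins))
  out <- list()
  cid <- 0L
  for (s in seq_along(bins)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- bins[s]
    comp[s] <- cid
    members <- bins[s]
    while (length(queue)) {
      b <- queue[[1L]]
      queue <- queue[-1L]
      ft <- (b - 1L) %/% nCh          # 0-based freq-time slab
      ch <- b - ft * nCh              # 1-based channel
      f <- ft %% nF + 1L
      tt <- ft %/% nF + 1L
      cand <- c((ft * nCh) + nbrList[[ch]],
                if (f > 1L) b - nCh,
                if (f < nF) b + nCh,
                if (tt > 1L) b - nCh * nF,
                if (tt < nT) b + nCh * nF)
      for (nb in cand) {
        j <- inSet[nb]
        if (j && !comp[j] && sgn[nb] == sgn[b]) {
          comp[j] <- cid
          queue <- c(queue, nb)
          members <- c(members, nb)
        }
      }
    }
    out[[cid]] <- members
  }
  out
}

# cluster masses satisfying the channel criterion, for one t-map
clusterMasses <- function(tv, thr, nCh, nF, nT, nbrList, minExtent, mode) {
  pos <- which(tv > thr)
  neg <- which(tv < -thr)
  if (mode == "bin-neighbours" && (length(pos) || length(neg))) {
    supra <- logical(length(tv))
    supra[pos] <- TRUE
    keepFun <- function(idx) {
      keep <- vapply(idx, function(b) {
        ft <- (b - 1L) %/% nCh
        ch <- b - ft * nCh
        sum(supra[(ft * nCh) + nbrList[[ch]]]) >= minExtent
      }, logical(1))
      idx[keep]
    }
    pos <- keepFun(pos)
    supra[] <- FALSE
    supra[neg] <- TRUE
    neg <- keepFun(neg)
  }
  bins <- c(pos, neg)
  if (!length(bins)) return(list(bins = list(), mass = numeric(0)))
  sgn <- rep(c(1L, -1L), c(length(pos), length(neg)))
  comps <- binComponents(bins, sgn, nCh, nF, nT, nbrList)
  if (mode == "extent") {
    keep <- vapply(comps, function(m)
      length(unique((m - 1L) %% nCh + 1L)) >= minExtent, logical(1))
    comps <- comps[keep]
  }
  list(bins = comps,
       mass = vapply(comps, function(m) sum(tv[m]), numeric(1)))
}

#' Cluster-based permutation test for paired channel x frequency (x time)
#' data
#'
#' Nonparametric family-wise inference: (1) per-bin two-tailed paired t
#' between the conditions; (2) suprathreshold bins (|t| above the paired-t
#' critical value at \code{alpha}) are clustered by adjacency -- channels via
#' the neighbour graph, frequency and time via grid adjacency -- separately
#' for positive and negative signs; (3) clusters spanning fewer than
#' \code{min_channel_extent} distinct channels are discarded (set
#' \code{channel_criterion = "bin-neighbours"} for the alternative reading
#' in which each suprathreshold bin must itself have at least that many
#' suprathreshold channel neighbours); (4) the null distribution is the
#' maximum absolute cluster mass (sum of t-values) over random per-unit
#' condition-label flips; (5) each cluster's p-value uses the add-one
#' estimator (1 + #permutations >= observed) / (1 + n_perm) and is judged
#' against alpha/2 per tail.
#'
#' @param condA,condB numeric arrays units x channels x freqs (x times) from
#'   the same units (paired design).
#' @param adjacency logical channel adjacency matrix (from
#'   [channelNeighbours()]); its dimnames name the channels.
#' @param n_perm number of permutations (default 500).
#' @param alpha nominal two-tailed alpha (also the cluster-forming alpha).
#' @param min_channel_extent minimum distinct channels per retained cluster.
#' @param channel_criterion "extent" (default) or "bin-neighbours".
#' @param seed integer seed for the permutation draws.
#' @return a [ClusterTestResult-class].
#' @export
clusterPermutationTest <- function(condA, condB, adjacency, n_perm = 500L,
                                   alpha = 0.05, min_channel_extent = 3L,
                                   channel_criterion = c("extent",
                                                         "bin-neighbours"),
                                   seed = 1L) {
  channel_criterion <- match.arg(channel_criterion)
  dA <- dim(condA)
  if (!identical(dA, dim(condB))) stop("condition arrays must match")
  if (length(dA) == 3L) {
    dim(condA) <- c(dA, 1L)
    dim(condB) <- c(dA, 1L)
    dA <- dim(condA)
  }
  n <- dA[1L]; nCh <- dA[2L]; nF <- dA[3L]; nT <- dA[4L]
  if (nrow(adjacency) != nCh)
    stop("adjacency must cover all channels")
  chLabels <- rownames(adjacency)
  if (is.null(chLabels)) chLabels <- sprintf("ch%02d", seq_len(nCh))
  nbrList <- lapply(seq_len(nCh), function(i) which(adjacency[i, ]))
  D <- matrix(condA - condB, n)               # units x bins (ch fastest)
  thr <- stats::qt(1 - alpha / 2, n - 1)
  tv <- colPairedT(D)
  obs <- clusterMasses(tv, thr, nCh, nF, nT, nbrList, min_channel_extent,
                       channel_criterion)
  nullMax <- withSeed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tp <- colPairedT(D * s)
      cm <- clusterMasses(tp, thr, nCh, nF, nT, nbrList,
                          min_channel_extent, channel_criterion)
      if (length(cm$mass)) max(abs(cm$mass)) else 0
    }, numeric(1))
  })
  pv <- vapply(obs$mass, function(m)
    (1 + sum(nullMax >= abs(m))) / (1 + n_perm), numeric(1))
  ord <- order(-abs(obs$mass))
  bins <- obs$bins[ord]; mass <- obs$mass[ord]; pv <- pv[ord]
  clusterDf <- lapply(bins, function(m) {
    ft <- (m - 1L) %/% nCh
    ch <- m - ft * nCh
    data.frame(channel = ch, label = chLabels[ch],
               freq = ft %% nF + 1L,
               time = if (nT > 1L) ft %/% nF + 1L else NA_integer_)
  })
  sig <- array(FALSE, c(nCh, nF, nT))
  for (i in seq_along(bins)) if (pv[i] <= alpha / 2) sig[bins[[i]]] <- TRUE
  tmap <- array(tv, c(nCh, nF, nT))
  if (nT == 1L) {
    dim(sig) <- c(nCh, nF)
    dim(tmap) <- c(nCh, nF)
  }
  new("ClusterTestResult", clusters = clusterDf, mass = mass, pvalues = pv,
      sigMask = sig, tmap = tmap, nPerm = n_perm, alpha = alpha,
      seed = as.numeric(seed))
}

#' Channels belonging to significant clusters
#' @param result a [ClusterTestResult-class].
#' @param sign "pos", "neg" or "any".
#' @return character vector of channel labels.
#' @export
significantChannels <- function(result, sign = c("any", "pos", "neg")) {
  sign <- match.arg(sign)
  sel <- result@pvalues <= result@alpha / 2
  if (sign == "pos") sel <- sel & result@mass > 0
  if (sign == "neg") sel <- sel & result@mass < 0
  unique(unlist(lapply(result@clusters[sel], `[[`, "label")))
}

#' Serialize a cluster test result to JSON
#' @param result a [ClusterTestResult-class].
#' @param path file path.
#' @export
writeClusterResult <- function(result, path) {
  obj <- list(n_perm = result@nPerm, alpha = result@alpha,
              seed = result@seed,
              clusters = lapply(seq_along(result@clusters), function(i)
                list(mass = result@mass[i], p = result@pvalues[i],
                     bins = result@clusters[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
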