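test_that("paired t statistic, df and effect size follow the textbook
           formulas", {
  same <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
  res <- pairedT(c(2, 3, 4), c(1, 1, 1))   # diffs 1, 2, 3
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  set.seed(21)
  x <- rnorm(15); y <- rnorm(15)
  r <- pairedT(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(r$t), 14), tolerance = 1e-10)
  expect_equal(r$d, mean(d) / sd(d), tolerance = 1e-10)
  expect_error(pairedT(1, 2), "at least 2")
  expect_error(pairedT(c(1, NA), c(1, 2)), "missing")
})

test_that("Holm correction steps down, stays monotone, and is uncapped", {
  expect_equal(holm(0.2), 0.2)
  expect_equal(holm(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm(c(0.5, 0.6)), c(1.0, 1.0))
  # uncapped values above 1 survive unless cap = TRUE
  expect_equal(holm(c(0.5, 0.53, 0.55)), c(1.5, 1.5, 1.5))
  expect_equal(holm(c(0.5, 0.53, 0.55), cap = TRUE), c(1, 1, 1))
  set.seed(22)
  p <- runif(20)
  expect_equal(holm(p, cap = TRUE), p.adjust(p, "holm"), tolerance = 1e-12)
  expect_true(all(holm(p) >= p))
  expect_error(holm(c(0.1, 1.2)), "lie in")
})

test_that("paired-t power matches the noncentral-t computation", {
  expect_equal(powerPairedT(28, 0), 0.05, tolerance = 1e-10)
  expect_equal(powerPairedT(28, 0.55), 0.80, tolerance = 0.005)
  expect_gt(powerPairedT(10000, 0.5), 0.9999)
  expect_error(powerPairedT(1, 0.5), "n must")
  expect_error(powerPairedT(28, 0.5, 1.5), "alpha")
})

test_that("IQR outlier rule with interpolated quartiles", {
  expect_false(any(iqrOutliers(rep(3, 10))))
  expect_equal(iqrOutliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(iqrOutliers(c(-100, 1, 2, 3, 4)),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(iqrOutliers(1:3), "at least 4")
})

test_that("repeated-measures ANOVA matches a hand-coded SS decomposition", {
  set.seed(23)
  dat <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  res <- rmAnova2(dat)
  # independent sums-of-squares oracle
  n <- 6; a <- 2; b <- 4
  gm <- mean(dat)
  mA <- apply(dat, 2, mean); mB <- apply(dat, 3, mean)
  mS <- apply(dat, 1, mean)
  mAB <- apply(dat, c(2, 3), mean)
  mSA <- apply(dat, c(1, 2), mean); mSB <- apply(dat, c(1, 3), mean)
  ssA <- n * b * sum((mA - gm)^2)
  ssB <- n * a * sum((mB - gm)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ssSA <- b * sum((sweep(sweep(mSA, 1, mS), 2, mA) + gm)^2)
  ssSB <- a * sum((sweep(sweep(mSB, 1, mS), 2, mB) + gm)^2)
  ssTot <- sum((dat - gm)^2)
  ssS <- a * b * sum((mS - gm)^2)
  ssSAB <- ssTot - ssS - ssA - ssB - ssAB - ssSA - ssSB
  fA <- (ssA / (a - 1)) / (ssSA / ((a - 1) * (n - 1)))
  fB <- (ssB / (b - 1)) / (ssSB / ((b - 1) * (n - 1)))
  fAB <- (ssAB / ((a - 1) * (b - 1))) /
    (ssSAB / ((a - 1) * (b - 1) * (n - 1)))
  expect_equal(res$F, c(fA, fB, fAB), tolerance = 1e-8)
  expect_equal(res$partial_eta_sq,
               c(ssA / (ssA + ssSA), ssB / (ssB + ssSB),
                 ssAB / (ssAB + ssSAB)), tolerance = 1e-8)
  # the load x frequency design of a 28-participant cohort
  big <- array(rnorm(28 * 2 * 9), c(28, 2, 9))
  res28 <- rmAnova2(big)
  expect_equal(unname(unlist(res28[res28$effect == "A:B",
                                   c("df_num", "df_den")])), c(8, 216))
  flat <- rmAnova2(array(5, c(6, 2, 4)))
  expect_true(all(flat$F == 0))
  expect_error(rmAnova2(array(NA_real_, c(4, 2, 2))), "missing")
})

test_that("cluster permutation test recovers a constructed effect and is
           silent without one", {
  set.seed(24)
  n <- 12; nCh <- 16; nF <- 9
  A <- array(rnorm(n * nCh * nF), c(n, nCh, nF))
  res0 <- clusterPermutationTest(A, A, adj16, n_perm = 100, seed = 1)
  expect_length(clusters(res0), 0)
  B <- array(rnorm(n * nCh * nF), c(n, nCh, nF))
  deg <- colSums(adj16)
  ctr <- which.max(deg)
  grp <- c(ctr, which(adj16[ctr, ]))[1:4]
  A2 <- A
  A2[, grp, 3:5] <- A2[, grp, 3:5] + 5
  res <- clusterPermutationTest(A2, B, adj16, n_perm = 500, seed = 7)
  expect_gte(length(clusters(res)), 1)
  top <- clusters(res)[[1]]
  injected <- paste(rep(grp, 3), rep(3:5, each = 4))
  expect_true(all(injected %in% paste(top$channel, top$freq)))
  expect_equal(clusterPvalues(res)[1], 1 / 501, tolerance = 1e-12)
  expect_true(clusterPvalues(res)[1] <= 0.025)
  # membership against an independent connected-components oracle
  tmap <- res@tmap
  thr <- qt(1 - 0.05 / 2, n - 1)
  supra <- which(tmap > thr, arr.ind = TRUE)
  g <- igraph::make_empty_graph(nrow(supra), directed = FALSE)
  for (i in seq_len(nrow(supra))) for (j in seq_len(nrow(supra))) {
    if (i < j) {
      sameF <- supra[i, 2] == supra[j, 2]
      sameC <- supra[i, 1] == supra[j, 1]
      if ((sameF && adj16[supra[i, 1], supra[j, 1]]) ||
          (sameC && abs(supra[i, 2] - supra[j, 2]) == 1))
        g <- igraph::add_edges(g, c(i, j))
    }
  }
  comp <- igraph::components(g)
  sizes <- sort(table(comp$membership), decreasing = TRUE)
  expect_equal(nrow(top), unname(sizes[1]))
})

test_that("cluster test permutation machinery is seeded and sane", {
  set.seed(25)
  n <- 10
  A <- array(rnorm(n * 8 * 5), c(n, 8, 5))
  B <- array(rnorm(n * 8 * 5), c(n, 8, 5))
  A[, 1:4, 2:3] <- A[, 1:4, 2:3] + 3
  adj <- channelNeighbours(lay8, 1.0)
  r1 <- clusterPermutationTest(A, B, adj, n_perm = 200, seed = 9)
  r2 <- clusterPermutationTest(A, B, adj, n_perm = 200, seed = 9)
  expect_identical(clusterPvalues(r1), clusterPvalues(r2))
  expect_true(all(clusterPvalues(r1) > 0 & clusterPvalues(r1) <= 1))
  # p monotone in |mass|
  if (length(clusters(r1)) > 1) {
    o <- order(-abs(r1@mass))
    expect_true(all(diff(clusterPvalues(r1)[o]) >= 0))
  }
  # observed statistics invariant under unit reordering
  perm <- sample(n)
  r3 <- clusterPermutationTest(A[perm, , ], B[perm, , ], adj,
                               n_perm = 200, seed = 9)
  expect_equal(r3@tmap, r1@tmap, tolerance = 1e-12)
  expect_identical(lapply(clusters(r3), `[[`, "channel"),
                   lapply(clusters(r1), `[[`, "channel"))
  expect_equal(r3@mass, r1@mass, tolerance = 1e-12)
})

test_that("minimum channel extent discards narrow clusters", {
  set.seed(26)
  n <- 10
  A <- array(rnorm(n * 8 * 5, sd = 0.1), c(n, 8, 5))
  B <- array(rnorm(n * 8 * 5, sd = 0.1), c(n, 8, 5))
  A[, 2, 1:5] <- A[, 2, 1:5] + 5           # strong but single-channel
  adj <- channelNeighbours(lay8, 1.0)
  res <- clusterPermutationTest(A, B, adj, n_perm = 100,
                                min_channel_extent = 3, seed = 2)
  expect_length(clusters(res), 0)
  res1 <- clusterPermutationTest(A, B, adj, n_perm = 100,
                                 min_channel_extent = 1, seed = 2)
  expect_gte(length(clusters(res1)), 1)
})
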