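test_that("tSNR arithmetic, scale invariance and sampling behaviour", {
  d <- c(8, 8, 6)
  mask <- array(TRUE, d)
  set.seed(3)
  nt <- 500
  # every voxel: mean 100, alternating +/-2 -> sd 2.002 (exact sd formula)
  base <- array(100, c(d, nt))
  base <- sweep(base, 4, rep(c(-2, 2), nt / 2), "+")
  run <- FmriRun(base, 0.78)
  expect_equal(computeTSNR(run, mask)$tsnr, 100 / sd(rep(c(-2, 2), nt / 2)),
               tolerance = 1e-9)
  # invariant to doubling
  run2 <- FmriRun(runData(run) * 2, 0.78)
  expect_equal(computeTSNR(run2, mask)$tsnr, computeTSNR(run, mask)$tsnr)
  # white noise sd 10 around mean 200: tSNR concentrates near 20
  arr <- array(rnorm(prod(d) * nt, 200, 10), c(d, nt))
  ts <- computeTSNR(FmriRun(arr, 0.78), mask)$tsnr
  expect_gt(ts, 19); expect_lt(ts, 21)
  # global mode and the all-constant error
  expect_equal(computeTSNR(run, mask, mode = "global")$tsnr,
               100 / sd(rep(c(-2, 2), nt / 2)), tolerance = 1e-9)
  const <- FmriRun(array(5, c(d, 10)), 0.78)
  expect_error(computeTSNR(const, mask), "constant")
})

test_that("parcel time series equal the brute-force voxel average", {
  d <- c(10, 10, 6)
  lab <- array(0L, d)
  lab[1:3, 1:3, 1] <- 1L          # 9 voxels
  lab[5:9, 5:9, 2:3] <- 2L        # 50 voxels
  lab[1:2, 9:10, 6] <- 3L         # 4 voxels -> dropped at min 5
  set.seed(11)
  arr <- array(rnorm(prod(d) * 20, 100, 10), c(d, 20))
  run <- FmriRun(arr, 0.78)
  pts <- parcelTimeseries(run, lab, minVoxels = 5)
  expect_equal(pts$keptNodes, c(1L, 2L))
  expect_equal(pts$droppedNodes, 3L)
  # brute force with explicit loops
  for (k in 1:2) {
    idx <- which(lab == k, arr.ind = TRUE)
    brute <- vapply(1:20, function(t)
      mean(vapply(seq_len(nrow(idx)), function(r)
        arr[idx[r, 1], idx[r, 2], idx[r, 3], t], numeric(1))), numeric(1))
    expect_lt(max(abs(pts$series[, as.character(k)] - brute)), 1e-9)
  }
  # a parcel of identical voxel timecourses returns that timecourse
  tc <- rnorm(20)
  arr2 <- array(0, c(d, 20))
  for (t in 1:20) arr2[, , , t][lab == 1] <- tc[t]
  expect_equal(unname(parcelTimeseries(FmriRun(arr2, 0.78), lab)$series[, "1"]),
               tc)
})

test_that("connectivity matrices are exact on toy node sets", {
  set.seed(13)
  a <- rnorm(50)
  series <- cbind(a, -a, rnorm(50), rnorm(50), a + rnorm(50, sd = 0.5))
  cent <- matrix(rnorm(15, sd = 20), 5, 3)
  cm <- connectivityMatrix(series, cent)
  expect_equal(cm@mat[1, 2], -1)
  expect_equal(cm@mat[1, 1], 1)
  expect_true(isSymmetric(cm@mat))
  expect_length(edgeValues(cm), 5 * 4 / 2)
  # brute-force pairwise loop oracle
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(abs(cm@mat[i, j] - cor(series[, i], series[, j])), 1e-12)
  # distances are centroid Euclidean
  expect_equal(cm@distances[1, 2], sqrt(sum((cent[1, ] - cent[2, ])^2)))
  # constant node -> NA edges with a warning
  expect_warning(cm2 <- connectivityMatrix(cbind(a, rep(1, 50)), cent[1:2, ]),
                 "constant")
  expect_true(is.na(cm2@mat[1, 2]))
})

test_that("edge-wise QC-FD statistics are calibrated and exact", {
  set.seed(17)
  n <- 30; ne <- 200
  fd <- runif(n, 0.1, 0.6)
  edges <- matrix(rnorm(n * ne), n, ne)
  dist <- runif(ne, 10, 80)
  res <- qcfdEdges(edges, fd, dist)
  band <- 2.576 * sqrt(0.05 * 0.95 / ne)
  expect_gte(res$proportionSignificant, 0.05 - band)
  expect_lte(res$proportionSignificant, 0.05 + band)
  # a perfectly linear edge: r = 1, p ~ 0
  edges[, 1] <- 0.2 + 3 * fd
  res2 <- qcfdEdges(edges, fd, dist)
  expect_equal(res2$edgeR[1], 1)
  expect_lt(res2$edgeP[1], 1e-20)
  # p-values match cor.test
  ct <- cor.test(edges[, 2], fd)
  expect_equal(res2$edgeP[2], ct$p.value, tolerance = 1e-10)
  expect_equal(res2$edgeR[2], unname(ct$estimate), tolerance = 1e-12)
  # lowess profile covers the edges
  expect_length(res2$lowessFit$x, ne)
  expect_error(qcfdEdges(edges, rep(0.3, n), dist), "zero variance")
})

test_that("tSNR-FD correlation is exact and calibrated under the null", {
  qc <- data.frame(meanFd = runif(30, 0.1, 0.5))
  qc$tsnrPre <- 80 - 50 * qc$meanFd
  qc$tsnrPost <- rnorm(30, 70, 5)
  res <- tsnrFdCorrelation(qc, "pre")
  expect_equal(res$r, -1)
  # null: |r| < 0.3 in at least 95 % of seeds at n = 100
  hits <- vapply(1:40, function(s) {
    set.seed(200 + s)
    qc0 <- data.frame(meanFd = runif(100, 0.1, 0.5),
                      tsnrPre = rnorm(100, 60, 8), tsnrPost = rnorm(100, 70, 8))
    abs(tsnrFdCorrelation(qc0, "pre")$r) < 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("DVARS-FD regression recovers exact and null relations", {
  set.seed(23)
  fd <- c(0, abs(rnorm(499, 0.3, 0.2)))
  pairs <- list(list(fd = fd, dvars = 2 * fd + 1))
  res <- dvarsFdRegression(pairs)
  expect_equal(res$perSubject$slope[1], 2, tolerance = 1e-9)
  expect_equal(res$perSubject$intercept[1], 1, tolerance = 1e-9)
  expect_equal(res$perSubject$r2[1], 1, tolerance = 1e-9)
  expect_equal(res$pooled$slope, 2, tolerance = 1e-9)
  # independent DVARS: r2 < 0.02 in >= 95 % of seeds
  hits <- vapply(1:40, function(s) {
    set.seed(300 + s)
    f <- c(0, abs(rnorm(499, 0.3, 0.2)))
    d <- c(0, abs(rnorm(499, 5, 1)))
    dvarsFdRegression(list(list(fd = f, dvars = d)))$pooled$r2 < 0.02
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # constant-FD subject is skipped with a warning, pooled still reported
  expect_warning(res3 <- dvarsFdRegression(list(
    list(fd = fd, dvars = 2 * fd + 1),
    list(fd = rep(0.2, 500), dvars = rnorm(500, 5)))), "constant FD")
  expect_true(is.na(res3$perSubject$slope[2]))
  expect_false(is.na(res3$pooled$r2))
})

test_that("group FD statistics recover a planted offset and stay null-calibrated", {
  set.seed(29)
  qc <- data.frame(meanFd = c(rnorm(50, 0.40, 0.1), rnorm(50, 0.48, 0.1)),
                   group = rep(c("A", "B"), each = 50),
                   age = runif(100, 6, 8))
  res <- groupFdStats(qc, covariate = "age")
  expect_gte(res$difference, 0.05)
  expect_lte(res$difference, 0.11)
  expect_lt(res$test$p.value, 0.05)
  # age was independent of FD
  expect_lt(abs(res$covariate$r), 0.3)
  # identical groups: p roughly uniform (few rejections across seeds)
  rej <- vapply(1:30, function(s) {
    set.seed(400 + s)
    qc0 <- data.frame(meanFd = rnorm(40, 0.4, 0.1),
                      group = rep(c("A", "B"), each = 20))
    groupFdStats(qc0)$test$p.value < 0.05
  }, logical(1))
  expect_lte(sum(rej), 5)
  expect_error(groupFdStats(data.frame(meanFd = 1:4, group = c("A", "A", "A", "B"))),
               "at least 3")
})
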