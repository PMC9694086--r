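msMask3 <- function(d) array(TRUE, d)

test_that("intensity normalization scales each frame to the target mean", {
  d <- c(6, 6, 4)
  run <- msStackRun(list(array(500, d), array(2000, d)))
  out <- normalizeIntensity(run, msMask3(d), target = 10000)
  expect_equal(mean(runData(out)[, , , 1]), 10000)
  expect_equal(mean(runData(out)[, , , 2]), 10000)
  expect_equal(runData(out)[1, 1, 1, 1], 500 * 20)
  # idempotent, and invariant to a global x3
  out2 <- normalizeIntensity(out, msMask3(d))
  expect_equal(runData(out2), runData(out), tolerance = 1e-9)
  run3 <- FmriRun(runData(run) * 3, tr = 0.78)
  expect_equal(runData(normalizeIntensity(run3, msMask3(d))), runData(out),
               tolerance = 1e-9)
  # non-positive in-mask mean is an error
  bad <- msStackRun(list(array(500, d), array(-1, d)))
  expect_error(normalizeIntensity(bad, msMask3(d)), "non-positive")
})

# two disjoint sparse blobs with distinct smooth timecourses: an exactly
# rank-2 dataset whose spatial sources are independent (super-Gaussian)
msPlantedICA <- function(noiseSd = 0.05, nFrames = 120, seed = 55) {
  set.seed(seed)
  d <- c(12, 12, 8)
  m1 <- array(0, d); m1[2:4, 2:4, 2:4] <- 1
  m2 <- array(0, d); m2[8:11, 8:11, 5:7] <- 1
  tt <- seq_len(nFrames) * 0.78
  t1 <- as.numeric(scale(sin(2 * pi * 0.03 * tt)))
  t2 <- as.numeric(scale(sin(2 * pi * 0.07 * tt + 1) +
                         0.4 * sin(2 * pi * 0.02 * tt)))
  arr <- array(100, c(d, nFrames))
  for (t in seq_len(nFrames))
    arr[, , , t] <- arr[, , , t] + 5 * m1 * t1[t] + 5 * m2 * t2[t] +
      array(rnorm(prod(d), 0, noiseSd), d)
  list(run = FmriRun(arr, 0.78), mask = msMask3(d), t1 = t1, t2 = t2)
}

test_that("spatial ICA recovers planted components and is deterministic", {
  p <- msPlantedICA()
  cs <- decomposeICA(p$run, p$mask, nComponents = 4, seed = 3)
  expect_true(cs@converged)
  cc <- abs(cor(cs@timecourses, cbind(p$t1, p$t2)))
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  # unit-variance timecourse convention
  expect_equal(apply(cs@timecourses, 2, sd), rep(1, 4), tolerance = 1e-8)
  # same seed twice: identical decomposition
  cs2 <- decomposeICA(p$run, p$mask, nComponents = 4, seed = 3)
  expect_identical(cs@maps, cs2@maps)
  expect_identical(cs@timecourses, cs2@timecourses)
  # contract: model order must be below the frame count
  expect_error(decomposeICA(p$run, p$mask, nComponents = 120), "frame count")
})

test_that("components plus residual reconstruct the data", {
  p <- msPlantedICA(noiseSd = 0)
  cs <- decomposeICA(p$run, p$mask, nComponents = 2, seed = 3)
  nt <- nFrames(p$run)
  X <- t(matrix(runData(p$run), ncol = nt)[cs@maskIndex, ])
  Xc <- X - rep(colMeans(X), each = nt)
  recon <- cs@timecourses %*% t(cs@maps)
  expect_equal(recon, Xc, tolerance = 1e-6, ignore_attr = TRUE)
})

# directly-constructed component sets let feature tests use exact geometry
msComponentSet <- function(tpl, maps, tcs) {
  tcs <- apply(tcs, 2, function(x) x / sd(x))
  new("ComponentSet", maps = maps, timecourses = tcs,
      maskIndex = as.integer(which(tpl@brainMask)),
      dimVol = as.integer(dim(tpl@brainMask)),
      explainedVariance = rep(1 / ncol(maps), ncol(maps)), converged = TRUE)
}

test_that("component features read out planted spatial structure", {
  tpl <- msTemplate()
  nvox <- sum(tpl@brainMask)
  nt <- 200
  tt <- seq_len(nt) * 0.78
  lowTc <- sin(2 * pi * 0.03 * tt)
  rimMap <- as.numeric(rimMask(tpl)[tpl@brainMask])
  gmMap <- as.numeric(tpl@gmMask[tpl@brainMask])
  slcMap <- as.numeric(motionscrub:::.sliceMask(tpl, 4)[tpl@brainMask])
  cs <- msComponentSet(tpl, cbind(rimMap, gmMap, slcMap),
                       cbind(lowTc, lowTc, lowTc))
  fe <- extractComponentFeatures(cs, tpl, tr = 0.78)
  # rim-ring map: edge mass dominates, grey matter nearly absent
  expect_gt(fe$edgeFraction[1], 0.5)
  expect_lt(fe$gmOverlap[1], 0.2)
  # grey-matter map: the converse
  expect_gt(fe$gmOverlap[2], 0.9)
  expect_lt(fe$edgeFraction[2], 0.1)
  # every-4th-slice map: the period-4 bin is the largest off-DC peak
  d <- dim(tpl@brainMask)
  prof <- vapply(seq_len(d[3]), function(z)
    mean(abs(slcMap)[arrayInd(which(tpl@brainMask), d)[, 3] == z]), numeric(1))
  prof[is.na(prof)] <- 0
  pz <- Mod(fft(prof - mean(prof)))^2
  half <- 2:(floor(d[3] / 2) + 1)
  expect_equal(which.max(pz[half]), which(half == d[3] / 4 + 1))
  expect_gt(fe$slicePeriodicity[3], fe$slicePeriodicity[1])
  expect_gt(fe$slicePeriodicity[3], 0.3)  # above the classifier threshold
  # 0.03 Hz sinusoid has essentially no power above 0.1 Hz
  expect_lt(fe$highfreqFraction[1], 0.05)
})

test_that("temporal features separate low-frequency, high-frequency and jumps", {
  tpl <- msSmallTemplate()
  nvox <- sum(tpl@brainMask)
  nt <- 200
  set.seed(5)
  hfTc <- rnorm(nt)                       # white: mostly > 0.1 Hz at TR 0.78
  jumpTc <- sin(2 * pi * 0.02 * (1:nt)); jumpTc[100:nt] <- jumpTc[100:nt] + 6
  maps <- matrix(rnorm(nvox * 2), nvox)
  cs <- msComponentSet(tpl, maps, cbind(hfTc, jumpTc))
  fe <- extractComponentFeatures(cs, tpl, tr = 0.78)
  expect_gt(fe$highfreqFraction[1], 0.5)
  expect_gt(fe$jumpScore[2], 6)
  expect_lt(fe$highfreqFraction[2], 0.5)
})

test_that("classification rules fire as configured", {
  base <- data.frame(component = 1:5, edgeFraction = 0, gmOverlap = 0,
                     highfreqFraction = 0, slicePeriodicity = 0, jumpScore = 0)
  base$edgeFraction[2] <- 0.5
  base$slicePeriodicity[3] <- 0.4
  base$highfreqFraction[4] <- 0.8
  base$jumpScore[5] <- 10; base$gmOverlap[5] <- 0.9
  la <- classifyComponents(base)
  expect_equal(la$label, c("signal", "noise", "noise", "noise", "signal"))
  expect_equal(la$ruleTrace[1], "none")
  expect_equal(la$ruleTrace[2], "edge")
  expect_equal(la$ruleTrace[5], "gm-override")
})

test_that("aggressive cleanup regresses noise exactly and only noise", {
  tpl <- msSmallTemplate()
  nvox <- sum(tpl@brainMask)
  d <- dim(tpl@brainMask)
  nt <- 60
  set.seed(9)
  noiseTc <- as.numeric(scale(cumsum(rnorm(nt))))
  blob <- as.numeric(seq_len(nvox) <= 50)
  arr <- array(100, c(d, nt))
  idx <- which(tpl@brainMask)
  for (t in seq_len(nt))
    arr[, , , t][idx] <- 100 + 8 * blob * noiseTc[t]
  run <- FmriRun(arr, 0.78)
  cs <- msComponentSet(tpl, cbind(blob, rnorm(nvox)),
                       cbind(noiseTc, rnorm(nt)))
  labs <- data.frame(component = 1:2, label = c("noise", "signal"))
  cleaned <- aggressiveCleanup(run, cs, labs)
  # the data were exactly the noise timecourse on a blob: cleaning leaves a
  # temporally constant volume
  sds <- apply(matrix(runData(cleaned), ncol = nt)[idx, ], 1, sd)
  expect_lt(max(sds), 1e-9)
  # no noise components labeled -> identity
  labs0 <- data.frame(component = 1:2, label = c("signal", "signal"))
  expect_identical(runData(aggressiveCleanup(run, cs, labs0)), runData(run))
  # collinear noise columns are dropped with a warning
  cs2 <- msComponentSet(tpl, cbind(blob, blob), cbind(noiseTc, noiseTc))
  labs2 <- data.frame(component = 1:2, label = c("noise", "noise"))
  expect_warning(aggressiveCleanup(run, cs2, labs2), "collinear")
})

test_that("cleanup residuals are orthogonal and variance never increases", {
  sub <- msRenderedSubject()
  tpl <- sub$template
  run <- normalizeIntensity(sub$run, tpl@brainMask)
  cs <- suppressWarnings(decomposeICA(run, tpl@brainMask, nComponents = 20,
                                      seed = 77))
  fe <- extractComponentFeatures(cs, tpl, tr = 0.78)
  la <- classifyComponents(fe)
  expect_gt(sum(la$label == "noise"), 0)
  cleaned <- aggressiveCleanup(run, cs, la)
  nt <- nFrames(run)
  idx <- cs@maskIndex
  Y0 <- t(matrix(runData(run), ncol = nt)[idx, ])
  Y1 <- t(matrix(runData(cleaned), ncol = nt)[idx, ])
  N <- cs@timecourses[, la$label == "noise", drop = FALSE]
  someVox <- seq(1, ncol(Y1), by = 17)
  expect_lt(max(abs(cor(Y1[, someVox], N))), 1e-8)
  v0 <- apply(Y0, 2, var); v1 <- apply(Y1, 2, var)
  expect_true(all(v1 <= v0 + 1e-9))
})
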