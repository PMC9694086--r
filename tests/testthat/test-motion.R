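test_that("FD follows the displacement-sum formula on hand cases", {
  # single 0.2 mm translation step
  p <- matrix(0, 4, 6); p[2:4, 4] <- 0.2
  fd <- computeFD(MotionTrace(p, tr = 0.78))
  expect_equal(fdValues(fd), c(0, 0.2, 0, 0))
  # single 0.01 rad rotation step at 50 mm radius -> 0.5 mm
  p <- matrix(0, 2, 6); p[2, 3] <- 0.01
  expect_equal(fdValues(computeFD(MotionTrace(p, 0.78), rotationRadius = 50)),
               c(0, 0.5))
  # constant parameters -> all zero
  p <- matrix(rep(c(0.01, -0.02, 0.005, 1, 2, -1), each = 5), 5, 6)
  expect_equal(fdValues(computeFD(MotionTrace(p, 0.78))), rep(0, 5))
  # mixed step: sum of all six contributions
  p <- matrix(0, 2, 6); p[2, ] <- c(0.002, -0.001, 0.003, 0.1, -0.2, 0.05)
  expect_equal(fdValues(computeFD(MotionTrace(p, 0.78)))[2],
               0.1 + 0.2 + 0.05 + 50 * (0.002 + 0.001 + 0.003))
})

test_that("FD is invariant to a constant parameter offset", {
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(rnorm(60, sd = 0.3), 10, 6)
    off <- rnorm(6)
    f1 <- fdValues(computeFD(MotionTrace(p, 0.78)))
    f2 <- fdValues(computeFD(MotionTrace(sweep(p, 2, -off), 0.78)))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("generator FD bookkeeping matches computeFD to 1e-9", {
  for (sd in c(2, 17, 91)) {
    trc <- simulateMotionTrace(250, 0.78, targetMeanFd = 0.5, seed = sd)
    expect_lt(max(abs(attr(trc, "fd") - fdValues(computeFD(trc)))), 1e-9)
  }
})

test_that("DVARS matches a brute-force voxel loop on random grids", {
  bruteDvars <- function(arr, mask) {
    nt <- dim(arr)[4]
    out <- numeric(nt)
    idx <- which(mask, arr.ind = TRUE)
    for (t in 2:nt) {
      acc <- 0
      for (r in seq_len(nrow(idx))) {
        d <- arr[idx[r, 1], idx[r, 2], idx[r, 3], t] -
             arr[idx[r, 1], idx[r, 2], idx[r, 3], t - 1]
        acc <- acc + d * d
      }
      out[t] <- sqrt(acc / nrow(idx))
    }
    out
  }
  set.seed(7)
  for (i in 1:3) {
    arr <- array(rnorm(8 * 8 * 8 * 5, 100, 10), c(8, 8, 8, 5))
    mask <- array(runif(512) < 0.6, c(8, 8, 8))
    dv <- dvarsValues(computeDVARS(FmriRun(arr, 0.78), mask))
    expect_lt(max(abs(dv - bruteDvars(arr, mask))), 1e-9)
  }
})

test_that("DVARS degenerate cases", {
  v <- array(rnorm(4^3, 100, 5), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  run <- msStackRun(list(v, v))
  expect_equal(dvarsValues(computeDVARS(run, mask)), c(0, 0))
  run2 <- msStackRun(list(v, v + 3))
  expect_equal(dvarsValues(computeDVARS(run2, mask)), c(0, 3))
  expect_error(computeDVARS(run, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("good-time accumulation uses a strict threshold and tr seconds", {
  fd <- new("FDSeries", fd = c(0, 0.1, 0.5, 0.2), rotationRadius = 50, tr = 0.78)
  rep <- accumulateGoodTime(fd, threshold = 0.4, target = 240)
  expect_equal(rep$goodFrames, 3L)
  expect_equal(rep$goodSeconds, 3 * 0.78)
  expect_false(rep$targetMet)
  # boundary is exclusive: fd == threshold does not count
  fd2 <- new("FDSeries", fd = c(0, rep(0.4, 5)), rotationRadius = 50, tr = 0.78)
  expect_equal(accumulateGoodTime(fd2, 0.4)$goodFrames, 1L)
  # 308 good frames at tr 0.78 -> 240.24 s, target met
  fd3 <- new("FDSeries", fd = rep(0, 308), rotationRadius = 50, tr = 0.78)
  rep3 <- accumulateGoodTime(fd3, 0.4, target = 240)
  expect_equal(rep3$goodSeconds, 240.24)
  expect_true(rep3$targetMet)
})

test_that("good-time is monotonically nondecreasing in the threshold", {
  set.seed(11)
  fd <- new("FDSeries", fd = c(0, abs(rnorm(99, 0.3, 0.3))),
            rotationRadius = 50, tr = 0.78)
  secs <- vapply(seq(0.1, 1, by = 0.1),
                 function(th) accumulateGoodTime(fd, th)$goodSeconds,
                 numeric(1))
  expect_true(all(diff(secs) >= 0))
})

test_that("applying an all-zero trace is the identity", {
  sub <- msRenderedSubject()
  run <- sub$run[1:3]
  tr0 <- MotionTrace(matrix(0, 3, 6), tr = 0.78)
  expect_identical(runData(applyRigidMotion(run, tr0)), runData(run))
  expect_error(applyRigidMotion(run, MotionTrace(matrix(0, 2, 6), 0.78)),
               "length")
})

test_that("apply then invert round-trips within interpolation loss", {
  tpl <- msTemplate()
  run <- FmriRun(array(tpl@intensity, c(dim(tpl@intensity), 1)), tr = 0.78)
  tr <- MotionTrace(matrix(c(0.01, -0.008, 0.015, 1.0, -0.5, 0.25), 1, 6), 0.78)
  back <- applyRigidMotion(applyRigidMotion(run, tr), tr, invert = TRUE)
  rms <- sqrt(mean((runData(back)[, , , 1][tpl@brainMask] -
                    tpl@intensity[tpl@brainMask])^2))
  expect_lt(rms, 0.03 * quantile(tpl@intensity, 0.99))
})

test_that("rigid motion estimation recovers planted parameters", {
  tpl <- msTemplate()
  v <- tpl@intensity
  truth <- rbind(c(0, 0, 0, 1.0, -0.5, 0.25),
                 c(0, 0, 0.02, 0, 0, 0),
                 c(0.015, -0.01, 0.02, 0.8, 1.2, -0.6))
  vols <- c(list(v), lapply(seq_len(nrow(truth)), function(t)
    array(motionscrub:::.resampleVolume(v, truth[t, ], tpl@voxelSize),
          dim(v))))
  run <- msStackRun(vols)
  est <- estimateRigidMotion(run, tpl@brainMask, coarse = FALSE)
  err <- motionParams(est)[-1, ] - truth
  expect_lt(max(abs(err[, 1:3])), 0.005)   # rotations, rad
  expect_lt(max(abs(err[, 4:6])), 0.25)    # translations, mm
  expect_equal(motionParams(est)[1, ], rep(0, 6), ignore_attr = TRUE)
})

test_that("motion correction removes >= 80 % of frame-to-reference RMS", {
  tpl <- msTemplate()
  # motion-dominated frames (several mm / several hundredths rad): below
  # that, the residual is the trilinear interpolation floor, not misfit
  p <- rbind(0,
             c(0.02, -0.01, 0.03, 3.0, -2.0, 1.5),
             c(0.03, 0.02, -0.02, -4.0, 2.5, -2.0),
             c(0.01, 0.04, 0.02, 2.0, 4.0, -1.0),
             c(-0.03, 0.01, -0.04, -3.0, -3.0, 2.0))
  trc <- MotionTrace(p, tr = 0.78)
  truth <- makeGroundTruth(tpl, list(trc), seed = 32, noiseSd = 0,
                           netAmp = 0, rimAmp = 0, sliceAmp = 0,
                           spinHistorySd = 0)
  run <- renderRun(tpl, truth, run = 1, seed = 33)
  est <- estimateRigidMotion(run, tpl@brainMask)
  corr <- applyRigidMotion(run, est, invert = TRUE)
  idx <- which(tpl@brainMask)
  ref <- as.numeric(runData(run)[, , , 1])[idx]
  rms <- function(r) sqrt(mean(vapply(2:nFrames(r), function(t)
    mean((as.numeric(runData(r)[, , , t])[idx] - ref)^2), numeric(1))))
  expect_lt(rms(corr), 0.2 * rms(run))
})
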