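msToyRun <- function(nFrames, value = 1000, dim3 = c(6, 6, 4), tr = 0.78) {
  FmriRun(array(value, c(dim3, nFrames)), tr = tr)
}

test_that("dummy discard removes exactly the first frames", {
  run <- msToyRun(300)
  trc <- MotionTrace(matrix(rnorm(300 * 6, sd = 0.1), 300, 6), 0.78)
  out <- discardDummies(run, trc, 3)
  expect_equal(nFrames(out$run), 297L)
  expect_equal(motionParams(out$trace), motionParams(trc)[-(1:3), ],
               ignore_attr = TRUE)
  # n_dummy 0 is the identity
  out0 <- discardDummies(run, trc, 0)
  expect_identical(runData(out0$run), runData(run))
  # a 3-frame run cannot lose 3 dummies
  expect_error(discardDummies(msToyRun(3), MotionTrace(matrix(0, 3, 6), 0.78), 3),
               "too short")
})

test_that("FD censoring keeps boundary frames and imposes no segment rule", {
  keep <- censorByFD(c(0, .1, .5, .2, .6), threshold = 0.4)
  expect_equal(which(keep), c(1L, 2L, 4L))
  expect_true(all(censorByFD(c(0, .1, .2), 0.2)))    # threshold == max kept
  # single surviving frames survive by default; minSegment drops them
  fd <- c(0, 1, 0.1, 1, 0.1, 0.1, 1)
  expect_equal(which(censorByFD(fd, 0.4)), c(1L, 3L, 5L, 6L))
  expect_equal(which(censorByFD(fd, 0.4, minSegment = 2L)), c(5L, 6L))
})

test_that("censor keep-sets nest across thresholds", {
  set.seed(13)
  for (i in 1:100) {
    fd <- c(0, abs(rnorm(149, 0.3, 0.25)))
    k1 <- censorByFD(fd, 0.25); k2 <- censorByFD(fd, 0.3)
    k3 <- censorByFD(fd, 0.4);  k4 <- censorByFD(fd, 0.5)
    expect_true(all(k1 <= k2) && all(k2 <= k3) && all(k3 <= k4))
  }
})

test_that("concatenation preserves acquisition order and provenance", {
  r1 <- msToyRun(120); r2 <- msToyRun(60)
  # give each frame a recognisable value
  r1@data[1, 1, 1, ] <- 1:120; r2@data[1, 1, 1, ] <- 1000 + 1:60
  k1 <- rep(c(TRUE, FALSE), 60)[1:120]; k1[1:40] <- TRUE   # 100 kept
  k2 <- rep(TRUE, 60); k2[1:10] <- FALSE                   # 50 kept
  out <- concatenateRuns(list(r1, r2), list(k1, k2))
  expect_equal(nFrames(out$run), sum(k1) + sum(k2))
  expect_equal(out$plan@runBoundaries, c(1L, sum(k1) + 1L))
  tab <- planTable(out$plan)
  expect_equal(nrow(tab), 180L)
  expect_equal(sum(tab$kept), sum(k1) + sum(k2))
  # the concatenated frames are the kept source frames, in order
  expect_equal(runData(out$run)[1, 1, 1, ],
               c((1:120)[k1], (1000 + 1:60)[k2]))
  # identity on one fully-kept run
  one <- concatenateRuns(list(r1))
  expect_identical(runData(one$run), runData(r1))
  # tr mismatch is a contract violation
  r3 <- msToyRun(60, tr = 1.0)
  expect_error(concatenateRuns(list(r1, r3)), "TR")
})

test_that("censor-then-concatenate bookkeeping is grouping-invariant", {
  set.seed(17)
  runs <- lapply(c(40, 30, 50), msToyRun)
  fds <- lapply(runs, function(r) c(0, abs(rnorm(nFrames(r) - 1, 0.3, 0.2))))
  keeps <- lapply(fds, censorByFD, threshold = 0.3)
  whole <- concatenateRuns(runs, keeps)
  # concatenating (1,2) then appending 3 flags the same acquisition frames
  part <- concatenateRuns(runs[1:2], keeps[1:2])
  tabW <- planTable(whole$plan)
  tabP <- planTable(part$plan)
  expect_equal(tabW$kept[tabW$sourceRun <= 2], tabP$kept)
  expect_equal(tabW$sourceFrame[tabW$sourceRun <= 2], tabP$sourceFrame)
})

test_that("FOV outliers follow the z-score rule on brain-voxel counts", {
  # cuboid "brain" whose voxel count is controlled exactly per frame
  mkFrame <- function(n) {
    v <- array(0, c(12, 12, 8))
    v[seq_len(n)] <- 1000
    v
  }
  counts <- c(rep(500, 20), rep(520, 19), 200)  # last frame far out
  run <- msStackRun(lapply(counts, mkFrame))
  det <- detectFovOutliers(run, zCut = 4)
  expect_equal(det$counts, counts)
  expect_equal(which(det$outlier),
               which(abs(counts - mean(counts)) > 4 * sd(counts)))
  expect_equal(which(det$outlier), 40L)
  # a frame at 3.9 SD is not flagged at zCut 4
  c2 <- c(rep(c(490, 510), 20))
  c2 <- c(c2, round(mean(c2) - 3.9 * sd(c(c2, mean(c2)))))
  run2 <- msStackRun(lapply(c2, mkFrame))
  det2 <- detectFovOutliers(run2, zCut = 4)
  expect_equal(which(det2$outlier),
               which(abs(c2 - mean(c2)) > 4 * sd(c2)))
  # identical frames: sd 0 path warns, flags nothing
  run3 <- msStackRun(lapply(rep(500, 10), mkFrame))
  expect_warning(det3 <- detectFovOutliers(run3), "equal")
  expect_false(any(det3$outlier))
})

test_that("planted dropout frames are the only FOV outliers", {
  tpl <- msTemplate()
  trc <- simulateMotionTrace(80, 0.78, targetMeanFd = 0.3, seed = 41)
  truth <- makeGroundTruth(tpl, list(trc), seed = 42,
                           dropoutFrames = list(c(25L, 60L)))
  run <- renderRun(tpl, truth, run = 1, seed = 43)
  det <- detectFovOutliers(run, zCut = 4)
  expect_equal(which(det$outlier), c(25L, 60L))
  # the dropout frame loses >= 25 % of its brain voxels
  expect_lt(det$counts[25], 0.75 * mean(det$counts[-c(25, 60)]))
})

test_that("trim keeps floor(duration/tr) frames and is idempotent", {
  r1 <- msToyRun(400)
  out <- concatenateRuns(list(r1))
  tr1 <- trimToDuration(out$run, out$plan, duration = 240)
  expect_equal(nFrames(tr1$run), 307L)  # floor(240 / 0.78)
  tab <- planTable(tr1$plan)
  expect_equal(sum(tab$reason == "trim"), 400L - 307L)
  # idempotent
  tr2 <- trimToDuration(tr1$run, tr1$plan, duration = 240)
  expect_identical(runData(tr2$run), runData(tr1$run))
  expect_identical(planTable(tr2$plan), planTable(tr1$plan))
  # tr = 1 s -> exactly 240 frames
  rA <- msToyRun(300, tr = 1.0)
  outA <- concatenateRuns(list(rA))
  expect_equal(nFrames(trimToDuration(outA$run, outA$plan, 240)$run), 240L)
  # 200 retained frames at tr 0.78 is 156 s < 240 s: the exclusion event
  rB <- msToyRun(200)
  outB <- concatenateRuns(list(rB))
  expect_error(trimToDuration(outB$run, outB$plan, 240),
               class = "msInsufficientData")
})

test_that("subject retention matches brute force and is monotone", {
  set.seed(19)
  fds <- lapply(1:12, function(i) c(0, abs(rnorm(499, runif(1, 0.1, 0.6), 0.2))))
  ths <- c(0.25, 0.3, 0.4, 0.5)
  ret <- subjectRetention(fds, ths, tr = 0.78, minDuration = 240)
  brute <- vapply(ths, function(th) sum(vapply(fds, function(f)
    sum(f <= th) * 0.78 >= 240, logical(1))), numeric(1))
  expect_equal(ret$nRetained, brute)
  expect_true(all(diff(ret$nRetained) >= 0))
  # all subjects below every threshold: full retention
  quiet <- lapply(1:5, function(i) rep(0.05, 500))
  expect_equal(subjectRetention(quiet, ths, tr = 0.78)$nRetained, rep(5, 4))
  # group counts sum to the total
  g <- rep(c("A", "B"), 6)
  retG <- subjectRetention(fds, ths, tr = 0.78, groups = g)
  expect_equal(retG$n_A + retG$n_B, retG$nRetained)
})
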