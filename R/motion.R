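#' Compute framewise displacement from a motion trace
#'
#' FD at frame t (t >= 2) is the sum of absolute changes of the three
#' translations plus \code{rotationRadius} times the sum of absolute changes
#' of the three rotations, i.e. rotations are converted to arc length on a
#' sphere approximating the head (50 mm by default). The first frame has
#' FD 0 by convention, so it is never censored by FD alone.
#'
#' @param trace a [MotionTrace-class].
#' @param rotationRadius sphere radius in mm.
#' @return An [FDSeries-class].
#' @examples
#' p <- matrix(0, 4, 6); p[2, 4] <- 0.2   # one 0.2 mm translation step
#' fdValues(computeFD(MotionTrace(p, tr = 0.78)))
#' @export
computeFD <- function(trace, rotationRadius = 50) {
  stopifnot(is(trace, "MotionTrace"))
  p <- trace@params
  if (!all(is.finite(p))) stop("motion parameters must be finite")
  if (nrow(p) == 1L) {
    fd <- 0
  } else {
    d <- abs(diff(p))
    fd <- c(0, rowSums(d[, 4:6, drop = FALSE]) +
                 rotationRadius * rowSums(d[, 1:3, drop = FALSE]))
  }
  new("FDSeries", fd = fd, rotationRadius = rotationRadius, tr = trace@tr)
}

#' Compute DVARS from a run
#'
#' DVARS at frame t is the root mean square, over the brain mask, of the
#' voxelwise intensity difference between frames t and t-1; the first frame
#' is 0 by convention.
#'
#' @param run an [FmriRun-class].
#' @param brainMask 3-D logical array.
#' @return A [DvarsSeries-class].
#' @export
computeDVARS <- function(run, brainMask) {
  stopifnot(is(run, "FmriRun"))
  idx <- which(brainMask)
  if (!length(idx)) stop("brain mask is empty")
  nt <- nFrames(run)
  if (nt < 2L) stop("need at least 2 frames")
  x <- matrix(run@data, ncol = nt)[idx, , drop = FALSE]
  dv <- c(0, sqrt(colMeans((x[, -1L, drop = FALSE] -
                            x[, -nt, drop = FALSE])^2)))
  new("DvarsSeries", dvars = dv, maskSize = length(idx))
}

#' Real-time good-frame accumulation report
#'
#' Emulates scan-time motion monitoring: counts frames whose FD is strictly
#' below \code{threshold}, converts to seconds of usable data, and reports
#' whether the session target has been met. The comparison is strict
#' ("less than"), matching the monitoring convention; note the censoring
#' step ([censorByFD()]) instead keeps frames with FD \code{<=} threshold.
#'
#' @param fd an [FDSeries-class].
#' @param threshold FD threshold in mm (default 0.4).
#' @param target required seconds of good data (default 240).
#' @return A list with \code{goodFrames}, \code{goodSeconds},
#'   \code{targetMet}.
#' @examples
#' fd <- new("FDSeries", fd = c(0, 0.1, 0.5, 0.2), rotationRadius = 50, tr = 0.78)
#' accumulateGoodTime(fd, threshold = 0.4, target = 240)
#' @export
accumulateGoodTime <- function(fd, threshold = 0.4, target = 240) {
  stopifnot(is(fd, "FDSeries"), threshold > 0)
  good <- sum(fd@fd < threshold)
  secs <- good * fd@tr
  list(goodFrames = good, goodSeconds = secs, targetMet = secs >= target)
}

#' Apply (or undo) rigid-body motion to every frame of a run
#'
#' Each frame is resampled under its own six-parameter rigid transform
#' (trilinear interpolation, zero outside the grid). With
#' \code{invert = TRUE} the inverse transform is applied, which is the
#' motion-correction direction: applying the inverse of an estimated trace
#' realigns frames to the reference.
#'
#' @param run an [FmriRun-class].
#' @param trace a [MotionTrace-class] with one row per frame.
#' @param invert apply the inverse transform.
#' @return A resampled [FmriRun-class]. Frames with all-zero parameters are
#'   copied untouched (exact identity).
#' @export
applyRigidMotion <- function(run, trace, invert = FALSE) {
  stopifnot(is(run, "FmriRun"), is(trace, "MotionTrace"))
  nt <- nFrames(run)
  if (nrow(trace@params) != nt)
    stop("trace length must equal the frame count")
  d <- dim(run@data)[1:3]
  out <- run@data
  for (t in seq_len(nt)) {
    p <- trace@params[t, ]
    if (all(p == 0)) next
    out[, , , t] <- .rigidResampleCpp(as.numeric(run@data[, , , t]),
                                      as.integer(d), as.numeric(p),
                                      run@voxelSize, isTRUE(invert))
  }
  FmriRun(out, tr = run@tr, voxelSize = run@voxelSize)
}

# FFT of a (wrapped) separable Gaussian kernel for fast 3-D smoothing.
.smoothKernelFFT <- function(d, sigma = 1.2) {
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  ker <- outer(outer(k1(d[1]), k1(d[2])), k1(d[3]))
  stats::fft(ker)
}

# Gaussian-smooth a 3-D volume by FFT convolution (circular boundaries;
# phantom intensities vanish near the grid edge so wrap-around is benign).
.smooth3d <- function(vol, kernelFFT) {
  Re(stats::fft(stats::fft(vol) * kernelFFT, inverse = TRUE)) / length(vol)
}

# Resample one 3-D volume under a 6-parameter rigid transform.
.resampleVolume <- function(vol, par, voxelSize, invert = FALSE) {
  .rigidResampleCpp(as.numeric(vol), as.integer(dim(vol)), as.numeric(par),
                    rep_len(as.numeric(voxelSize), 3L), isTRUE(invert))
}

#' Estimate rigid-body motion by intensity-based realignment
#'
#' Each frame is registered to the reference frame by minimising the masked
#' mean squared intensity difference after inverse-resampling the frame.
#' The search is coarse-to-fine: an optional coarse grid over translations
#' (2 mm steps) seeds a damped Gauss-Newton (Levenberg-Marquardt)
#' refinement of all six parameters with a central-difference Jacobian --
#' the standard scheme for intensity-based rigid realignment. The reference
#' frame's parameters are exactly zero.
#'
#' Frames whose estimate lands outside the stated bounds are flagged
#' (attribute \code{boundsHit} on the returned trace) rather than failing.
#'
#' @param run an [FmriRun-class] with at least 2 frames.
#' @param brainMask 3-D logical array (non-empty).
#' @param reference reference frame index.
#' @param maxTrans,maxRot bounds (mm / radians) used for flagging and the
#'   coarse grid extent.
#' @param coarse logical; run the coarse translation grid first.
#' @return A [MotionTrace-class]; attribute \code{boundsHit} is a logical
#'   vector over frames.
#' @export
estimateRigidMotion <- function(run, brainMask, reference = 1L,
                                maxTrans = 4, maxRot = 0.06, coarse = TRUE) {
  stopifnot(is(run, "FmriRun"))
  idx <- which(brainMask)
  if (!length(idx)) stop("brain mask is empty")
  nt <- nFrames(run)
  if (nt < 2L) stop("need at least 2 frames")
  d <- dim(run@data)[1:3]
  # two tricks standard in intensity-based realignment: (1) register
  # smoothed images, so trilinear interpolation loss (high-frequency) does
  # not drown the alignment signal; (2) symmetric cost -- frame and
  # reference are each resampled by half the candidate transform, so the
  # per-resample interpolation loss is the same on both sides and cancels
  # instead of biasing the minimum toward zero rotation
  smooth <- .smoothKernelFFT(d, sigma = 1.2)
  ref <- array(.smooth3d(run@data[, , , reference], smooth), d)
  params <- matrix(0, nt, 6L)
  bounds <- logical(nt)
  vs <- run@voxelSize
  resid <- function(frame, p) {
    w1 <- .rigidResampleCpp(frame, as.integer(d), p / 2, vs, TRUE)
    w2 <- .rigidResampleCpp(ref, as.integer(d), p / 2, vs, FALSE)
    w1[idx] - w2[idx]
  }
  h <- c(rep(1e-3, 3), rep(0.05, 3))  # finite-difference steps (rad / mm)
  for (t in seq_len(nt)) {
    if (t == reference) next
    frame <- as.numeric(.smooth3d(run@data[, , , t], smooth))
    p <- rep(0, 6L)
    r <- resid(frame, p)
    cost <- mean(r^2)
    if (coarse) {
      for (tx in seq(-maxTrans, maxTrans, by = 2))
        for (ty in seq(-maxTrans, maxTrans, by = 2))
          for (tz in seq(-maxTrans, maxTrans, by = 2)) {
            if (tx == 0 && ty == 0 && tz == 0) next
            pc <- c(0, 0, 0, tx, ty, tz)
            rc <- resid(frame, pc)
            cc <- mean(rc^2)
            if (cc < cost) { cost <- cc; p <- pc; r <- rc }
          }
    }
    lambda <- 1e-3
    for (it in 1:40) {
      J <- vapply(1:6, function(j) {
        e <- numeric(6); e[j] <- h[j]
        (resid(frame, p + e) - resid(frame, p - e)) / (2 * h[j])
      }, numeric(length(idx)))
      H <- crossprod(J)
      g <- crossprod(J, r)
      improved <- FALSE
      for (try in 1:8) {
        step <- tryCatch(solve(H + lambda * diag(diag(H)), -g),
                         error = function(e) NULL)
        if (is.null(step)) { lambda <- lambda * 10; next }
        pNew <- p + as.numeric(step)
        rNew <- resid(frame, pNew)
        cNew <- mean(rNew^2)
        if (cNew < cost) {
          p <- pNew; r <- rNew
          done <- (cost - cNew) < 1e-9 * cost ||
            (max(abs(step[1:3])) < 1e-5 && max(abs(step[4:6])) < 5e-4)
          cost <- cNew
          lambda <- max(lambda / 3, 1e-8)
          improved <- TRUE
          break
        }
        lambda <- lambda * 10
      }
      if (!improved || done) break
    }
    params[t, ] <- p
    bounds[t] <- any(abs(p[1:3]) > maxRot) || any(abs(p[4:6]) > maxTrans)
  }
  out <- MotionTrace(params, tr = run@tr, referenceFrame = as.integer(reference))
  attr(out, "boundsHit") <- bounds
  out
}
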