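#' Discard initial dummy volumes
#'
#' Drops the first \code{nDummy} frames (pre-steady-state magnetization)
#' from both the image and its motion trace. FD should be recomputed on the
#' remainder ([computeFD()] restarts at 0 automatically).
#'
#' @param run an [FmriRun-class].
#' @param trace the matching [MotionTrace-class].
#' @param nDummy number of initial frames to discard (default 3).
#' @return A list with elements \code{run} and \code{trace}.
#' @export
discardDummies <- function(run, trace, nDummy = 3L) {
  stopifnot(is(run, "FmriRun"), is(trace, "MotionTrace"), nDummy >= 0L)
  nt <- nFrames(run)
  if (nFrames(trace) != nt) stop("trace length must equal the frame count")
  if (nt < nDummy + 2L)
    stop("run too short: need at least nDummy + 2 frames")
  if (nDummy == 0L) return(list(run = run, trace = trace))
  keep <- (nDummy + 1L):nt
  list(run = run[keep],
       trace = MotionTrace(trace@params[keep, , drop = FALSE], tr = trace@tr))
}

#' FD-threshold keep mask
#'
#' A frame survives censoring iff its FD does not exceed the threshold
#' (boundary frames are kept, matching "volumes whose FD exceeded the
#' threshold were removed"). No neighbour expansion and no minimum
#' segment length are applied by default; \code{minSegment} can impose one
#' (segments of consecutive kept frames shorter than it are dropped too, in
#' which case the mask loses its nesting property across thresholds).
#'
#' @param fd an [FDSeries-class] or a numeric FD vector.
#' @param threshold FD threshold in mm.
#' @param minSegment minimum length (frames) of a retained segment;
#'   0 disables (the default).
#' @return Logical keep mask over frames.
#' @examples
#' censorByFD(c(0, .1, .5, .2, .6), threshold = 0.4)
#' @export
censorByFD <- function(fd, threshold, minSegment = 0L) {
  if (is(fd, "FDSeries")) fd <- fd@fd
  stopifnot(threshold > 0)
  keep <- fd <= threshold
  if (minSegment > 0L && any(keep)) {
    r <- rle(keep)
    r$values[r$values & r$lengths < minSegment] <- FALSE
    keep <- inverse.rle(r)
  }
  keep
}

#' Concatenate censored runs into one sequence
#'
#' Joins the surviving frames of several runs, in acquisition order, into a
#' single [FmriRun-class], recording per-frame provenance in a
#' [CensorPlan-class]. All runs must share grid shape, voxel size and TR.
#'
#' @param runs list of [FmriRun-class] objects.
#' @param keepMasks list of per-run logical keep masks (default: keep all).
#' @param traces optional list of [MotionTrace-class]; when given, the kept
#'   frames' parameters are concatenated and returned as \code{trace}.
#' @param reason tag recorded for dropped frames (default \code{"fd"}).
#' @param thresholdFd threshold recorded in the plan (bookkeeping only).
#' @param fd optional list of per-run FD vectors stored in the plan.
#' @return A list with \code{run}, \code{plan} and (if traces were given)
#'   \code{trace}.
#' @export
concatenateRuns <- function(runs, keepMasks = NULL, traces = NULL,
                            reason = "fd", thresholdFd = Inf, fd = NULL) {
  stopifnot(length(runs) >= 1L)
  d0 <- dim(runs[[1L]]@data)[1:3]
  vs0 <- runs[[1L]]@voxelSize
  tr0 <- runs[[1L]]@tr
  for (r in runs) {
    if (!identical(dim(r@data)[1:3], d0) || !isTRUE(all.equal(r@voxelSize, vs0)))
      stop("runs differ in grid shape or voxel size")
    if (!isTRUE(all.equal(r@tr, tr0))) stop("runs differ in TR")
  }
  if (is.null(keepMasks))
    keepMasks <- lapply(runs, function(r) rep(TRUE, nFrames(r)))
  tabs <- list(); datas <- list(); pars <- list()
  bound <- integer(0); nextIdx <- 1L
  for (i in seq_along(runs)) {
    keep <- keepMasks[[i]]
    nt <- nFrames(runs[[i]])
    if (length(keep) != nt) stop("keep mask length must equal frame count")
    ci <- rep(NA_integer_, nt)
    ci[keep] <- seq.int(nextIdx, length.out = sum(keep))
    tabs[[i]] <- data.frame(
      sourceRun = i, sourceFrame = seq_len(nt), kept = keep,
      reason = ifelse(keep, "kept", reason), concatIndex = ci,
      fd = if (is.null(fd)) NA_real_ else fd[[i]])
    bound <- c(bound, nextIdx)
    nextIdx <- nextIdx + sum(keep)
    if (any(keep)) {
      datas[[length(datas) + 1L]] <- runs[[i]]@data[, , , keep, drop = FALSE]
      if (!is.null(traces))
        pars[[length(pars) + 1L]] <- traces[[i]]@params[keep, , drop = FALSE]
    }
  }
  tab <- do.call(rbind, tabs)
  if (nextIdx == 1L) stop("no frames survive censoring")
  arr <- array(unlist(datas, use.names = FALSE), dim = c(d0, nextIdx - 1L))
  plan <- new("CensorPlan", table = tab, runBoundaries = bound,
              thresholdFd = thresholdFd)
  out <- list(run = FmriRun(arr, tr = tr0, voxelSize = vs0), plan = plan)
  if (!is.null(traces))
    out$trace <- MotionTrace(do.call(rbind, pars), tr = tr0)
  out
}

#' Per-volume brain-voxel counts
#'
#' A light-weight per-volume brain extraction used for field-of-view
#' screening: voxels above \code{frac} (default 0.35) of the volume's
#' robust maximum (98th percentile), restricted to the largest 6-connected
#' component, are counted as brain.
#'
#' @param run an [FmriRun-class].
#' @param frac fraction of the robust maximum used as threshold.
#' @return Integer vector of per-frame brain-voxel counts.
#' @export
brainVoxelCounts <- function(run, frac = 0.35) {
  stopifnot(is(run, "FmriRun"))
  d <- dim(run@data)[1:3]
  nt <- nFrames(run)
  counts <- integer(nt)
  for (t in seq_len(nt)) {
    v <- run@data[, , , t]
    cut <- frac * stats::quantile(v, 0.98, names = FALSE)
    m <- v > cut
    if (!any(m)) { counts[t] <- 0L; next }
    lab <- .labelComponentsCpp(m, as.integer(d))
    counts[t] <- max(tabulate(lab[lab > 0L]))
  }
  counts
}

#' Detect field-of-view outlier frames
#'
#' Flags frames whose brain-voxel count deviates from the across-frame mean
#' by more than \code{zCut} standard deviations (default 4): frames where
#' the head has partially left the imaging volume have anomalously low
#' counts even when otherwise artifact-free. The mean and SD are computed
#' over all frames in a single pass by default; \code{iterative = TRUE}
#' re-estimates them after excluding flagged frames until stable.
#'
#' @param run an [FmriRun-class] with at least 8 frames.
#' @param zCut standard-deviation cut.
#' @param frac threshold fraction passed to [brainVoxelCounts()].
#' @param iterative recompute mean/SD after excluding flagged frames.
#' @return A list: \code{counts}, \code{mean}, \code{sd}, \code{zCut},
#'   \code{outlier} (logical per frame).
#' @export
detectFovOutliers <- function(run, zCut = 4, frac = 0.35, iterative = FALSE) {
  stopifnot(is(run, "FmriRun"))
  if (nFrames(run) < 8L) stop("need at least 8 frames for a meaningful SD")
  counts <- brainVoxelCounts(run, frac = frac)
  use <- rep(TRUE, length(counts))
  repeat {
    m <- mean(counts[use]); s <- stats::sd(counts[use])
    if (s == 0) {
      warning("all brain-voxel counts equal; no FOV outliers detectable")
      out <- rep(FALSE, length(counts))
      break
    }
    out <- abs(counts - m) > zCut * s
    if (!iterative || identical(out, !use)) break
    use <- !out
  }
  list(counts = counts, mean = m, sd = s, zCut = zCut, outlier = out)
}

#' Trim a concatenated run to a fixed analysis duration
#'
#' Keeps the first \code{floor(duration / tr)} surviving frames (so the
#' retained data never exceeds the stated duration) and tags all later
#' surviving frames with reason \code{"trim"} in the plan. Trimming an
#' already-trimmed pair is the identity. If fewer frames survive than the
#' duration requires, an \code{msInsufficientData} error is signalled:
#' this is the subject-exclusion event.
#'
#' @param run the concatenated [FmriRun-class].
#' @param plan the matching [CensorPlan-class].
#' @param duration analysis duration in seconds (default 240).
#' @return A list with the trimmed \code{run} and updated \code{plan}.
#' @export
trimToDuration <- function(run, plan, duration = 240) {
  stopifnot(is(run, "FmriRun"), is(plan, "CensorPlan"), duration > 0)
  nKeep <- floor(duration / run@tr)
  nt <- nFrames(run)
  if (nt < nKeep)
    stop(structure(class = c("msInsufficientData", "error", "condition"),
                   list(message = sprintf(
                     "insufficient data: %.1f s retained < %.1f s required",
                     nt * run@tr, duration), call = sys.call(-1))))
  if (nt == nKeep) return(list(run = run, plan = plan))
  tab <- plan@table
  drop <- which(tab$kept & tab$concatIndex > nKeep)
  tab$kept[drop] <- FALSE
  tab$reason[drop] <- "trim"
  tab$concatIndex[drop] <- NA_integer_
  bound <- plan@runBoundaries[plan@runBoundaries <= nKeep]
  plan2 <- new("CensorPlan", table = tab, runBoundaries = bound,
               thresholdFd = plan@thresholdFd)
  list(run = run[seq_len(nKeep)], plan = plan2)
}

#' Subject retention as a function of censoring threshold
#'
#' For each threshold, a subject is retained iff the frames with FD at or
#' below the threshold add up to at least \code{minDuration} seconds.
#' The retained count is monotonically non-decreasing in the threshold.
#'
#' @param fdList list of per-subject FD vectors (all runs pooled, in
#'   acquisition order) or [FDSeries-class] objects.
#' @param thresholds FD thresholds in mm.
#' @param tr repetition time in seconds (ignored for FDSeries inputs).
#' @param minDuration required seconds of retained data (default 240).
#' @param groups optional per-subject group factor for per-group counts.
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{nRetained}, \code{propRetained} and one \code{n_<level>} column
#'   per group level.
#' @export
subjectRetention <- function(fdList, thresholds = c(0.25, 0.3, 0.4, 0.5),
                             tr = NULL, minDuration = 240, groups = NULL) {
  fds <- lapply(fdList, function(f) if (is(f, "FDSeries")) f@fd else f)
  trs <- vapply(fdList, function(f) if (is(f, "FDSeries")) f@tr else tr,
                numeric(1))
  if (anyNA(trs)) stop("tr must be supplied for plain numeric FD vectors")
  ret <- vapply(thresholds, function(th) {
    vapply(seq_along(fds), function(i) {
      sum(fds[[i]] <= th) * trs[i] >= minDuration
    }, logical(1))
  }, logical(length(fds)))
  ret <- matrix(ret, nrow = length(fds))
  out <- data.frame(threshold = thresholds,
                    nRetained = colSums(ret),
                    propRetained = colMeans(ret))
  if (!is.null(groups)) {
    groups <- factor(groups)
    for (lev in levels(groups))
      out[[paste0("n_", lev)]] <- colSums(ret[groups == lev, , drop = FALSE])
  }
  out
}
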