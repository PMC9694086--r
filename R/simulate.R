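#' Simulate a rigid-body motion trace with a heavy-tailed FD distribution
#'
#' Head motion is modelled as continuous low-amplitude Gaussian jitter plus
#' sparse large "jump" events (Bernoulli-thinned, log-normal amplitudes
#' split randomly across the six parameters), the simplest generator that
#' reproduces the right-skewed per-frame FD distribution of fidgety
#' pediatric cohorts (mean well above median). After drawing, all parameter
#' steps are rescaled by one common factor so the realized mean FD over
#' frames 2..n equals \code{targetMeanFd} exactly (FD is 1-homogeneous in
#' the steps), which keeps subject-level mean FD an exact design variable
#' while leaving the distributional shape random.
#'
#' @param nFrames number of frames (>= 2).
#' @param tr repetition time in seconds (> 0).
#' @param targetMeanFd target mean FD in mm.
#' @param eventRate per-frame probability of a jump event.
#' @param eventMeanlog,eventSdlog log-normal parameters of event amplitude (mm).
#' @param jitterSd standard deviation (mm) of each translation jitter step;
#'   rotations jitter with sd \code{jitterSd / rotationRadius}.
#' @param rotationRadius sphere radius (mm) used in the FD bookkeeping.
#' @param seed optional integer seed.
#' @return A [MotionTrace-class] (reference = frame 1, parameters start at
#'   zero) with attribute \code{fd}: the generator's own FD bookkeeping.
#' @examples
#' tr <- simulateMotionTrace(600, 0.78, targetMeanFd = 0.5, seed = 7)
#' mean(attr(tr, "fd"))
#' @export
simulateMotionTrace <- function(nFrames, tr, targetMeanFd = 0.5,
                                eventRate = 0.1, eventMeanlog = log(1.4),
                                eventSdlog = 1.0, jitterSd = 0.04,
                                rotationRadius = 50, seed = NULL) {
  if (tr <= 0) stop("tr must be positive")
  stopifnot(nFrames >= 2, targetMeanFd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ns <- nFrames - 1L
  steps <- cbind(matrix(stats::rnorm(ns * 3, 0, jitterSd / rotationRadius), ns, 3),
                 matrix(stats::rnorm(ns * 3, 0, jitterSd), ns, 3))
  ev <- stats::runif(ns) < eventRate
  for (i in which(ev)) {
    amp <- stats::rlnorm(1, eventMeanlog, eventSdlog)
    w <- abs(stats::rnorm(6)); w <- w / sum(w) * amp
    sg <- sample(c(-1, 1), 6, replace = TRUE)
    steps[i, 1:3] <- steps[i, 1:3] + sg[1:3] * w[1:3] / rotationRadius
    steps[i, 4:6] <- steps[i, 4:6] + sg[4:6] * w[4:6]
  }
  # generator-side FD bookkeeping (sum |dt| + R * sum |dr|)
  fdSteps <- rowSums(abs(steps[, 4:6, drop = FALSE])) +
    rotationRadius * rowSums(abs(steps[, 1:3, drop = FALSE]))
  m <- mean(fdSteps)
  if (m > 0 && targetMeanFd > 0) {
    steps <- steps * (targetMeanFd / m)
    fdSteps <- fdSteps * (targetMeanFd / m)
  } else if (targetMeanFd == 0) {
    steps[] <- 0; fdSteps[] <- 0
  }
  params <- rbind(0, apply(steps, 2L, cumsum))
  out <- MotionTrace(params, tr = tr, referenceFrame = 1L)
  attr(out, "fd") <- c(0, fdSteps)
  out
}

#' Assemble the ground truth for one synthetic subject
#'
#' Given a phantom template and per-run motion traces, draws everything the
#' renderer needs and the tests score against: low-frequency network time
#' courses (sums of sinusoids in 0.01-0.08 Hz) painted on node groups;
#' motion-locked artifact time courses (rim artifact proportional to FD;
#' slice-periodic artifact gated by an FD trigger with an alternating
#' high-frequency sign); an optional motion-scaled connectivity confound
#' (FD-spike-locked signal shared across nodes with source weights decaying
#' with distance, amplitude proportional to the subject's mean FD); and
#' analytic node-level series mirroring what parcel averaging of the
#' rendered data would give.
#'
#' @param template a [PhantomTemplate-class].
#' @param traces list of [MotionTrace-class], one per run (as returned by
#'   [simulateMotionTrace()], whose \code{fd} attribute is reused when
#'   present).
#' @param seed integer seed.
#' @param nNetworks number of embedded networks.
#' @param noiseSd thermal noise SD in intensity units (template brain is
#'   ~1000).
#' @param netAmp network signal amplitude (intensity units per unit tc).
#' @param rimAmp rim artifact amplitude per mm FD.
#' @param sliceAmp slice artifact amplitude per mm FD.
#' @param sliceTrigger FD (mm) above which the slice artifact is active.
#' @param artifactFdCap FD (mm) at which artifact amplitude saturates
#'   (gross-motion frames are censored anyway; unbounded amplitudes would
#'   be unphysical).
#' @param spinHistorySd SD of the per-slice spin-history gain (fractional
#'   signal change per mm FD): motion in an interleaved acquisition leaves
#'   slice-wise signal modulation on every frame, including sub-threshold
#'   ones.
#' @param spinDynamicFrac fraction of \code{spinHistorySd} that is
#'   frame-varying at the voxel level and therefore not removable by
#'   component regression; the majority of motion-locked variance is
#'   structured (removable), as cleanup of real data shows.
#' @param slicePeriod artifact slice period.
#' @param dropoutFrames list (per run) of frame indices rendered with a
#'   partial field-of-view exit.
#' @param dropoutExitFraction fraction of brain voxels pushed off-grid on
#'   dropout frames.
#' @param confoundStrength scale of the motion-correlated connectivity
#'   confound (0 disables it).
#' @param confoundSources number of confound foci.
#' @param confoundLambda distance decay scale (mm) of source weights.
#' @param confoundAmp base intensity amplitude of the confound.
#' @param rotationRadius FD rotation radius (mm).
#' @return A [GroundTruth-class].
#' @export
makeGroundTruth <- function(template, traces, seed = 1, nNetworks = 3,
                            noiseSd = 15, netAmp = 15, rimAmp = 250,
                            sliceAmp = 150, sliceTrigger = 0.3,
                            artifactFdCap = 1.5, spinHistorySd = 0.1,
                            spinDynamicFrac = 0.35,
                            slicePeriod = 4L, dropoutFrames = NULL,
                            dropoutExitFraction = 0.3,
                            confoundStrength = 0, confoundSources = 3,
                            confoundLambda = 25, confoundAmp = 15,
                            rotationRadius = 50) {
  stopifnot(is(template, "PhantomTemplate"), length(traces) >= 1L)
  set.seed(as.integer(seed))
  nRuns <- length(traces)
  N <- nNodes(template)
  if (is.null(dropoutFrames)) dropoutFrames <- rep(list(integer(0)), nRuns)

  fd <- lapply(traces, function(tr) {
    f <- attr(tr, "fd")
    if (is.null(f)) f <- computeFD(tr, rotationRadius)@fd
    f
  })
  meanFd <- mean(unlist(fd))

  # node-to-network assignment: contiguous blocks of the node list, weights
  # jittered around 1 so parcels within a network are strongly coupled
  member <- sort(rep_len(seq_len(nNetworks), N))
  W <- matrix(0, N, nNetworks)
  W[cbind(seq_len(N), member)] <- stats::runif(N, 0.8, 1.2)

  # confound: foci at random node centroids, weights decay with distance
  cw <- matrix(0, N, confoundSources)
  if (confoundStrength > 0) {
    foci <- template@nodeCentroids[sample.int(N, confoundSources), , drop = FALSE]
    for (s in seq_len(confoundSources)) {
      d <- sqrt(colSums((t(template@nodeCentroids) - foci[s, ])^2))
      cw[, s] <- exp(-d / confoundLambda)
    }
  }

  netTc <- vector("list", nRuns)
  artTc <- vector("list", nRuns)
  confTc <- vector("list", nRuns)
  nodeSeries <- vector("list", nRuns)
  meanParcelVox <- mean(tabulate(template@parcellation[template@parcellation > 0]))
  confAmpSubj <- confoundStrength * meanFd * confoundAmp
  for (r in seq_len(nRuns)) {
    tt <- seq_len(nFrames(traces[[r]])) * traces[[r]]@tr
    nt <- length(tt)
    n <- vapply(seq_len(nNetworks), function(k) {
      f <- stats::runif(3, 0.01, 0.08)
      a <- stats::runif(3, 0.6, 1.2)
      ph <- stats::runif(3, 0, 2 * pi)
      x <- a[1] * sin(2 * pi * f[1] * tt + ph[1]) +
           a[2] * sin(2 * pi * f[2] * tt + ph[2]) +
           a[3] * sin(2 * pi * f[3] * tt + ph[3])
      as.numeric(scale(x))
    }, numeric(nt))
    netTc[[r]] <- n
    f <- pmin(fd[[r]], artifactFdCap)
    artTc[[r]] <- list(rim = f,
                       slice = f * (fd[[r]] > sliceTrigger) * (-1)^seq_len(nt),
                       spin = f,
                       spinGain = stats::rnorm(dim(template@intensity)[3], 0,
                                               spinHistorySd))
    cc <- matrix(0, nt, confoundSources)
    if (confoundStrength > 0) {
      gate <- f * (f > 0.25)
      cc <- gate * matrix(stats::rnorm(nt * confoundSources), nt)
    }
    confTc[[r]] <- cc
    nodeSeries[[r]] <- netAmp * (n %*% t(W)) + confAmpSubj * (cc %*% t(cw)) +
      matrix(stats::rnorm(nt * N, 0, noiseSd / sqrt(meanParcelVox)), nt, N)
  }

  new("GroundTruth", motion = traces, fd = fd, networkTimecourses = netTc,
      networkWeights = W, artifactTimecourses = artTc,
      confound = list(sourceWeights = cw, timecourses = confTc,
                      amplitude = confAmpSubj),
      nodeSeries = nodeSeries, dropoutFrames = dropoutFrames,
      noiseSd = noiseSd, subjectMeanFdTarget = meanFd,
      params = list(netAmp = netAmp, rimAmp = rimAmp, sliceAmp = sliceAmp,
                    sliceTrigger = sliceTrigger, artifactFdCap = artifactFdCap,
                    spinHistorySd = spinHistorySd,
                    spinDynamicFrac = spinDynamicFrac,
                    slicePeriod = slicePeriod,
                    dropoutExitFraction = dropoutExitFraction,
                    rotationRadius = rotationRadius))
}

# z translation (mm) pushing `frac` of the brain voxels beyond the grid top
.dropoutShift <- function(template, frac) {
  d <- dim(template@brainMask)
  vz <- template@voxelSize[3]
  zIdx <- arrayInd(which(template@brainMask), d)[, 3]
  zmm <- (zIdx - (d[3] + 1) / 2) * vz
  zEdge <- ((d[3] - 1) / 2 + 0.5) * vz
  # want P(z + s > zEdge) >= frac
  zEdge - stats::quantile(zmm, 1 - frac, names = FALSE) + 0.51 * vz
}

#' Render one synthetic functional run
#'
#' Produces the 4-D image for one run of a subject: per frame, the template
#' plus network (and confound) signals painted on the parcels is resampled
#' under that frame's rigid-body motion (trilinear), then motion-locked
#' artifacts are added in acquisition space -- a brain-edge rim scaled by
#' FD(t) and, on frames with FD above the trigger, a slice-periodic pattern
#' on every \code{slicePeriod}-th slice -- plus Gaussian thermal noise.
#' Frames listed in the run's dropout set are rendered with an extra
#' out-of-plane translation pushing \code{dropoutExitFraction} of the brain
#' off the grid. A per-slice spin-history gain, scaled by FD, modulates
#' every frame multiplicatively.
#'
#' @param template a [PhantomTemplate-class].
#' @param truth a [GroundTruth-class] whose run \code{run} has the motion.
#' @param run run index within the truth.
#' @param seed integer seed (thermal noise only; all structure is fixed by
#'   the truth).
#' @return An [FmriRun-class].
#' @export
renderRun <- function(template, truth, run = 1L, seed = 1) {
  stopifnot(is(template, "PhantomTemplate"), is(truth, "GroundTruth"))
  set.seed(as.integer(seed))
  trace <- truth@motion[[run]]
  nt <- nFrames(trace)
  d <- dim(template@intensity)
  P <- truth@params
  fd <- truth@fd[[run]]

  parcelVox <- split(which(template@parcellation > 0),
                     template@parcellation[template@parcellation > 0])
  rim <- which(rimMask(template))
  slc <- which(.sliceMask(template, truth@params$slicePeriod))
  # node signal = network part + confound part (same construction as the
  # analytic nodeSeries but without the per-parcel measurement noise, which
  # in the rendered data arises from voxelwise thermal noise)
  nodeVal <- P$netAmp * (truth@networkTimecourses[[run]] %*% t(truth@networkWeights)) +
    truth@confound$amplitude *
      (truth@confound$timecourses[[run]] %*% t(truth@confound$sourceWeights))
  drop <- truth@dropoutFrames[[run]]
  dropShift <- if (length(drop)) .dropoutShift(template, P$dropoutExitFraction) else 0
  spinGain <- truth@artifactTimecourses[[run]]$spinGain
  spinDynSd <- truth@params$spinHistorySd * truth@params$spinDynamicFrac

  out <- array(0, c(d, nt))
  base <- template@intensity
  for (t in seq_len(nt)) {
    vol <- base
    for (i in seq_along(parcelVox))
      vol[parcelVox[[i]]] <- vol[parcelVox[[i]]] + nodeVal[t, i]
    par <- trace@params[t, ]
    if (t %in% drop) par[6] <- par[6] + dropShift
    if (any(par != 0))
      vol <- .resampleVolume(vol, par, template@voxelSize, invert = FALSE)
    fdc <- min(fd[t], P$artifactFdCap)
    vol[rim] <- vol[rim] + P$rimAmp * fdc
    if (fd[t] > P$sliceTrigger)
      vol[slc] <- vol[slc] + P$sliceAmp * fdc * (-1)^t
    # spin-history: a static slice-wise multiplicative gain scaled by FD
    # (a removable rank-1 artifact component) plus an equally strong
    # voxel-level frame-varying part (irreducible motion-scaled intensity
    # instability; voxel-level so it averages out of parcel means but
    # still degrades voxelwise tSNR in proportion to motion)
    gain <- 1 + fdc * rep(spinGain, each = d[1] * d[2])
    vol <- vol * gain
    if (spinDynSd > 0 && fdc > 0)
      vol <- vol * (1 + fdc * spinDynSd * stats::rnorm(length(vol)))
    if (truth@noiseSd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, truth@noiseSd)
    out[, , , t] <- vol
  }
  FmriRun(out, tr = trace@tr, voxelSize = template@voxelSize)
}

#' Simulate a multi-subject, multi-run synthetic cohort
#'
#' Draws a cohort of subjects over one shared phantom template. Per-subject
#' target mean FD is uniform over \code{fdRange} plus a group offset for
#' group "B" (emulating a sex difference in head motion); each run gets its
#' own motion trace calibrated to the subject's target. With
#' \code{confoundStrength > 0} a motion-scaled, distance-dependent shared
#' signal is injected (see [makeGroundTruth()]) so QC-FD inflation exists
#' for the pipeline to remove; with 0 the cohort is null by construction.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param runsPerSubject runs per subject.
#' @param nFrames frames per run.
#' @param tr repetition time in seconds.
#' @param fdRange range (mm) of the per-subject target mean FD.
#' @param groupOffset FD offset (mm) added to group "B" subjects.
#' @param confoundStrength connectivity confound scale (0 = null cohort).
#' @param nNodes,gridShape,voxelSize template geometry (ignored when
#'   \code{template} is given).
#' @param dropoutRate per-run probability of one field-of-view dropout
#'   frame.
#' @param render render the 4-D volumes up front. With FALSE the cohort
#'   stays light (traces, truths and render seeds only); consumers such as
#'   [runCohort()] render each subject on demand via [renderSubject()],
#'   which keeps the memory footprint to one subject at a time.
#' @param template optional pre-built [PhantomTemplate-class] shared by the
#'   cohort.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @param ... further arguments passed to [makeGroundTruth()].
#' @return A list with class \code{msCohort}: \code{template},
#'   \code{subjects} (each \code{list(id, runs, traces, truth)}),
#'   \code{covariates} (data.frame with subject, group, age,
#'   targetMeanFd, meanFd), and the call parameters.
#' @export
simulateCohort <- function(nSubjects, runsPerSubject = 2L, nFrames = 300L,
                           tr = 0.78, fdRange = c(0.2, 0.65),
                           groupOffset = 0.08, confoundStrength = 0,
                           nNodes = 12, gridShape = c(32, 32, 24),
                           voxelSize = 2.5, dropoutRate = 0,
                           render = TRUE, template = NULL, seed = 1, ...) {
  stopifnot(nSubjects >= 3)
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(template))
    template <- makePhantom(gridShape, voxelSize, nNodes, seed = seed)
  group <- rep_len(c("A", "B"), nSubjects)
  target <- stats::runif(nSubjects, fdRange[1], fdRange[2]) +
    ifelse(group == "B", groupOffset, 0)
  age <- stats::runif(nSubjects, 6, 8)
  subSeed <- sample.int(.Machine$integer.max %/% 2L, nSubjects)
  subjects <- vector("list", nSubjects)
  meanFd <- numeric(nSubjects)
  for (i in seq_len(nSubjects)) {
    set.seed(subSeed[i])
    runSeeds <- sample.int(.Machine$integer.max %/% 2L, 2L * runsPerSubject + 1L)
    traces <- lapply(seq_len(runsPerSubject), function(r)
      simulateMotionTrace(nFrames, tr, targetMeanFd = target[i],
                          seed = runSeeds[r]))
    dropout <- lapply(seq_len(runsPerSubject), function(r) {
      set.seed(runSeeds[runsPerSubject + r])
      if (stats::runif(1) < dropoutRate)
        sample.int(nFrames - 10L, 1L) + 5L else integer(0)
    })
    truth <- makeGroundTruth(template, traces,
                             seed = runSeeds[2L * runsPerSubject + 1L],
                             dropoutFrames = dropout,
                             confoundStrength = confoundStrength, ...)
    renderSeeds <- runSeeds[seq_len(runsPerSubject)] + 1L
    runs <- NULL
    if (render)
      runs <- lapply(seq_len(runsPerSubject), function(r)
        renderRun(template, truth, run = r, seed = renderSeeds[r]))
    meanFd[i] <- mean(unlist(truth@fd))
    subjects[[i]] <- list(id = sprintf("s%03d", i), runs = runs,
                          traces = traces, truth = truth,
                          renderSeeds = renderSeeds)
  }
  structure(list(template = template, subjects = subjects,
                 covariates = data.frame(subject = sprintf("s%03d", seq_len(nSubjects)),
                                         group = group, age = age,
                                         targetMeanFd = target, meanFd = meanFd),
                 tr = tr, seed = seed, confoundStrength = confoundStrength),
            class = "msCohort")
}

#' @export
print.msCohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d run(s), %s, confound %g, seed %d\n",
              nrow(x$covariates), length(x$subjects[[1]]$traces),
              if (is.null(x$subjects[[1]]$runs)) "node-level only" else "rendered",
              x$confoundStrength, x$seed))
  invisible(x)
}


#' Render (or fetch) the runs of one cohort subject
#'
#' Cohorts simulated with \code{render = FALSE} carry everything needed to
#' reproduce their 4-D runs bit-identically (truth + per-run seeds); this
#' renders subject \code{i} on demand.
#'
#' @param cohort an \code{msCohort} from [simulateCohort()].
#' @param i subject index.
#' @return List of [FmriRun-class], one per run.
#' @export
renderSubject <- function(cohort, i) {
  sub <- cohort$subjects[[i]]
  if (!is.null(sub$runs)) return(sub$runs)
  lapply(seq_along(sub$traces), function(r)
    renderRun(cohort$template, sub$truth, run = r, seed = sub$renderSeeds[r]))
}
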