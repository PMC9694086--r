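#' Construct a pipeline configuration
#'
#' Collects every tunable parameter of the censor-concatenate-denoise
#' pipeline with the study defaults: censor at FD 0.3 mm (comparison
#' thresholds 0.25 / 0.3 / 0.4 / 0.5 mm), 3 dummy volumes, trim to 240 s,
#' field-of-view cut at 4 SD, 60 ICA components, 50 mm FD rotation radius
#' and per-volume normalization to 10,000.
#'
#' @param fdThreshold FD censoring threshold (mm); \code{Inf} disables
#'   censoring.
#' @param nDummy dummy volumes discarded per run.
#' @param duration analysis duration (s).
#' @param zCut field-of-view outlier cut (SD units).
#' @param nComponents ICA model order.
#' @param rotationRadius FD rotation radius (mm).
#' @param fCut component high-frequency cutoff (Hz).
#' @param slicePeriod probed slice period.
#' @param minVoxels parcel inclusion minimum.
#' @param normTarget per-volume intensity target.
#' @param tsnrMode "voxelwise" or "global".
#' @param lowessFrac lowess span for distance profiles.
#' @param classifier named rule thresholds (edge, slice, highfreq, jump,
#'   gmOverride).
#' @param applyCleanup run ICA + aggressive regression (default TRUE).
#' @param reestimate re-estimate motion even when traces are supplied.
#' @param seed base seed for all pipeline randomness.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(fdThreshold = 0.3, nDummy = 3L, duration = 240,
                           zCut = 4, nComponents = 60L, rotationRadius = 50,
                           fCut = 0.1, slicePeriod = 4L, minVoxels = 5L,
                           normTarget = 10000, tsnrMode = "voxelwise",
                           lowessFrac = 2/3,
                           classifier = c(edge = 0.45, slice = 0.30,
                                          highfreq = 0.50, jump = 6.0,
                                          gmOverride = 0.68),
                           applyCleanup = TRUE, reestimate = FALSE,
                           seed = 1L) {
  new("PipelineConfig", fdThreshold = fdThreshold, nDummy = as.integer(nDummy),
      duration = duration, zCut = zCut, nComponents = as.integer(nComponents),
      rotationRadius = rotationRadius, fCut = fCut,
      slicePeriod = as.integer(slicePeriod), minVoxels = as.integer(minVoxels),
      normTarget = normTarget, tsnrMode = tsnrMode, lowessFrac = lowessFrac,
      classifier = classifier, applyCleanup = isTRUE(applyCleanup),
      reestimate = isTRUE(reestimate), seed = as.integer(seed))
}

# mark frames (by concat index) dropped for `reason`, renumber survivors
.dropFromPlan <- function(plan, dropConcatIdx, reason) {
  tab <- plan@table
  hit <- tab$kept & tab$concatIndex %in% dropConcatIdx
  tab$kept[hit] <- FALSE
  tab$reason[hit] <- reason
  tab$concatIndex[hit] <- NA_integer_
  tab$concatIndex[tab$kept] <- seq_len(sum(tab$kept))
  bounds <- tapply(tab$concatIndex[tab$kept], tab$sourceRun[tab$kept], min)
  new("CensorPlan", table = tab,
      runBoundaries = as.integer(sort(unname(bounds))),
      thresholdFd = plan@thresholdFd)
}

#' Run the full preprocessing pipeline for one subject
#'
#' Executes dummy-volume discard, FD computation (estimating motion by
#' realignment when no traces are supplied or \code{reestimate} is set),
#' FD censoring, run concatenation, field-of-view outlier rejection by
#' brain-voxel count, motion correction, per-volume intensity
#' normalization, spatial ICA with rule-based component labeling and
#' aggressive noise regression, and trimming to the analysis duration. A
#' subject whose surviving data fall short of the duration is *excluded*
#' (a normal status, not an error). Every input frame is accounted for
#' exactly once in the returned plan (kept / dummy / fd / fov / trim).
#'
#' @param runs list of [FmriRun-class] (>= 1).
#' @param traces list of matching [MotionTrace-class], or NULL to estimate.
#' @param template the [PhantomTemplate-class] supplying brain/grey-matter
#'   masks and the parcellation.
#' @param config a [PipelineConfig-class].
#' @param id subject identifier carried into the QC row.
#' @param keepData keep the (large) cleaned and pre-cleanup 4-D arrays in
#'   the result; set FALSE in cohort loops.
#' @return A list (class \code{msSubjectResult}) with \code{status}
#'   ("completed" / "excluded"), \code{qcRow}, \code{plan},
#'   \code{stageLog}, \code{nodeSeries}, \code{dvarsPre}/\code{dvarsPost}
#'   (fd/dvars pairs before and after censoring), and -- when completed and
#'   \code{keepData} -- \code{cleanedRun}, \code{preRun},
#'   \code{components}, \code{features}, \code{labels}.
#' @export
runSubject <- function(runs, traces = NULL, template, config = pipelineConfig(),
                       id = "s1", keepData = TRUE) {
  stopifnot(length(runs) >= 1L, is(config, "PipelineConfig"))
  brain <- template@brainMask
  log <- list()
  if (is.null(traces) || config@reestimate)
    traces <- lapply(runs, estimateRigidMotion, brainMask = brain)

  nIn <- vapply(runs, nFrames, integer(1))
  dd <- lapply(seq_along(runs), function(i)
    discardDummies(runs[[i]], traces[[i]], config@nDummy))
  runs2 <- lapply(dd, `[[`, "run")
  traces2 <- lapply(dd, `[[`, "trace")
  fds <- lapply(traces2, computeFD, rotationRadius = config@rotationRadius)
  fdVecs <- lapply(fds, fdValues)
  keep <- lapply(fds, censorByFD, threshold = config@fdThreshold)
  log$frames <- data.frame(run = seq_along(runs), input = nIn,
                           postDummy = vapply(runs2, nFrames, integer(1)),
                           postCensor = vapply(keep, sum, integer(1)))

  # pre-censor concatenation for the DVARS-FD baseline
  rawCat <- concatenateRuns(runs2, traces = traces2, reason = "fd",
                            thresholdFd = Inf, fd = fdVecs)
  dvarsPre <- list(fd = computeFD(rawCat$trace, config@rotationRadius)@fd,
                   dvars = computeDVARS(rawCat$run, brain)@dvars)
  rm(rawCat)

  cat0 <- concatenateRuns(runs2, keep, traces2, reason = "fd",
                          thresholdFd = config@fdThreshold, fd = fdVecs)
  run <- cat0$run; plan <- cat0$plan; trace <- cat0$trace
  # prepend the dummy frames to the ledger so every acquisition frame of
  # every input run appears exactly once
  if (config@nDummy > 0L) {
    tab <- plan@table
    tab$sourceFrame <- tab$sourceFrame + config@nDummy
    dumm <- do.call(rbind, lapply(seq_along(runs), function(i)
      data.frame(sourceRun = i, sourceFrame = seq_len(config@nDummy),
                 kept = FALSE, reason = "dummy", concatIndex = NA_integer_,
                 fd = NA_real_)))
    tab <- rbind(dumm, tab)
    tab <- tab[order(tab$sourceRun, tab$sourceFrame), ]
    rownames(tab) <- NULL
    plan <- new("CensorPlan", table = tab, runBoundaries = plan@runBoundaries,
                thresholdFd = plan@thresholdFd)
  }

  # a subject that already falls short of the duration is excluded before
  # the (more expensive) field-of-view screen, which can only drop more
  if (nFrames(run) * run@tr < config@duration) {
    tab <- plan@table
    fdKept <- tab$fd[tab$kept][order(tab$concatIndex[tab$kept])]
    qcRow <- data.frame(subject = id, meanFd = mean(fdKept),
                        tsnrPre = NA_real_, tsnrPost = NA_real_,
                        retainedSeconds = nFrames(run) * run@tr)
    return(structure(list(status = "excluded", id = id, qcRow = qcRow,
                          plan = plan, stageLog = log, dvarsPre = dvarsPre,
                          dvarsPost = if (nFrames(run) >= 11L)
                            list(fd = fdKept,
                                 dvars = computeDVARS(run, brain)@dvars)),
                     class = "msSubjectResult"))
  }

  fov <- detectFovOutliers(run, zCut = config@zCut)
  if (any(fov$outlier)) {
    keepIdx <- which(!fov$outlier)
    plan <- .dropFromPlan(plan, which(fov$outlier), "fov")
    run <- run[keepIdx]
    trace <- MotionTrace(trace@params[keepIdx, , drop = FALSE], tr = trace@tr)
  }
  log$fovOutliers <- sum(fov$outlier)
  nKept <- nFrames(run)
  log$keptFrames <- nKept
  retainedSeconds <- nKept * run@tr

  # mean FD over the frames that will survive the trim, using the original
  # per-run FD values carried in the plan
  nTrim <- floor(config@duration / run@tr)
  tab <- plan@table
  fdKept <- tab$fd[tab$kept][order(tab$concatIndex[tab$kept])]
  # post-censor DVARS-FD pairing: each surviving frame keeps its original
  # FD value (so the x-axis is capped at the threshold, as in a censored
  # scatter); DVARS is computed on the spliced data
  dvarsPost <- list(fd = fdKept,
                    dvars = computeDVARS(run, brain)@dvars)

  if (retainedSeconds < config@duration) {
    qcRow <- data.frame(subject = id, meanFd = mean(fdKept),
                        tsnrPre = NA_real_, tsnrPost = NA_real_,
                        retainedSeconds = retainedSeconds)
    return(structure(list(status = "excluded", id = id, qcRow = qcRow,
                          plan = plan, stageLog = log, dvarsPre = dvarsPre,
                          dvarsPost = dvarsPost),
                     class = "msSubjectResult"))
  }
  meanFd <- mean(fdKept[seq_len(nTrim)])

  run <- applyRigidMotion(run, trace, invert = TRUE)
  run <- normalizeIntensity(run, brain, target = config@normTarget)

  comps <- NULL; feats <- NULL; labs <- NULL
  if (config@applyCleanup) {
    nc <- min(config@nComponents, nKept - 2L, sum(brain) - 1L)
    if (nc < config@nComponents)
      log$nComponents <- nc
    log$icaConverged <- TRUE
    comps <- withCallingHandlers(
      decomposeICA(run, brain, nComponents = nc, seed = config@seed),
      warning = function(w) {
        if (grepl("fixed-point iteration", conditionMessage(w))) {
          log$icaConverged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    feats <- extractComponentFeatures(comps, template, tr = run@tr,
                                      fCut = config@fCut,
                                      slicePeriod = config@slicePeriod)
    labs <- classifyComponents(feats, thresholds = config@classifier)
    cleaned <- aggressiveCleanup(run, comps, labs)
    log$noiseComponents <- sum(labs$label == "noise")
  } else {
    cleaned <- run
  }

  tprePair <- trimToDuration(run, plan, config@duration)
  plan <- tprePair$plan
  preTrim <- tprePair$run
  postTrim <- cleaned[seq_len(nTrim)]

  tsnrPre <- computeTSNR(preTrim, brain, mode = config@tsnrMode)$tsnr
  tsnrPost <- computeTSNR(postTrim, brain, mode = config@tsnrMode)$tsnr
  pts <- parcelTimeseries(postTrim, template@parcellation,
                          minVoxels = config@minVoxels)

  qcRow <- data.frame(subject = id, meanFd = meanFd, tsnrPre = tsnrPre,
                      tsnrPost = tsnrPost, retainedSeconds = retainedSeconds)
  out <- list(status = "completed", id = id, qcRow = qcRow, plan = plan,
              stageLog = log, nodeSeries = pts$series,
              keptNodes = pts$keptNodes, dvarsPre = dvarsPre,
              dvarsPost = dvarsPost)
  if (keepData) {
    out$cleanedRun <- postTrim
    out$preRun <- preTrim
    out$components <- comps
    out$features <- feats
    out$labels <- labs
  }
  structure(out, class = "msSubjectResult")
}

#' @export
print.msSubjectResult <- function(x, ...) {
  cat(sprintf("Subject %s: %s", x$id, x$status))
  if (x$status == "completed")
    cat(sprintf(" | mean FD %.3f mm | tSNR %.1f -> %.1f",
                x$qcRow$meanFd, x$qcRow$tsnrPre, x$qcRow$tsnrPost))
  cat("\n")
  invisible(x)
}

#' Run the pipeline over a cohort and assemble the QC-FD report
#'
#' Applies [runSubject()] to every subject of a (typically simulated)
#' cohort and computes the group-level evaluation battery: the QC table,
#' subject retention by threshold, edge-wise QC-FD statistics with the
#' distance profile, tSNR-FD correlations before and after cleanup,
#' pooled DVARS-FD regressions before and after censoring, and group FD
#' statistics. With a \code{thresholds} vector the whole analysis is
#' repeated per censoring threshold (a threshold sweep).
#'
#' @param cohort an \code{msCohort} from [simulateCohort()], or any list
#'   with \code{template} and \code{subjects} of the same shape.
#' @param config a [PipelineConfig-class]; its \code{fdThreshold} is used
#'   when \code{thresholds} is NULL.
#' @param thresholds optional FD thresholds (mm) to sweep.
#' @param verbose print per-subject progress.
#' @return For a single threshold, a list of class \code{msCohortReport}:
#'   \code{qcTable}, \code{retention}, \code{qcfd}, \code{tsnrFd}
#'   (pre/post), \code{dvars} (pre/post pooled), \code{groupStats},
#'   \code{manifest}. For a sweep, class \code{msSweepReport}: one report
#'   per threshold plus the shared retention table.
#' @export
runCohort <- function(cohort, config = pipelineConfig(), thresholds = NULL,
                      verbose = FALSE) {
  if (!is.null(thresholds)) {
    # subject-outer sweep: each subject is rendered once and pushed through
    # the pipeline at every threshold before being discarded
    resByTh <- lapply(thresholds, function(th) vector("list",
                                                      length(cohort$subjects)))
    names(resByTh) <- as.character(thresholds)
    for (i in seq_along(cohort$subjects)) {
      runs <- if (is.null(cohort$subjects[[i]]$runs)) renderSubject(cohort, i)
              else cohort$subjects[[i]]$runs
      for (th in as.character(thresholds)) {
        cfg <- config
        cfg@fdThreshold <- as.numeric(th)
        cfg@seed <- config@seed + i
        resByTh[[th]][[i]] <- runSubject(runs, cohort$subjects[[i]]$traces,
                                         cohort$template, cfg,
                                         id = cohort$subjects[[i]]$id,
                                         keepData = FALSE)
      }
      rm(runs)
      gc(FALSE)
      if (verbose) cat(sprintf("  %s done\n", cohort$subjects[[i]]$id))
    }
    reports <- lapply(as.character(thresholds), function(th) {
      cfg <- config
      cfg@fdThreshold <- as.numeric(th)
      .assembleCohortReport(resByTh[[th]], cohort, cfg)
    })
    names(reports) <- as.character(thresholds)
    return(structure(list(thresholds = thresholds, reports = reports,
                          retention = reports[[1L]]$retention),
                     class = "msSweepReport"))
  }

  subjects <- cohort$subjects
  template <- cohort$template
  results <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    cfg <- config
    cfg@seed <- config@seed + i
    runs <- if (is.null(subjects[[i]]$runs)) renderSubject(cohort, i)
            else subjects[[i]]$runs
    results[[i]] <- runSubject(runs, subjects[[i]]$traces,
                               template, cfg, id = subjects[[i]]$id,
                               keepData = FALSE)
    rm(runs)
    gc(FALSE)
    if (verbose)
      cat(sprintf("  %s: %s\n", subjects[[i]]$id, results[[i]]$status))
  }
  .assembleCohortReport(results, cohort, config)
}

# group-level report from a list of per-subject results
.assembleCohortReport <- function(results, cohort, config) {
  subjects <- cohort$subjects
  template <- cohort$template
  qcTable <- do.call(rbind, lapply(results, `[[`, "qcRow"))
  qcTable$status <- vapply(results, `[[`, character(1), "status")
  if (!is.null(cohort$covariates))
    qcTable <- merge(qcTable, cohort$covariates[, c("subject", "group", "age")],
                     by = "subject", sort = TRUE)

  # retention over the post-dummy FD series (dummies never count as data)
  fdList <- lapply(results, function(r) {
    tab <- planTable(r$plan)
    tab$fd[tab$reason != "dummy"]
  })
  retention <- subjectRetention(fdList, tr = repTime(subjects[[1L]]$traces[[1L]]),
                                minDuration = config@duration,
                                groups = if (!is.null(cohort$covariates))
                                  cohort$covariates$group)

  done <- qcTable$status == "completed"
  report <- list(qcTable = qcTable, retention = retention,
                 manifest = list(config = configAsList(config),
                                 nSubjects = length(subjects),
                                 nCompleted = sum(done),
                                 package = as.character(utils::packageVersion("motionscrub"))))
  if (sum(done) >= 5L) {
    doneRes <- results[done]
    nk <- length(doneRes[[1L]]$keptNodes)
    edgeMat <- t(vapply(doneRes, function(r) {
      cm <- connectivityMatrix(r$nodeSeries,
                               template@nodeCentroids[r$keptNodes, , drop = FALSE])
      edgeValues(cm)
    }, numeric(nk * (nk - 1) / 2)))
    cm1 <- connectivityMatrix(doneRes[[1L]]$nodeSeries,
                              template@nodeCentroids[doneRes[[1L]]$keptNodes, ,
                                                     drop = FALSE])
    qcDone <- qcTable[done, ]
    report$qcfd <- qcfdEdges(edgeMat, qcDone$meanFd, edgeDistances(cm1),
                             lowessFrac = config@lowessFrac)
    # per-subject edge values, for stringent-sample re-analyses (comparing
    # thresholds on the subjects who survive the strictest one)
    rownames(edgeMat) <- qcDone$subject
    report$qcfd$edgeMatrix <- edgeMat
    report$tsnrFd <- list(pre = tsnrFdCorrelation(qcDone, "pre"),
                          post = tsnrFdCorrelation(qcDone, "post"))
    pairsPost <- Filter(Negate(is.null), lapply(results, `[[`, "dvarsPost"))
    report$dvars <- list(
      pre = dvarsFdRegression(lapply(results, `[[`, "dvarsPre"))$pooled,
      post = dvarsFdRegression(pairsPost)$pooled)
    if (!is.null(qcDone$group) && all(table(qcDone$group) >= 3L))
      report$groupStats <- groupFdStats(qcDone, covariate = "age")
  } else {
    warning("fewer than 5 completed subjects; group statistics skipped")
  }
  structure(report, class = "msCohortReport")
}

#' @export
print.msCohortReport <- function(x, ...) {
  cat(sprintf("Cohort report: %d/%d subjects completed (FD threshold %s mm)\n",
              x$manifest$nCompleted, x$manifest$nSubjects,
              format(x$manifest$config$fdThreshold)))
  if (!is.null(x$qcfd))
    cat(sprintf("  significant QC-FD edges: %.1f %%\n",
                100 * x$qcfd$proportionSignificant))
  if (!is.null(x$tsnrFd))
    cat(sprintf("  tSNR-FD r: %.3f (pre) -> %.3f (post)\n",
                x$tsnrFd$pre$r, x$tsnrFd$post$r))
  if (!is.null(x$dvars))
    cat(sprintf("  pooled DVARS-FD r2: %.3f (pre-censor) -> %.3f (post)\n",
                x$dvars$pre$r2, x$dvars$post$r2))
  invisible(x)
}

#' @export
print.msSweepReport <- function(x, ...) {
  cat("Threshold sweep:\n")
  for (th in names(x$reports)) {
    r <- x$reports[[th]]
    cat(sprintf("  FD <= %s mm: %d completed, sig. edges %s\n", th,
                r$manifest$nCompleted,
                if (is.null(r$qcfd)) "NA" else
                  sprintf("%.1f %%", 100 * r$qcfd$proportionSignificant)))
  }
  invisible(x)
}

#' Flatten a PipelineConfig to a plain named list
#'
#' Used for serialization ([writeConfig()]) and run manifests.
#'
#' @param config a [PipelineConfig-class].
#' @return A named list of all slots.
#' @export
configAsList <- function(config) {
  sl <- methods::slotNames("PipelineConfig")
  out <- lapply(sl, function(s) methods::slot(config, s))
  names(out) <- sl
  out$classifier <- as.list(out$classifier)
  out
}
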