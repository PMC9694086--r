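#' Accessors for motionscrub data objects
#'
#' Small generic accessors so user code never touches slots directly:
#' \code{nFrames} (number of time frames), \code{repTime} (repetition time,
#' seconds), \code{voxelSize} (mm per axis), \code{runData} (the raw 4-D
#' array), \code{motionParams} (frames x 6 rigid-body parameters),
#' \code{fdValues} / \code{dvarsValues} (the per-frame series),
#' \code{nNodes} and \code{nodeCentroids} (parcel count / centroids) and
#' \code{planTable} (the per-frame censoring ledger).
#'
#' @param x a motionscrub object.
#' @return The obvious value; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("repTime", function(x) standardGeneric("repTime"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("runData", function(x) standardGeneric("runData"))
#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))
#' @rdname accessors
#' @export
setGeneric("fdValues", function(x) standardGeneric("fdValues"))
#' @rdname accessors
#' @export
setGeneric("dvarsValues", function(x) standardGeneric("dvarsValues"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("nodeCentroids", function(x) standardGeneric("nodeCentroids"))
#' @rdname accessors
#' @export
setGeneric("planTable", function(x) standardGeneric("planTable"))

#' @rdname accessors
setMethod("nFrames", "FmriRun", function(x) dim(x@data)[4L])
#' @rdname accessors
setMethod("nFrames", "MotionTrace", function(x) nrow(x@params))
#' @rdname accessors
setMethod("nFrames", "FDSeries", function(x) length(x@fd))
#' @rdname accessors
setMethod("repTime", "FmriRun", function(x) x@tr)
#' @rdname accessors
setMethod("repTime", "MotionTrace", function(x) x@tr)
#' @rdname accessors
setMethod("repTime", "FDSeries", function(x) x@tr)
#' @rdname accessors
setMethod("voxelSize", "FmriRun", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "PhantomTemplate", function(x) x@voxelSize)
#' @rdname accessors
setMethod("runData", "FmriRun", function(x) x@data)
#' @rdname accessors
setMethod("motionParams", "MotionTrace", function(x) x@params)
#' @rdname accessors
setMethod("fdValues", "FDSeries", function(x) x@fd)
#' @rdname accessors
setMethod("dvarsValues", "DvarsSeries", function(x) x@dvars)
#' @rdname accessors
setMethod("nNodes", "PhantomTemplate", function(x) nrow(x@nodeCentroids))
#' @rdname accessors
setMethod("nodeCentroids", "PhantomTemplate", function(x) x@nodeCentroids)
#' @rdname accessors
setMethod("planTable", "CensorPlan", function(x) x@table)

#' Subset the frames of a run
#'
#' `run[i]` keeps frames `i` (in order), returning a new [FmriRun-class].
#'
#' @param x an [FmriRun-class].
#' @param i frame indices or a logical mask.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FmriRun", function(x, i, j, ..., drop = FALSE) {
  FmriRun(x@data[, , , i, drop = FALSE], tr = x@tr, voxelSize = x@voxelSize)
})

#' @rdname accessors
#' @export
setMethod("nFrames", "CensorPlan", function(x) nrow(x@table))

setMethod("show", "FmriRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("FmriRun: %d x %d x %d grid, %d frames, TR %.3g s, voxels %s mm\n",
              d[1], d[2], d[3], d[4], object@tr,
              paste(signif(object@voxelSize, 3), collapse = " x ")))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d frames, TR %.3g s, reference frame %d\n",
              nrow(object@params), object@tr, object@referenceFrame))
  cat(sprintf("  max |rotation| %.4g rad, max |translation| %.4g mm\n",
              max(abs(object@params[, 1:3])), max(abs(object@params[, 4:6]))))
})

setMethod("show", "FDSeries", function(object) {
  cat(sprintf("FDSeries: %d frames, mean %.3g mm, median %.3g mm, max %.3g mm (radius %g mm)\n",
              length(object@fd), mean(object@fd), stats::median(object@fd),
              max(object@fd), object@rotationRadius))
})

setMethod("show", "DvarsSeries", function(object) {
  cat(sprintf("DvarsSeries: %d frames over %d voxels, mean %.4g\n",
              length(object@dvars), object@maskSize, mean(object@dvars)))
})

setMethod("show", "PhantomTemplate", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("PhantomTemplate: %d x %d x %d grid at %s mm, %d brain voxels, %d parcels\n",
              d[1], d[2], d[3], paste(signif(object@voxelSize, 3), collapse = "x"),
              sum(object@brainMask), nrow(object@nodeCentroids)))
})

setMethod("show", "CensorPlan", function(object) {
  tab <- object@table
  cat(sprintf("CensorPlan: %d frames, %d kept (threshold %g mm)\n",
              nrow(tab), sum(tab$kept), object@thresholdFd))
  drop <- table(tab$reason[!tab$kept])
  if (length(drop))
    cat("  dropped:", paste(sprintf("%s=%d", names(drop), drop), collapse = ", "), "\n")
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components, %d frames, %d mask voxels%s\n",
              ncol(object@maps), nrow(object@timecourses),
              length(object@maskIndex),
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d run(s), %d network(s), noise sd %.3g, target mean FD %.3g mm\n",
              length(object@motion), ncol(object@networkWeights),
              object@noiseSd, object@subjectMeanFdTarget))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  fdThreshold %g mm | nDummy %d | duration %g s | zCut %g\n",
              object@fdThreshold, object@nDummy, object@duration, object@zCut))
  cat(sprintf("  nComponents %d | rotationRadius %g mm | tsnrMode %s | seed %d\n",
              object@nComponents, object@rotationRadius, object@tsnrMode,
              object@seed))
})
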