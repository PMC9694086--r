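#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib motionscrub, .registration = TRUE
NULL

#' FmriRun: one functional acquisition
#'
#' Container for a single 4-D BOLD acquisition: an x-y-z-time intensity grid
#' together with its repetition time and voxel geometry. Intensities are in
#' arbitrary scanner units.
#'
#' @slot data 4-D numeric array (x, y, z, frame).
#' @slot tr repetition time in seconds.
#' @slot voxelSize numeric length-3, mm per axis.
#' @export
setClass("FmriRun",
  representation(data = "array", tr = "numeric", voxelSize = "numeric"))

setValidity("FmriRun", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4-D array (x, y, z, frame)")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (seconds)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive numbers (mm)")
  if (is.null(msg)) TRUE else msg
})

#' Construct an FmriRun
#'
#' @param data 4-D numeric array (x, y, z, frame).
#' @param tr repetition time in seconds.
#' @param voxelSize voxel edge lengths in mm (recycled to length 3).
#' @return An [FmriRun-class] object.
#' @examples
#' r <- FmriRun(array(rnorm(8 * 8 * 4 * 5), c(8, 8, 4, 5)), tr = 0.78)
#' nFrames(r)
#' @export
FmriRun <- function(data, tr, voxelSize = c(2.5, 2.5, 2.5)) {
  new("FmriRun", data = data, tr = as.numeric(tr),
      voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' MotionTrace: per-frame rigid-body parameters
#'
#' Six rigid-body parameters per frame in the FSL ordering: three rotations
#' (radians, about the x, y and z axes through the volume centre, applied in
#' that order) followed by three translations (mm). Parameters are relative
#' to the reference frame, whose row is all zeros.
#'
#' @slot params numeric matrix, frames x 6 (rx, ry, rz, tx, ty, tz).
#' @slot tr repetition time in seconds.
#' @slot referenceFrame index of the reference frame (1-based).
#' @export
setClass("MotionTrace",
  representation(params = "matrix", tr = "numeric", referenceFrame = "integer"))

setValidity("MotionTrace", function(object) {
  msg <- NULL
  if (ncol(object@params) != 6L)
    msg <- c(msg, "params must have 6 columns (rx, ry, rz, tx, ty, tz)")
  if (nrow(object@params) < 1L)
    msg <- c(msg, "params must have at least one row")
  if (!all(is.finite(object@params)))
    msg <- c(msg, "params must be finite")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MotionTrace
#'
#' @param params frames x 6 numeric matrix (rx, ry, rz in radians; tx, ty,
#'   tz in mm).
#' @param tr repetition time in seconds.
#' @param referenceFrame 1-based index of the reference frame.
#' @return A [MotionTrace-class] object.
#' @export
MotionTrace <- function(params, tr, referenceFrame = 1L) {
  params <- as.matrix(params)
  colnames(params) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  new("MotionTrace", params = params, tr = as.numeric(tr),
      referenceFrame = as.integer(referenceFrame))
}

#' FDSeries: framewise displacement per frame
#'
#' Framewise displacement (FD) summarises the head movement between
#' consecutive frames as the sum of absolute translation changes plus the
#' absolute rotation changes converted to arc length on a sphere of radius
#' \code{rotationRadius} (default 50 mm). \code{fd[1] == 0} by convention.
#'
#' @slot fd per-frame FD in mm.
#' @slot rotationRadius sphere radius (mm) used for the rotation terms.
#' @slot tr repetition time in seconds (carried for duration bookkeeping).
#' @export
setClass("FDSeries",
  representation(fd = "numeric", rotationRadius = "numeric", tr = "numeric"))

setValidity("FDSeries", function(object) {
  msg <- NULL
  if (length(object@fd) < 1L) msg <- c(msg, "fd must be non-empty")
  if (any(!is.finite(object@fd)) || any(object@fd < 0))
    msg <- c(msg, "fd values must be finite and non-negative")
  if (object@fd[1L] != 0) msg <- c(msg, "fd[1] must be 0 by convention")
  if (is.null(msg)) TRUE else msg
})

#' DvarsSeries: frame-to-frame intensity change
#'
#' DVARS is the root mean square over brain voxels of the intensity
#' difference between consecutive volumes; \code{dvars[1] == 0} by
#' convention. Units follow the image intensities.
#'
#' @slot dvars per-frame DVARS values.
#' @slot maskSize number of voxels in the brain mask used.
#' @export
setClass("DvarsSeries",
  representation(dvars = "numeric", maskSize = "integer"))

#' PhantomTemplate: static geometry of a synthetic brain
#'
#' Ellipsoidal "brain" with a grey-matter shell and a set of disjoint
#' parcels (nodes) drawn on the shell. All grids share one shape and voxel
#' size; parcel labels run 1..N and lie entirely inside the grey-matter
#' mask; \code{nodeCentroids} are the label-wise mean voxel coordinates in
#' mm (relative to the volume centre).
#'
#' @slot intensity 3-D baseline intensity grid (arbitrary units).
#' @slot brainMask 3-D logical array.
#' @slot gmMask 3-D logical array, subset of \code{brainMask}.
#' @slot parcellation 3-D integer array, 0 outside parcels.
#' @slot nodeCentroids N x 3 matrix of centroid coordinates (mm).
#' @slot voxelSize numeric length-3, mm.
#' @export
setClass("PhantomTemplate",
  representation(intensity = "array", brainMask = "array", gmMask = "array",
                 parcellation = "array", nodeCentroids = "matrix",
                 voxelSize = "numeric"))

setValidity("PhantomTemplate", function(object) {
  msg <- NULL
  d <- dim(object@intensity)
  if (length(d) != 3L) msg <- c(msg, "intensity must be 3-D")
  if (!identical(dim(object@brainMask), d) || !identical(dim(object@gmMask), d) ||
      !identical(dim(object@parcellation), d))
    msg <- c(msg, "all grids must share one shape")
  if (any(object@gmMask & !object@brainMask))
    msg <- c(msg, "gmMask must be a subset of brainMask")
  if (any(object@parcellation > 0 & !object@gmMask))
    msg <- c(msg, "parcels must lie inside gmMask")
  labs <- sort(unique(object@parcellation[object@parcellation > 0]))
  if (length(labs) && !identical(as.integer(labs), seq_along(labs)))
    msg <- c(msg, "parcel labels must be 1..N")
  if (length(labs) && min(tabulate(object@parcellation[object@parcellation > 0])) < 5L)
    msg <- c(msg, "each parcel must contain at least 5 voxels")
  if (length(labs) != nrow(object@nodeCentroids))
    msg <- c(msg, "nodeCentroids must have one row per parcel")
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: everything the synthetic generator knows about a subject
#'
#' Bookkeeping object recording, per run, the true motion trace and its FD
#' series, the network / artifact / confound time courses, the dropout
#' frames, and the noise level, so pipeline stages can be scored against
#' exact ground truth.
#'
#' @slot motion list of [MotionTrace-class], one per run.
#' @slot fd list of numeric FD series (the generator's own bookkeeping).
#' @slot networkTimecourses list of frames x K matrices, one per run.
#' @slot networkWeights N x K node-by-network weight matrix.
#' @slot artifactTimecourses list (per run) of named lists with elements
#'   \code{rim} and \code{slice}.
#' @slot confound list with elements \code{sourceWeights} (N x S),
#'   \code{timecourses} (per-run frames x S), \code{amplitude}.
#' @slot nodeSeries list of frames x N analytic node-level series.
#' @slot dropoutFrames list of integer vectors, one per run.
#' @slot noiseSd thermal noise standard deviation (intensity units).
#' @slot subjectMeanFdTarget target mean FD for this subject (mm).
#' @slot params named list of generator constants (artifact amplitudes,
#'   trigger, slice period, dropout exit fraction, ...).
#' @export
setClass("GroundTruth",
  representation(motion = "list", fd = "list", networkTimecourses = "list",
                 networkWeights = "matrix", artifactTimecourses = "list",
                 confound = "list", nodeSeries = "list",
                 dropoutFrames = "list", noiseSd = "numeric",
                 subjectMeanFdTarget = "numeric", params = "list"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  nr <- length(object@motion)
  if (length(object@fd) != nr || length(object@dropoutFrames) != nr)
    msg <- c(msg, "per-run slots must have one entry per run")
  for (r in seq_len(nr)) {
    nf <- nrow(object@motion[[r]]@params)
    dp <- object@dropoutFrames[[r]]
    if (length(dp) && (any(dp < 1L) || any(dp > nf)))
      msg <- c(msg, "dropoutFrames must be valid frame indices")
  }
  if (is.null(msg)) TRUE else msg
})

#' CensorPlan: per-frame keep/drop ledger for a concatenated sequence
#'
#' One row per original acquisition frame (across all runs, in order), with
#' the frame's provenance, whether it survives, why it was dropped
#' (\code{dummy}, \code{fd}, \code{fov} or \code{trim}; \code{kept}
#' otherwise) and its index in the concatenated sequence (NA if dropped).
#'
#' @slot table data.frame with columns \code{sourceRun}, \code{sourceFrame},
#'   \code{kept}, \code{reason}, \code{concatIndex}, \code{fd}.
#' @slot runBoundaries 1-based start index of each run's first surviving
#'   frame in the concatenated sequence.
#' @slot thresholdFd FD censoring threshold used (mm; \code{Inf} if none).
#' @export
setClass("CensorPlan",
  representation(table = "data.frame", runBoundaries = "integer",
                 thresholdFd = "numeric"))

setValidity("CensorPlan", function(object) {
  msg <- NULL
  need <- c("sourceRun", "sourceFrame", "kept", "reason", "concatIndex")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    tab <- object@table
    bad <- c("dummy", "fd", "fov", "trim")
    if (any(tab$kept & tab$reason != "kept"))
      msg <- c(msg, "kept frames must have reason 'kept'")
    if (any(!tab$kept & !(tab$reason %in% bad)))
      msg <- c(msg, "dropped frames need reason dummy/fd/fov/trim")
    if (anyNA(tab$concatIndex[tab$kept]))
      msg <- c(msg, "kept frames must carry a concatIndex")
  }
  if (length(object@runBoundaries)) {
    b <- object@runBoundaries
    if (b[1L] != 1L || any(diff(b) <= 0))
      msg <- c(msg, "runBoundaries must be strictly increasing and start at 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' ComponentSet: a spatial-ICA decomposition
#'
#' Holds the result of a spatial independent component analysis of an
#' in-mask data matrix: per-component spatial weight maps over the mask
#' voxels and unit-variance time courses, ordered by explained variance.
#' The outer products of maps and time courses plus the subspace residual
#' reconstruct the centred data.
#'
#' @slot maps voxels x K spatial weight matrix (mask voxels only).
#' @slot timecourses frames x K matrix, each column unit variance.
#' @slot maskIndex linear indices of the mask voxels within the volume.
#' @slot dimVol 3-D grid shape the maps refer to.
#' @slot explainedVariance per-component fraction of total data variance.
#' @slot converged logical, FALSE when the fixed-point iteration hit its
#'   iteration cap (the partial result is still returned).
#' @export
setClass("ComponentSet",
  representation(maps = "matrix", timecourses = "matrix",
                 maskIndex = "integer", dimVol = "integer",
                 explainedVariance = "numeric", converged = "logical"))

setValidity("ComponentSet", function(object) {
  msg <- NULL
  if (ncol(object@maps) != ncol(object@timecourses))
    msg <- c(msg, "maps and timecourses must agree on the component count")
  if (nrow(object@maps) != length(object@maskIndex))
    msg <- c(msg, "maps must have one row per mask voxel")
  sds <- apply(object@timecourses, 2L, stats::sd)
  if (any(abs(sds - 1) > 1e-6))
    msg <- c(msg, "timecourses must have unit variance")
  if (is.null(msg)) TRUE else msg
})

#' PipelineConfig: all tunable parameters of the preprocessing pipeline
#'
#' @slot fdThreshold FD censoring threshold in mm (frames with FD above it
#'   are dropped; \code{Inf} disables censoring).
#' @slot nDummy initial dummy volumes discarded per run.
#' @slot duration analysis duration in seconds the data are trimmed to.
#' @slot zCut standard-deviation cut for field-of-view outlier rejection.
#' @slot nComponents number of ICA components.
#' @slot rotationRadius sphere radius (mm) for the FD rotation terms.
#' @slot fCut high-frequency cutoff (Hz) for component features.
#' @slot slicePeriod slice periodicity (in slices) probed by the features.
#' @slot minVoxels minimum voxels for a parcel to enter connectivity.
#' @slot normTarget per-volume intensity normalization target.
#' @slot tsnrMode "voxelwise" or "global".
#' @slot lowessFrac lowess span for the distance profile.
#' @slot classifier named numeric vector of rule thresholds
#'   (edge, slice, highfreq, jump, gmOverride).
#' @slot applyCleanup run the ICA + aggressive-regression stage (FALSE
#'   skips it, e.g. for a censoring-only comparison arm).
#' @slot reestimate re-estimate motion even when traces are supplied.
#' @slot seed base seed funnelling all pipeline randomness.
#' @export
setClass("PipelineConfig",
  representation(fdThreshold = "numeric", nDummy = "integer",
                 duration = "numeric", zCut = "numeric",
                 nComponents = "integer", rotationRadius = "numeric",
                 fCut = "numeric", slicePeriod = "integer",
                 minVoxels = "integer", normTarget = "numeric",
                 tsnrMode = "character", lowessFrac = "numeric",
                 classifier = "numeric", applyCleanup = "logical",
                 reestimate = "logical", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- NULL
  if (object@fdThreshold <= 0) msg <- c(msg, "fdThreshold must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@zCut <= 0) msg <- c(msg, "zCut must be positive")
  if (object@nComponents < 2L) msg <- c(msg, "nComponents must be >= 2")
  if (object@rotationRadius <= 0) msg <- c(msg, "rotationRadius must be positive")
  if (!object@tsnrMode %in% c("voxelwise", "global"))
    msg <- c(msg, "tsnrMode must be 'voxelwise' or 'global'")
  need <- c("edge", "slice", "highfreq", "jump", "gmOverride")
  if (!all(need %in% names(object@classifier)))
    msg <- c(msg, "classifier must name edge, slice, highfreq, jump, gmOverride")
  if (is.null(msg)) TRUE else msg
})
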