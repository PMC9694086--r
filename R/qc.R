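#' Temporal signal-to-noise ratio
#'
#' In the primary ("voxelwise") mode, each in-mask voxel's temporal mean is
#' divided by its temporal SD and the ratios are averaged over the mask;
#' voxels with zero temporal SD are excluded with a warning. The "global"
#' mode instead takes the mean in-mask time series and returns its mean
#' over SD. Both are invariant to global intensity rescaling.
#'
#' @param run an [FmriRun-class] with at least 8 frames.
#' @param brainMask 3-D logical array.
#' @param mode "voxelwise" (default) or "global".
#' @return A list with \code{tsnr} (scalar) and, in voxelwise mode,
#'   \code{map} (per-mask-voxel tSNR, NA where excluded).
#' @export
computeTSNR <- function(run, brainMask, mode = c("voxelwise", "global")) {
  mode <- match.arg(mode)
  stopifnot(is(run, "FmriRun"))
  idx <- which(brainMask)
  if (!length(idx)) stop("brain mask is empty")
  nt <- nFrames(run)
  if (nt < 8L) stop("need at least 8 frames")
  x <- matrix(run@data, ncol = nt)[idx, , drop = FALSE]
  if (mode == "global") {
    g <- colMeans(x)
    if (stats::sd(g) == 0) stop("global time series is constant")
    return(list(tsnr = mean(g) / stats::sd(g)))
  }
  m <- rowMeans(x)
  s <- sqrt(pmax(rowSums((x - m)^2) / (nt - 1), 0))
  if (all(s == 0)) stop("all in-mask voxels are temporally constant")
  map <- ifelse(s > 0, m / s, NA_real_)
  if (any(s == 0))
    warning(sum(s == 0), " temporally constant voxel(s) excluded from tSNR")
  list(tsnr = mean(map, na.rm = TRUE), map = map)
}

#' Mean time series per parcel
#'
#' Averages the run over each parcel's voxels, dropping parcels with fewer
#' than \code{minVoxels} voxels (the node-inclusion rule).
#'
#' @param run an [FmriRun-class].
#' @param parcellation 3-D integer label array (0 = background).
#' @param minVoxels minimum voxels for a node to be kept (default 5).
#' @return A list: \code{series} (frames x nodes matrix, columns named by
#'   label), \code{keptNodes}, \code{droppedNodes}.
#' @export
parcelTimeseries <- function(run, parcellation, minVoxels = 5L) {
  stopifnot(is(run, "FmriRun"))
  idx <- which(parcellation > 0)
  if (!length(idx)) stop("parcellation has no labels")
  lab <- parcellation[idx]
  counts <- tabulate(lab)
  keep <- which(counts >= minVoxels)
  if (!length(keep)) stop("no parcel meets the minimum voxel count")
  nt <- nFrames(run)
  x <- matrix(run@data, ncol = nt)[idx, , drop = FALSE]
  sums <- rowsum(x, lab)
  series <- t(sums[keep, , drop = FALSE] / counts[keep])
  colnames(series) <- keep
  list(series = series, keptNodes = keep,
       droppedNodes = setdiff(which(counts > 0), keep))
}

#' ConnectivityMatrix: parcel-wise functional connectivity
#'
#' Pearson correlations between all node pairs, with centroid Euclidean
#' distances for the distance-dependence diagnostics. Symmetric, unit
#' diagonal; edges involving a constant node are NA.
#'
#' @slot mat node x node correlation matrix.
#' @slot distances node x node centroid distances (mm).
#' @export
setClass("ConnectivityMatrix",
  representation(mat = "matrix", distances = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- NULL
  m <- object@mat
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(m[is.finite(m)]) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!identical(dim(object@distances), dim(m)))
    msg <- c(msg, "distances must match the matrix shape")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@mat)
  cat(sprintf("ConnectivityMatrix: %d nodes, %d edges, mean r %.3f\n",
              n, n * (n - 1) / 2, mean(edgeValues(object), na.rm = TRUE)))
})

#' @rdname accessors
#' @export
setGeneric("edgeValues", function(x) standardGeneric("edgeValues"))
#' @rdname accessors
#' @export
setGeneric("edgeDistances", function(x) standardGeneric("edgeDistances"))
#' @rdname accessors
setMethod("edgeValues", "ConnectivityMatrix",
          function(x) x@mat[upper.tri(x@mat)])
#' @rdname accessors
setMethod("edgeDistances", "ConnectivityMatrix",
          function(x) x@distances[upper.tri(x@distances)])

#' Build a connectivity matrix from node time series
#'
#' @param series frames x nodes matrix (as from [parcelTimeseries()]).
#' @param centroids nodes x 3 centroid coordinates in mm.
#' @return A [ConnectivityMatrix-class]; constant nodes yield NA edges and
#'   a warning.
#' @export
connectivityMatrix <- function(series, centroids) {
  stopifnot(ncol(series) >= 2L, nrow(series) >= 3L,
            nrow(centroids) == ncol(series))
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant node(s); their edges are undefined (NA)")
  mat <- suppressWarnings(stats::cor(series))
  diag(mat) <- 1
  new("ConnectivityMatrix", mat = mat,
      distances = as.matrix(stats::dist(centroids)))
}

#' Edge-wise QC-FD analysis across subjects
#'
#' For every edge, the Pearson correlation across subjects between the edge
#' value and the subject's mean FD, with a two-sided t-test p-value; the
#' headline number is the proportion of edges with p < 0.05 (uncorrected --
#' the benchmark is the 5 % chance level). The correlation is also profiled
#' against internodal distance with a lowess fit, since motion inflates
#' short-range connectivity.
#'
#' @param edgeMatrix subjects x edges matrix of edge values.
#' @param meanFd per-subject mean FD (mm).
#' @param distances per-edge internodal distance (mm).
#' @param lowessFrac lowess smoother span (default 2/3).
#' @param fisherZ apply the Fisher z-transform to edge values first.
#' @return A list with \code{edgeR}, \code{edgeP},
#'   \code{proportionSignificant}, \code{distanceProfile} (data.frame
#'   distance/r) and \code{lowessFit}.
#' @export
qcfdEdges <- function(edgeMatrix, meanFd, distances, lowessFrac = 2/3,
                      fisherZ = FALSE) {
  n <- nrow(edgeMatrix)
  if (n < 5L) stop("need at least 5 subjects")
  if (length(meanFd) != n) stop("meanFd must have one value per subject")
  if (stats::sd(meanFd) == 0) stop("mean FD has zero variance across subjects")
  if (fisherZ) edgeMatrix <- atanh(pmin(pmax(edgeMatrix, -1 + 1e-12), 1 - 1e-12))
  r <- as.numeric(stats::cor(edgeMatrix, meanFd))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  prof <- data.frame(distance = distances, r = r)
  fit <- stats::lowess(distances, r, f = lowessFrac)
  list(edgeR = r, edgeP = p, proportionSignificant = mean(p < 0.05),
       distanceProfile = prof, lowessFit = fit)
}

#' Correlation of tSNR with mean FD across subjects
#'
#' The headline QC-FD number for image quality: Pearson r (with two-sided
#' p) between per-subject tSNR -- before or after cleanup -- and mean FD.
#'
#' @param qcTable data.frame with columns \code{meanFd}, \code{tsnrPre},
#'   \code{tsnrPost}.
#' @param stage "pre" or "post" cleanup.
#' @return list with \code{r} and \code{p}.
#' @export
tsnrFdCorrelation <- function(qcTable, stage = c("pre", "post")) {
  stage <- match.arg(stage)
  y <- qcTable[[if (stage == "pre") "tsnrPre" else "tsnrPost"]]
  ok <- is.finite(y) & is.finite(qcTable$meanFd)
  if (sum(ok) < 5L) stop("need at least 5 subjects with finite values")
  if (stats::sd(y[ok]) == 0 || stats::sd(qcTable$meanFd[ok]) == 0)
    stop("zero variance in tSNR or mean FD")
  ct <- stats::cor.test(qcTable$meanFd[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' DVARS-FD regression, per subject and pooled
#'
#' Ordinary least squares of DVARS on FD over frames (frame 1, where both
#' are 0 by convention, is dropped), per subject and pooled over all
#' subjects' frames. High r-squared means data variance is driven by
#' motion; censoring should reduce the pooled r-squared.
#'
#' @param pairs list of per-subject lists with elements \code{fd} and
#'   \code{dvars} (equal-length numeric vectors, frame 1 included).
#' @return A list with \code{perSubject} (data.frame slope, intercept, r2)
#'   and \code{pooled} (slope, intercept, r2). Subjects with constant FD
#'   are skipped with a warning.
#' @export
dvarsFdRegression <- function(pairs) {
  per <- data.frame(subject = seq_along(pairs), slope = NA_real_,
                    intercept = NA_real_, r2 = NA_real_)
  allFd <- numeric(0); allDv <- numeric(0)
  for (i in seq_along(pairs)) {
    fd <- pairs[[i]]$fd[-1L]
    dv <- pairs[[i]]$dvars[-1L]
    if (length(fd) < 10L) stop("need at least 10 paired frames per subject")
    if (stats::sd(fd) == 0) {
      warning("subject ", i, " has constant FD; skipped")
      next
    }
    fit <- stats::lm.fit(cbind(1, fd), dv)
    per$slope[i] <- fit$coefficients[2L]
    per$intercept[i] <- fit$coefficients[1L]
    per$r2[i] <- 1 - sum(fit$residuals^2) / sum((dv - mean(dv))^2)
    allFd <- c(allFd, fd); allDv <- c(allDv, dv)
  }
  fit <- stats::lm.fit(cbind(1, allFd), allDv)
  pooled <- list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r2 = 1 - sum(fit$residuals^2) / sum((allDv - mean(allDv))^2))
  list(perSubject = per, pooled = pooled)
}

#' Group statistics of mean FD
#'
#' Per-group mean and SD of subject mean FD, a Welch two-sample test
#' between the two groups, and (optionally) the Pearson correlation of
#' mean FD with a continuous covariate such as age.
#'
#' @param qcTable data.frame with \code{meanFd} and the group column.
#' @param group name of the (two-level) group column.
#' @param covariate optional name of a numeric covariate column.
#' @return A list: \code{groups} (data.frame group/n/mean/sd),
#'   \code{test} (Welch htest), \code{difference} (mean difference,
#'   level 2 minus level 1), and \code{covariate} (r, p) when requested.
#' @export
groupFdStats <- function(qcTable, group = "group", covariate = NULL) {
  g <- factor(qcTable[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (any(table(g) < 3L)) stop("need at least 3 subjects per group")
  fd <- qcTable$meanFd
  gs <- data.frame(group = levels(g),
                   n = as.integer(table(g)),
                   mean = as.numeric(tapply(fd, g, mean)),
                   sd = as.numeric(tapply(fd, g, stats::sd)))
  tt <- stats::t.test(fd ~ g)
  out <- list(groups = gs, test = tt,
              difference = gs$mean[2L] - gs$mean[1L])
  if (!is.null(covariate)) {
    ct <- stats::cor.test(fd, qcTable[[covariate]])
    out$covariate <- list(name = covariate, r = unname(ct$estimate),
                          p = ct$p.value)
  }
  out
}
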