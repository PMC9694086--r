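#' Build a synthetic brain phantom template
#'
#' Constructs an ellipsoidal "brain" on a regular grid: a smooth baseline
#' intensity (brighter towards the centre), a brain mask, a grey-matter
#' shell inside it, and \code{nNodes} disjoint parcels drawn on the shell by
#' farthest-point seeding followed by nearest-seed (Voronoi) assignment
#' capped at a maximum radius. Node centroids are the label-wise mean voxel
#' coordinates in mm, relative to the volume centre.
#'
#' @param gridShape three integers (each >= 12), the grid dimensions.
#' @param voxelSize voxel edge length in mm (scalar or length 3).
#' @param nNodes number of parcels to place (>= 2); every parcel is
#'   guaranteed at least 5 voxels or an error is raised.
#' @param seed integer seed; the template is deterministic given it.
#' @return A [PhantomTemplate-class].
#' @examples
#' tpl <- makePhantom(c(32, 32, 24), 2.5, nNodes = 10, seed = 1)
#' nNodes(tpl)
#' @export
makePhantom <- function(gridShape = c(32, 32, 24), voxelSize = 2.5,
                        nNodes = 10, seed = 1) {
  stopifnot(length(gridShape) == 3L, all(gridShape >= 12), nNodes >= 2)
  gridShape <- as.integer(gridShape)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  set.seed(as.integer(seed))

  ax <- lapply(1:3, function(a)
    (seq_len(gridShape[a]) - (gridShape[a] + 1) / 2) * voxelSize[a])
  # unequal semi-axes: a rotationally symmetric phantom would leave
  # rotations unidentifiable for the realignment stage
  semi <- c(0.42, 0.36, 0.40) * gridShape * voxelSize
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+")
  brain <- r2 <= 1
  # thin cortical shell (~25 % of brain volume): the gm-override
  # classification rule needs grey matter to be a selective region
  gm <- r2 >= 0.80^2 & r2 <= 0.92^2
  intensity <- array(0, gridShape)
  intensity[brain] <- 1000 * (1.15 - 0.35 * r2[brain])
  # grey-matter brightening as a smooth radial bump (a hard step would be
  # un-EPI-like and dominate interpolation error)
  intensity <- intensity + brain * 100 * exp(-((sqrt(r2) - 0.86) / 0.13)^2)
  # off-centre dark "ventricle" blob: breaks the remaining near-symmetry
  d2 <- outer(outer((ax[[1]] / semi[1] - 0.30)^2, (ax[[2]] / semi[2] - 0.12)^2,
                    "+"), (ax[[3]] / semi[3] - 0.08)^2, "+")
  intensity <- intensity * (1 - 0.35 * exp(-d2 / (2 * 0.18^2)))
  # smooth internal "anatomy": a handful of broad bright/dark blobs so the
  # image has the non-radial structure realignment needs
  for (b in 1:8) {
    ctr <- stats::runif(3, -0.5, 0.5)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 60, 130)
    sig <- stats::runif(1, 0.16, 0.26)
    b2 <- outer(outer((ax[[1]] / semi[1] - ctr[1])^2,
                      (ax[[2]] / semi[2] - ctr[2])^2, "+"),
                (ax[[3]] / semi[3] - ctr[3])^2, "+")
    intensity <- intensity + brain * amp * exp(-b2 / (2 * sig^2))
  }
  # soft edge: taper the outer 20 % of the radius so the image rolls off
  # over ~2 voxels as real EPI does (also keeps trilinear resampling
  # losses small)
  taper <- pmin(1, pmax(0, (1 - sqrt(r2)) / 0.20))
  intensity <- intensity * taper

  # parcels on the grey-matter shell
  shellIdx <- which(gm)
  co <- arrayInd(shellIdx, gridShape)
  mm <- cbind(ax[[1]][co[, 1]], ax[[2]][co[, 2]], ax[[3]][co[, 3]])
  if (length(shellIdx) < 5L * nNodes)
    stop("cannot place parcels: grey-matter shell too small for ", nNodes,
         " nodes of >= 5 voxels")
  seeds <- integer(nNodes)
  seeds[1] <- sample.int(length(shellIdx), 1L)
  dmin <- sqrt(colSums((t(mm) - mm[seeds[1], ])^2))
  if (nNodes > 1) for (k in 2:nNodes) {
    seeds[k] <- which.max(dmin)
    dmin <- pmin(dmin, sqrt(colSums((t(mm) - mm[seeds[k], ])^2)))
  }
  dSeed <- vapply(seeds, function(s) sqrt(colSums((t(mm) - mm[s, ])^2)),
                  numeric(nrow(mm)))
  nearest <- max.col(-dSeed, ties.method = "first")
  within <- dSeed[cbind(seq_len(nrow(mm)), nearest)] <= 3 * mean(voxelSize)
  lab <- ifelse(within, nearest, 0L)
  counts <- tabulate(lab[lab > 0L], nbins = nNodes)
  if (any(counts < 5L))
    stop("cannot place parcels: ", sum(counts < 5L), " of ", nNodes,
         " nodes would have fewer than 5 voxels at this resolution")
  parcellation <- array(0L, gridShape)
  parcellation[shellIdx] <- as.integer(lab)
  centroids <- t(vapply(seq_len(nNodes), function(k)
    colMeans(mm[lab == k, , drop = FALSE]), numeric(3)))
  colnames(centroids) <- c("x", "y", "z")

  new("PhantomTemplate", intensity = intensity, brainMask = brain,
      gmMask = gm, parcellation = parcellation, nodeCentroids = centroids,
      voxelSize = voxelSize)
}

# erode a logical 3-D mask by one voxel (6-connectivity)
.erode1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, a, by) {
    r <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by > 0) { dst[[a]] <- (1 + by):d[a]; src[[a]] <- 1:(d[a] - by) }
    else        { dst[[a]] <- 1:(d[a] + by); src[[a]] <- (1 - by):d[a] }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (a in 1:3) for (b in c(-1L, 1L)) out <- out & shift(mask, a, b)
  out
}

#' Brain-rim mask of a phantom
#'
#' The one-voxel-thick outer shell of the brain mask (brain minus its
#' 6-connected erosion), the locus of motion-locked edge-ring artifacts.
#'
#' @param template a [PhantomTemplate-class].
#' @param width shell thickness in voxels.
#' @return 3-D logical array.
#' @export
rimMask <- function(template, width = 1L) {
  m <- template@brainMask
  e <- m
  for (i in seq_len(width)) e <- .erode1(e)
  m & !e
}

# slice mask for the periodic artifact: every `period`-th z slice, within brain
.sliceMask <- function(template, period = 4L, phase = 1L) {
  d <- dim(template@brainMask)
  sel <- ((seq_len(d[3]) - phase) %% period) == 0L
  m <- array(FALSE, d)
  m[, , sel] <- TRUE
  m & template@brainMask
}
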