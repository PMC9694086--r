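#' Per-volume intensity normalization
#'
#' Rescales every frame so its mean intensity over the brain mask equals
#' \code{target} (10,000 by default), removing arbitrary scanner scale
#' differences between runs before decomposition. Idempotent, and invariant
#' to any global rescaling of the input.
#'
#' @param run an [FmriRun-class].
#' @param brainMask 3-D logical array.
#' @param target target in-mask mean.
#' @return A normalized [FmriRun-class].
#' @export
normalizeIntensity <- function(run, brainMask, target = 10000) {
  stopifnot(is(run, "FmriRun"))
  idx <- which(brainMask)
  if (!length(idx)) stop("brain mask is empty")
  nt <- nFrames(run)
  x <- matrix(run@data, ncol = nt)
  m <- colMeans(x[idx, , drop = FALSE])
  if (any(m <= 0))
    stop("frame(s) with non-positive in-mask mean cannot be normalized: ",
         paste(which(m <= 0), collapse = ", "))
  x <- sweep(x, 2L, target / m, "*")
  FmriRun(array(x, dim(run@data)), tr = run@tr, voxelSize = run@voxelSize)
}

#' Spatial ICA of a 4-D run
#'
#' Decomposes the in-mask data into \code{nComponents} spatially
#' independent components: voxelwise temporal means are removed, the data
#' are reduced to the top \code{nComponents} principal components, and a
#' symmetric fixed-point iteration with the tanh contrast maximizes spatial
#' independence. Components are returned with unit-variance time courses
#' (spatial maps absorb the scale), positively skewed maps (sign
#' convention) and ordered by explained variance, so a decomposition is
#' fully deterministic given the seed.
#'
#' @param run an [FmriRun-class].
#' @param brainMask 3-D logical array.
#' @param nComponents number of components (< frames and < mask voxels).
#' @param seed integer seed for the random orthogonal initialization.
#' @param maxit,tol fixed-point iteration cap and convergence tolerance on
#'   the rotation update.
#' @return A [ComponentSet-class]; if the iteration cap is hit a warning is
#'   issued and \code{converged} is FALSE (the partial result is returned).
#' @export
decomposeICA <- function(run, brainMask, nComponents = 60L, seed = 1L,
                         maxit = 200L, tol = 1e-4) {
  stopifnot(is(run, "FmriRun"))
  idx <- which(brainMask)
  nt <- nFrames(run)
  K <- as.integer(nComponents)
  if (K >= nt) stop("nComponents must be smaller than the frame count")
  if (K >= length(idx)) stop("nComponents must be smaller than the mask size")
  X <- t(matrix(run@data, ncol = nt)[idx, , drop = FALSE])  # T x V
  X <- X - rep(colMeans(X), each = nt)                      # centre voxels
  V <- ncol(X)
  totSS <- sum(X^2)
  if (totSS == 0) stop("data are constant; nothing to decompose")

  # temporal-covariance PCA (T x T), then whitened spatial matrix Z (K x V)
  eg <- eigen(tcrossprod(X) / V, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(K)], .Machine$double.eps)
  U <- eg$vectors[, seq_len(K), drop = FALSE]
  Z <- crossprod(U / rep(sqrt(lam), each = nt), X)  # rows: unit variance

  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(K * K), K, K)
  sym <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    crossprod(t(e$vectors) / sqrt(pmax(e$values, .Machine$double.eps)),
              t(e$vectors)) %*% W
  }
  W <- sym(W)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    S <- W %*% Z
    G <- tanh(S)
    W1 <- sym(tcrossprod(G, Z) / V - diag(rowMeans(1 - G^2)) %*% W)
    delta <- max(abs(abs(diag(tcrossprod(W1, W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fixed-point iteration did not converge in ", maxit,
            " iterations; returning partial result")
  S <- W %*% Z                               # K x V spatial sources
  A <- U %*% (diag(sqrt(lam), K) %*% t(W))   # T x K mixing (time courses)

  # unit-variance time courses; maps carry the scale; deterministic sign
  sdA <- apply(A, 2L, stats::sd)
  sdA[sdA == 0] <- 1
  A <- sweep(A, 2L, sdA, "/")
  S <- S * sdA
  for (k in seq_len(K)) {
    sg <- sum(S[k, ]^3)
    if (sg == 0) sg <- S[k, which.max(abs(S[k, ]))]
    if (sg < 0) { S[k, ] <- -S[k, ]; A[, k] <- -A[, k] }
  }
  ev <- colSums(A^2) * rowSums(S^2) / totSS
  ord <- order(ev, decreasing = TRUE)
  new("ComponentSet", maps = t(S)[, ord, drop = FALSE],
      timecourses = A[, ord, drop = FALSE], maskIndex = as.integer(idx),
      dimVol = as.integer(dim(run@data)[1:3]),
      explainedVariance = ev[ord], converged = converged)
}

#' Spatial, spectral and temporal features of ICA components
#'
#' Computes, per component, the hand-labeling features used to separate
#' signal from noise: \code{edgeFraction} (share of absolute spatial weight
#' on the brain rim), \code{gmOverlap} (share on grey matter),
#' \code{highfreqFraction} (share of off-DC temporal spectral power above
#' \code{fCut}), \code{slicePeriodicity} (normalized spectral peak of the
#' slice-wise mean absolute weight at a period of \code{slicePeriod}
#' slices) and \code{jumpScore} (largest time-course step over the robust
#' SD of the steps).
#'
#' @param components a [ComponentSet-class].
#' @param template the [PhantomTemplate-class] (or any object with brain,
#'   grey-matter and rim geometry) the maps are aligned with.
#' @param tr repetition time in seconds (> 0).
#' @param fCut high-frequency cutoff in Hz.
#' @param slicePeriod probed slice period.
#' @return data.frame, one row per component.
#' @export
extractComponentFeatures <- function(components, template, tr,
                                     fCut = 0.1, slicePeriod = 4L) {
  stopifnot(is(components, "ComponentSet"), is(template, "PhantomTemplate"))
  if (tr <= 0) stop("tr must be positive")
  idx <- components@maskIndex
  d <- components@dimVol
  rim <- which(rimMask(template))
  gm <- which(template@gmMask)
  inRim <- idx %in% rim
  inGm <- idx %in% gm
  zOf <- arrayInd(idx, d)[, 3]
  nz <- d[3]
  tgtBin <- round(nz / slicePeriod) + 1L
  halfZ <- 2:(floor(nz / 2) + 1L)
  nt <- nrow(components@timecourses)
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  halfT <- 2:(floor(nt / 2) + 1L)

  K <- ncol(components@maps)
  out <- data.frame(component = seq_len(K), edgeFraction = NA_real_,
                    gmOverlap = NA_real_, highfreqFraction = NA_real_,
                    slicePeriodicity = NA_real_, jumpScore = NA_real_)
  for (k in seq_len(K)) {
    w <- abs(components@maps[, k])
    # robust map thresholding (as mixture-model thresholding does for real
    # ICA maps): spatial fractions are computed over supra-threshold mass,
    # otherwise the flat noise floor dilutes every fraction toward the
    # mask-wide base rate
    cut <- stats::median(w) + 2 * stats::mad(w)
    w <- pmax(w - cut, 0)
    if (sum(w) == 0) w <- abs(components@maps[, k])
    tot <- sum(w)
    if (tot == 0) tot <- 1
    out$edgeFraction[k] <- sum(w[inRim]) / tot
    out$gmOverlap[k] <- sum(w[inGm]) / tot
    prof <- rep(0, nz)
    mz <- tapply(w, zOf, mean)
    prof[as.integer(names(mz))] <- mz
    pz <- Mod(stats::fft(prof - mean(prof)))^2
    denomZ <- sum(pz[halfZ])
    out$slicePeriodicity[k] <- if (denomZ > 0) pz[tgtBin] / denomZ else 0
    tc <- components@timecourses[, k]
    pt <- Mod(stats::fft(tc - mean(tc)))^2
    denomT <- sum(pt[halfT])
    out$highfreqFraction[k] <-
      if (denomT > 0) sum(pt[halfT][freqs[halfT] > fCut]) / denomT else 0
    dtc <- diff(tc)
    md <- stats::mad(dtc)
    out$jumpScore[k] <- if (md > 0) max(abs(dtc)) / md
                        else if (max(abs(dtc)) > 0) Inf else 0
  }
  out
}

#' Rule-based signal/noise labeling of components
#'
#' A component is called noise when any noise rule fires -- rim-dominated
#' map, slice-periodic map, predominantly high-frequency time course, or a
#' sudden-jump time course -- unless its grey-matter overlap exceeds the
#' override threshold, in which case it is protected as signal (grey-matter
#' structure is the strongest signal indicator). The rule(s) that fired are
#' recorded per component.
#'
#' @param features data.frame from [extractComponentFeatures()].
#' @param thresholds named numeric vector with elements \code{edge},
#'   \code{slice}, \code{highfreq}, \code{jump}, \code{gmOverride}.
#' @return data.frame with columns \code{component}, \code{label}
#'   ("signal"/"noise") and \code{ruleTrace}.
#' @export
classifyComponents <- function(features,
                               thresholds = c(edge = 0.45, slice = 0.30,
                                              highfreq = 0.50, jump = 6.0,
                                              gmOverride = 0.68)) {
  stopifnot(all(c("edge", "slice", "highfreq", "jump", "gmOverride") %in%
                names(thresholds)))
  rules <- cbind(edge = features$edgeFraction > thresholds["edge"],
                 slice = features$slicePeriodicity > thresholds["slice"],
                 highfreq = features$highfreqFraction > thresholds["highfreq"],
                 jump = features$jumpScore > thresholds["jump"])
  fired <- apply(rules, 1L, function(r) paste(colnames(rules)[r], collapse = ","))
  override <- features$gmOverlap >= thresholds["gmOverride"]
  noise <- rowSums(rules) > 0 & !override
  data.frame(component = features$component,
             label = ifelse(noise, "noise", "signal"),
             ruleTrace = ifelse(noise, fired,
                                ifelse(rowSums(rules) > 0, "gm-override", "none")))
}

#' Aggressive cleanup: regress noise time courses out of the data
#'
#' Performs the "aggressive" denoising step: every in-mask voxel time
#' series is regressed on all noise-labeled component time courses (plus an
#' intercept) and replaced by intercept + residual, so the cleaned data
#' share no variance with any noise time course (residual correlations are
#' zero to numerical precision). Collinear noise columns are dropped with a
#' warning. Voxels outside the decomposition mask are left untouched.
#'
#' @param run the [FmriRun-class] the components were computed from.
#' @param components a [ComponentSet-class].
#' @param labels data.frame from [classifyComponents()] (or any with
#'   columns \code{component}, \code{label}).
#' @return The cleaned [FmriRun-class]; with no noise components, the
#'   input is returned unchanged.
#' @export
aggressiveCleanup <- function(run, components, labels) {
  stopifnot(is(run, "FmriRun"), is(components, "ComponentSet"))
  nt <- nFrames(run)
  if (nrow(components@timecourses) != nt)
    stop("component time courses must match the frame count")
  noiseIdx <- labels$component[labels$label == "noise"]
  if (!length(noiseIdx)) return(run)
  N <- components@timecourses[, noiseIdx, drop = FALSE]
  N <- sweep(N, 2L, colMeans(N))
  qrN <- qr(N)
  if (qrN$rank < ncol(N)) {
    warning("dropping ", ncol(N) - qrN$rank,
            " collinear noise time course(s)")
    N <- N[, qrN$pivot[seq_len(qrN$rank)], drop = FALSE]
  }
  idx <- components@maskIndex
  x <- matrix(run@data, ncol = nt)
  Y <- t(x[idx, , drop = FALSE])            # T x V
  B <- qr.coef(qr(cbind(1, N)), Y)          # intercept + noise betas
  Y <- Y - N %*% B[-1L, , drop = FALSE]     # keep intercept in the data
  x[idx, ] <- t(Y)
  FmriRun(array(x, dim(run@data)), tr = run@tr, voxelSize = run@voxelSize)
}
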