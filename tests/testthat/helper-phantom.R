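# shared fixtures, built once per test run and cached
.msTestCache <- new.env(parent = emptyenv())

# default-geometry template (the study conditions: 32x32x24 at 2.5 mm)
msTemplate <- function() {
  if (is.null(.msTestCache$tpl))
    .msTestCache$tpl <- makePhantom(c(32, 32, 24), 2.5, nNodes = 12, seed = 1)
  .msTestCache$tpl
}

# small template for cheap geometric tests
msSmallTemplate <- function() {
  if (is.null(.msTestCache$tplSmall))
    .msTestCache$tplSmall <- makePhantom(c(20, 20, 16), 2.5, nNodes = 6, seed = 3)
  .msTestCache$tplSmall
}

# a rendered single-run subject with moderate motion (cached)
msRenderedSubject <- function() {
  if (is.null(.msTestCache$subj)) {
    tpl <- msTemplate()
    trc <- simulateMotionTrace(200, 0.78, targetMeanFd = 0.35, seed = 21)
    truth <- makeGroundTruth(tpl, list(trc), seed = 22)
    run <- renderRun(tpl, truth, run = 1, seed = 23)
    .msTestCache$subj <- list(template = tpl, trace = trc, truth = truth,
                              run = run)
  }
  .msTestCache$subj
}

# stack a list of 3-D volumes into an FmriRun
msStackRun <- function(vols, tr = 0.78, voxelSize = 2.5) {
  arr <- array(unlist(vols, use.names = FALSE),
               c(dim(vols[[1]]), length(vols)))
  FmriRun(arr, tr = tr, voxelSize = voxelSize)
}
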