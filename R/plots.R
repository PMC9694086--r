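#' Quick-look QC plots
#'
#' Base-graphics summaries of a cohort report: subject retention by
#' censoring threshold, tSNR against mean FD, the QC-FD distance profile
#' with its lowess fit, and pooled DVARS against FD.
#'
#' @param report an \code{msCohortReport} from [runCohort()].
#' @param which one of "retention", "tsnrFd", "distance".
#' @param ... passed to the underlying plot call.
#' @return Invisibly, NULL; called for the plot side effect.
#' @export
plotCohortQC <- function(report, which = c("retention", "tsnrFd", "distance"),
                         ...) {
  which <- match.arg(which)
  if (which == "retention") {
    ret <- report$retention
    graphics::plot(ret$threshold, ret$nRetained, type = "b", pch = 19,
                   xlab = "FD threshold (mm)", ylab = "subjects retained",
                   ylim = c(0, max(ret$nRetained)), ...)
  } else if (which == "tsnrFd") {
    qc <- report$qcTable[report$qcTable$status == "completed", ]
    graphics::plot(qc$meanFd, qc$tsnrPre, pch = 1,
                   xlab = "mean FD (mm)", ylab = "tSNR",
                   ylim = range(c(qc$tsnrPre, qc$tsnrPost)), ...)
    graphics::points(qc$meanFd, qc$tsnrPost, pch = 19)
    graphics::legend("topright", pch = c(1, 19),
                     legend = c("before cleanup", "after cleanup"))
  } else {
    if (is.null(report$qcfd)) stop("report carries no edge-wise QC-FD result")
    prof <- report$qcfd$distanceProfile
    graphics::plot(prof$distance, prof$r, pch = 16, col = "grey50",
                   xlab = "internodal distance (mm)",
                   ylab = "edge-FD correlation (r)", ...)
    graphics::lines(report$qcfd$lowessFit, lwd = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(NULL)
}
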