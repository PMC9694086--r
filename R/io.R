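#' Read and write runs as NIfTI-1
#'
#' Runs are stored as standard 4-D NIfTI-1 images; the voxel size goes into
#' pixdim 1-3 and the repetition time into pixdim 4.
#'
#' @param run an [FmriRun-class].
#' @param path file path (".nii" or ".nii.gz").
#' @return \code{writeRunNifti} returns \code{path} invisibly;
#'   \code{readRunNifti} returns an [FmriRun-class].
#' @export
writeRunNifti <- function(run, path) {
  stopifnot(is(run, "FmriRun"))
  img <- RNifti::asNifti(run@data)
  RNifti::pixdim(img) <- c(run@voxelSize, run@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeRunNifti
#' @param tr repetition time override (seconds); taken from pixdim 4 when
#'   NULL.
#' @export
readRunNifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) {
    if (length(pd) >= 4L && pd[4L] > 0) tr <- pd[4L]
    else stop("no TR in the file; supply tr=")
  }
  FmriRun(array(as.numeric(img), dim(img)), tr = tr, voxelSize = pd[1:3])
}

#' Read and write motion traces in the FSL .par dialect
#'
#' Six whitespace-separated columns, one row per frame: rotations in
#' radians (x, y, z) first, then translations in mm.
#'
#' @param trace a [MotionTrace-class].
#' @param path file path.
#' @return \code{writeMotionTrace} returns \code{path} invisibly;
#'   \code{readMotionTrace} a [MotionTrace-class].
#' @export
writeMotionTrace <- function(trace, path) {
  stopifnot(is(trace, "MotionTrace"))
  utils::write.table(format(trace@params, digits = 10, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMotionTrace
#' @param tr repetition time in seconds (not stored in .par files).
#' @export
readMotionTrace <- function(path, tr) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("a .par file must have 6 columns")
  MotionTrace(unname(m), tr = tr)
}

#' Write a per-frame series as single-column TSV
#'
#' Used for FD and DVARS series: a header line with the series name, then
#' one value per frame.
#'
#' @param x an [FDSeries-class], [DvarsSeries-class] or numeric vector.
#' @param path file path.
#' @param name column header (defaults to the series type).
#' @return \code{path}, invisibly.
#' @export
writeSeriesTSV <- function(x, path, name = NULL) {
  v <- if (is(x, "FDSeries")) x@fd else if (is(x, "DvarsSeries")) x@dvars else x
  if (is.null(name))
    name <- if (is(x, "FDSeries")) "fd" else if (is(x, "DvarsSeries")) "dvars"
            else "value"
  utils::write.table(stats::setNames(data.frame(v), name), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write censor plans as TSV
#'
#' The per-frame ledger is written as a TSV with two comment header lines
#' carrying the FD threshold and the run boundaries.
#'
#' @param plan a [CensorPlan-class].
#' @param path file path.
#' @return \code{writeCensorPlan} returns \code{path} invisibly;
#'   \code{readCensorPlan} a [CensorPlan-class].
#' @export
writeCensorPlan <- function(plan, path) {
  stopifnot(is(plan, "CensorPlan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# thresholdFd\t%.17g", plan@thresholdFd),
               paste0("# runBoundaries\t",
                      paste(plan@runBoundaries, collapse = ","))), con)
  utils::write.table(plan@table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCensorPlan
#' @export
readCensorPlan <- function(path) {
  hdr <- readLines(path, n = 2L)
  th <- as.numeric(sub("^# thresholdFd\t", "", hdr[1L]))
  rb <- as.integer(strsplit(sub("^# runBoundaries\t", "", hdr[2L]), ",")[[1L]])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                           stringsAsFactors = FALSE)
  new("CensorPlan", table = tab, runBoundaries = rb, thresholdFd = th)
}

#' Read and write noise-component labels in the FIX text style
#'
#' One "index, label" line per component, then a final line with a
#' bracketed, comma-separated, 1-based list of the noise components, e.g.
#' \code{[2, 7, 13]} -- the format downstream regression tools consume.
#'
#' @param labels data.frame from [classifyComponents()].
#' @param path file path.
#' @return \code{writeNoiseLabels} returns \code{path} invisibly;
#'   \code{readNoiseLabels} the integer noise indices.
#' @export
writeNoiseLabels <- function(labels, path) {
  noise <- labels$component[labels$label == "noise"]
  lines <- c(sprintf("%d, %s", labels$component, labels$label),
             paste0("[", paste(noise, collapse = ", "), "]"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNoiseLabels
#' @export
readNoiseLabels <- function(path) {
  lines <- readLines(path)
  last <- trimws(lines[length(lines)])
  if (!grepl("^\\[.*\\]$", last)) stop("last line must be a bracketed list")
  inner <- trimws(gsub("^\\[|\\]$", "", last))
  if (!nzchar(inner)) return(integer(0))
  as.integer(strsplit(inner, ",")[[1L]])
}

#' Read and write pipeline configurations as YAML
#'
#' Serialization round-trips losslessly through [configAsList()].
#'
#' @param config a [PipelineConfig-class].
#' @param path file path.
#' @return \code{writeConfig} returns \code{path} invisibly;
#'   \code{readConfig} a [PipelineConfig-class].
#' @export
writeConfig <- function(config, path) {
  lst <- configAsList(config)
  lst$fdThreshold <- if (is.finite(lst$fdThreshold)) lst$fdThreshold else ".inf"
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$classifier <- unlist(lst$classifier)
  if (identical(lst$fdThreshold, ".inf")) lst$fdThreshold <- Inf
  do.call(pipelineConfig, lst)
}

#' Write a cohort report as JSON
#'
#' Serializes the scalar parts of an \code{msCohortReport} (QC table,
#' retention, headline QC-FD numbers, manifest) to JSON.
#'
#' @param report an \code{msCohortReport} from [runCohort()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  out <- list(manifest = report$manifest,
              qcTable = report$qcTable,
              retention = report$retention)
  if (!is.null(report$qcfd))
    out$qcfd <- list(proportionSignificant = report$qcfd$proportionSignificant)
  if (!is.null(report$tsnrFd))
    out$tsnrFd <- list(pre = report$tsnrFd$pre, post = report$tsnrFd$post)
  if (!is.null(report$dvars)) out$dvars <- report$dvars
  if (!is.null(report$groupStats))
    out$groupStats <- list(groups = report$groupStats$groups,
                           difference = report$groupStats$difference,
                           p = report$groupStats$test$p.value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a subject's ground truth as TSV + JSON sidecar
#'
#' Per-run FD series and dropout frames as TSV, generator constants and
#' scalar truth as a JSON sidecar; lets rendered phantoms be consumed
#' outside R.
#'
#' @param truth a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The sidecar path, invisibly.
#' @export
writeGroundTruth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(truth@fd))
    writeSeriesTSV(truth@fd[[r]],
                   file.path(dir, sprintf("%s_run%d_fd.tsv", prefix, r)),
                   name = "fd")
  side <- list(nRuns = length(truth@fd), noiseSd = truth@noiseSd,
               subjectMeanFdTarget = truth@subjectMeanFdTarget,
               dropoutFrames = truth@dropoutFrames, params = truth@params,
               confoundAmplitude = truth@confound$amplitude)
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
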