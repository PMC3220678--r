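## TIFF/CSV/YAML plumbing: assemble Fields from files, write them back, and
## round-trip measurement tables and configurations.

.readGray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]   # collapse to one channel
    storage.mode(m) <- "double"
    m
  })
}

#' Load a Field from TIFF files
#'
#' Accepts either a directory laid out as \code{live_01.tif, live_02.tif,
#' ...} (zero-padded acquisition index; alternatively a single multi-page
#' \code{live.tif} in acquisition order) plus \code{fixed_target.tif} and
#' \code{fixed_nuclear.tif}, or an explicit list with elements \code{live}
#' (paths in order, or one multi-page file), \code{fixedTarget} and
#' \code{fixedNuclear}. Validity masks are all-true on load.
#'
#' @param paths directory path or named list of file paths.
#' @param fieldId field identifier (defaults to the directory name).
#' @param frameIntervalMin minutes between live frames.
#' @param bitDepth camera bit depth.
#' @return A \linkS4class{Field}.
#' @export
loadField <- function(paths, fieldId = NULL, frameIntervalMin = 10,
                      bitDepth = 12L) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    live <- sort(Sys.glob(file.path(paths, "live_*.tif*")))
    if (!length(live)) live <- file.path(paths, "live.tif")
    paths <- list(live = live,
                  fixedTarget = file.path(paths, "fixed_target.tif"),
                  fixedNuclear = file.path(paths, "fixed_nuclear.tif"))
    if (is.null(fieldId)) fieldId <- basename(dirname(paths$fixedTarget))
  }
  if (!is.list(paths) ||
      !all(c("live", "fixedTarget", "fixedNuclear") %in% names(paths)))
    stop("'paths' must be a directory or a list with 'live', 'fixedTarget', ",
         "'fixedNuclear'")
  if (is.null(fieldId)) fieldId <- "field"
  frames <- unlist(lapply(paths$live, .readGray), recursive = FALSE)
  fixedT <- .readGray(paths$fixedTarget)[[1]]
  fixedN <- .readGray(paths$fixedNuclear)[[1]]
  shapes <- unique(vapply(c(frames, list(fixedT), list(fixedN)),
                          function(m) paste(dim(m), collapse = "x"), ""))
  if (length(shapes) != 1L)
    stop("images differ in shape: ", paste(shapes, collapse = ", "))
  Field(frames, fixedT, fixedN, fieldId = fieldId,
        frameIntervalMin = frameIntervalMin, bitDepth = bitDepth)
}

#' Write a Field as TIFF files
#'
#' Writes \code{live_01.tif ...}, \code{fixed_target.tif} and
#' \code{fixed_nuclear.tif} into a directory, as 16-bit grayscale. Integer
#' pixel values up to 65535 round-trip exactly through
#' \code{\link{loadField}}.
#'
#' @param field a \linkS4class{Field}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeField <- function(field, dir) {
  stopifnot(is(field, "Field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(m, f)
    tiff::writeTIFF(pmin(pmax(m, 0), 65535) / 65535, file.path(dir, f),
                    bits.per.sample = 16L)
  for (i in seq_len(nFrames(field)))
    w(field@liveFrames[[i]]@pixels, sprintf("live_%02d.tif", i))
  w(field@fixedTarget@pixels, "fixed_target.tif")
  w(field@fixedNuclear@pixels, "fixed_nuclear.tif")
  invisible(dir)
}

#' Write / read a measurement table
#'
#' One row per (cell, frame), stable column order, header always present; a
#' written table read back is numerically identical (within 1e-9). An empty
#' table writes a header-only CSV.
#'
#' @param rows data.frame of per-cell per-frame measurements.
#' @param path CSV path.
#' @return \code{writeMeasurements}: invisibly, the path.
#' @export
writeMeasurements <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write measurements to: ", path)
  invisible(path)
}

#' @rdname writeMeasurements
#' @return \code{readMeasurements}: the data.frame.
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a pipeline configuration
#'
#' YAML (\code{.yml}/\code{.yaml}) or JSON, keyed by the
#' \linkS4class{PipelineConfig} constructor arguments.
#'
#' @param path configuration file path.
#' @return \code{readPipelineConfig}: a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(PipelineConfig, cfg)
}

#' @rdname readPipelineConfig
#' @param config a \linkS4class{PipelineConfig} to write.
#' @return \code{writePipelineConfig}: invisibly, the path.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  lst <- list(d = config@d, e = config@e, alpha = config@alpha,
              maxShift = config@maxShift,
              minAreaFraction = config@minAreaFraction,
              logSigma = config@logSigma, seed = config@seed)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
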