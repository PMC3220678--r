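## End-to-end orchestration of the retrospective pipeline.

#' Measure nuclear and cytoplasmic intensities across a registered series
#'
#' For every registered frame and every cell, computes the mean and
#' population s.d. of the target-protein intensity over the valid pixels of
#' the (eroded) nuclear region, and the mean over the cytoplasmic region.
#'
#' @param frames list of registered \linkS4class{IntensityImage}.
#' @param erodedNuclei eroded nuclear \linkS4class{LabelMap}.
#' @param cytoplasm cytoplasmic \linkS4class{LabelMap}.
#' @param frameIntervalMin minutes between frames (frame i is at i x interval).
#' @return data.frame with one row per (cell, frame): \code{cell_id},
#'   \code{frame}, \code{t_min}, \code{nuclear_mean}, \code{nuclear_sd},
#'   \code{nuclear_area}, \code{cyto_mean}, \code{cyto_area}, \code{flag}.
#' @export
measureField <- function(frames, erodedNuclei, cytoplasm,
                         frameIntervalMin = 10) {
  stopifnot(is(erodedNuclei, "LabelMap"), is(cytoplasm, "LabelMap"))
  ids <- cellIds(erodedNuclei)
  labN <- erodedNuclei@labels
  labC <- cytoplasm@labels
  idxN <- split(which(labN > 0L), labN[labN > 0L])
  idxC <- split(which(labC > 0L), labC[labC > 0L])
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- .asIntensityImage(frames[[i]])
    px <- fr@pixels; ok <- fr@valid
    nm <- nsd <- cm <- rep(NA_real_, length(ids))
    na_ <- ca <- integer(length(ids))
    flag <- character(length(ids))
    for (k in seq_along(ids)) {
      key <- as.character(ids[k])
      iN <- idxN[[key]]; iN <- iN[ok[iN]]
      iC <- idxC[[key]]; iC <- iC[ok[iC]]
      na_[k] <- length(iN); ca[k] <- length(iC)
      if (length(iN) >= 2L) {
        v <- px[iN]
        nm[k] <- mean(v)
        nsd[k] <- sqrt(mean((v - nm[k])^2))
      } else flag[k] <- "too_few_pixels"
      if (length(iC)) cm[k] <- mean(px[iC])
      else flag[k] <- paste0(flag[k], ifelse(flag[k] == "", "", ";"),
                             "empty_cytoplasm")
    }
    out[[i]] <- data.frame(cell_id = ids, frame = i,
      t_min = i * frameIntervalMin, nuclear_mean = nm, nuclear_sd = nsd,
      nuclear_area = na_, cyto_mean = cm, cyto_area = ca, flag = flag)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the retrospective pipeline on one field
#'
#' Registers the live series to the fixed-cell reference, segments nuclei
#' from the fixed nuclear stain and assigns cytoplasm from the first
#' registered frame, erodes the nuclear masks, excludes cells touching image
#' edges or registration borders, measures every frame, builds per-cell
#' traces, and (when a control fit is supplied) classifies each mask as
#' matched or mismatched-or-false from the first-frame statistics.
#'
#' @param field a \linkS4class{Field}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param controlFit optional \linkS4class{RobustFit} from a stationary
#'   control population (see \code{\link{controlMaskStats}}).
#' @return list with \code{shifts}, \code{registered} (frames), \code{nuclei},
#'   \code{cytoplasm}, \code{erodedNuclei}, \code{edgeExcluded},
#'   \code{measurements}, \code{traces} and \code{classes} (NULL without a
#'   control fit). Measurements and traces cover non-edge cells only.
#' @export
analyzeField <- function(field, config = PipelineConfig(),
                         controlFit = NULL) {
  stopifnot(is(field, "Field"), is(config, "PipelineConfig"))
  reg <- registerSeries(field, maxShift = config@maxShift)
  nuclei <- segmentNuclei(fixedNuclear(field),
                          minAreaFraction = config@minAreaFraction,
                          logSigma = config@logSigma)
  if (!length(cellIds(nuclei)))
    return(list(shifts = reg$shifts, registered = reg$frames,
                nuclei = nuclei, cytoplasm = NULL, erodedNuclei = NULL,
                edgeExcluded = logical(), measurements = NULL, traces = NULL,
                classes = NULL))
  cyto <- assignCytoplasm(reg$frames[[1]], nuclei, d = config@d)
  eroded <- erodeNuclei(nuclei, e = config@e)
  excl <- excludeEdgeCells(nuclei, cyto, reg$frames)
  keep <- as.integer(names(excl))[!excl]

  meas <- measureField(reg$frames, eroded, cyto,
                       frameIntervalMin = frameInterval(field))
  meas <- meas[meas$cell_id %in% keep, ]
  traces <- buildCellTraces(meas)

  classes <- NULL
  if (!is.null(controlFit)) {
    s1 <- measureMaskStats(reg$frames[[1]], eroded)
    s1 <- s1[s1$cell_id %in% keep, ]
    classes <- classifyMasks(s1, controlFit)
  }
  list(shifts = reg$shifts, registered = reg$frames, nuclei = nuclei,
       cytoplasm = cyto, erodedNuclei = eroded, edgeExcluded = excl,
       measurements = meas, traces = traces, classes = classes)
}

#' First-frame mask statistics of a cell-movement control
#'
#' Registers a control field (typically a single live frame plus the fixed
#' pair), segments and erodes its nuclei, and returns the per-nucleus
#' mean/s.d. statistics of the first registered frame — the population to
#' which the robust s.d.-vs-mean line is fitted.
#'
#' @param field a control \linkS4class{Field}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame as from \code{\link{measureMaskStats}}.
#' @export
controlMaskStats <- function(field, config = PipelineConfig()) {
  stopifnot(is(field, "Field"))
  reg <- registerSeries(field, maxShift = config@maxShift)
  nuclei <- segmentNuclei(fixedNuclear(field),
                          minAreaFraction = config@minAreaFraction,
                          logSigma = config@logSigma)
  eroded <- erodeNuclei(nuclei, e = config@e)
  measureMaskStats(reg$frames[[1]], eroded)
}
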