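## Translocation descriptors and kinetic summaries. All descriptors are
## ratios of per-cell nuclear/cytoplasmic mean intensities, hence invariant
## under a global multiplicative intensity gain.

#' Nuclear-to-cytoplasmic ratio, normalized at time 0
#'
#' (nuclear mean / cytoplasmic mean) divided by the same cell's ratio at the
#' first frame, so every trace starts at 1.
#'
#' @param nuclearMean,cytoplasmicMean per-frame mean intensities.
#' @param baselineRatio the cell's un-normalized ratio at the first frame.
#' @return Numeric; NA (with a warning) where a denominator is non-positive.
#' @export
ncRatio <- function(nuclearMean, cytoplasmicMean, baselineRatio) {
  n <- max(length(nuclearMean), length(cytoplasmicMean),
           length(baselineRatio))
  nm <- rep_len(nuclearMean, n)
  cm <- rep_len(cytoplasmicMean, n)
  b <- rep_len(baselineRatio, n)
  out <- ifelse(cm > 0 & b > 0, (nm / cm) / b, NA_real_)
  if (anyNA(out)) warning("non-positive denominator: value undefined")
  out
}

#' Nuclear accumulation (NA)
#'
#' A nucleus's mean intensity divided by the same nucleus's mean at time 0,
#' normalizing away per-cell expression differences.
#'
#' @param nuclearMeanT mean intensity at time t.
#' @param nuclearMeanT0 mean intensity at the first frame.
#' @return Numeric; NA (with a warning) where the baseline is non-positive.
#' @export
nuclearAccumulation <- function(nuclearMeanT, nuclearMeanT0) {
  n <- max(length(nuclearMeanT), length(nuclearMeanT0))
  t <- rep_len(nuclearMeanT, n)
  t0 <- rep_len(nuclearMeanT0, n)
  out <- ifelse(t0 > 0, t / t0, NA_real_)
  if (anyNA(out)) warning("non-positive baseline: value undefined")
  out
}

#' Nuclear increment (NI)
#'
#' Frame-to-frame change of the nuclear mean normalized by the first frame's
#' mean: (I_i - I_{i-1}) / I_1, a direct proxy of translocation speed.
#'
#' @param meanI nuclear mean at frame i.
#' @param meanPrev nuclear mean at frame i-1.
#' @param meanFirst nuclear mean at the first frame.
#' @return Numeric; NA (with a warning) where the first-frame mean is
#'   non-positive.
#' @export
nuclearIncrement <- function(meanI, meanPrev, meanFirst) {
  n <- max(length(meanI), length(meanPrev), length(meanFirst))
  mi <- rep_len(meanI, n)
  mp <- rep_len(meanPrev, n)
  m1 <- rep_len(meanFirst, n)
  out <- ifelse(m1 > 0, (mi - mp) / m1, NA_real_)
  if (anyNA(out)) warning("non-positive first-frame mean: value undefined")
  out
}

#' Difference variation between two measurements
#'
#' |v1 - v2| / (v1 + v2), in [0, 1]: a normalized disagreement between two
#' measurements of the same quantity (e.g. the same descriptor computed from
#' two mask settings). The more reliable descriptor yields the smaller
#' difference variation.
#'
#' @param value1,value2 non-negative measurements.
#' @return Numeric in [0, 1]; NA (with a warning) where the sum is zero.
#' @export
differenceVariation <- function(value1, value2) {
  if (any(value1 < 0 | value2 < 0, na.rm = TRUE))
    stop("values must be non-negative")
  out <- ifelse(value1 + value2 > 0,
                abs(value1 - value2) / (value1 + value2), NA_real_)
  if (anyNA(out)) warning("zero sum: difference variation undefined")
  out
}

#' Build per-cell traces from a measurement table
#'
#' Computes, per cell and frame, nuclear accumulation (\code{na}), the
#' normalized N:C ratio (\code{nc_ratio}), the raw un-normalized ratio
#' (\code{raw_nc}) and the nuclear increment (\code{ni}; NA at the first
#' frame), from per-frame nuclear and cytoplasmic means.
#'
#' @param measurements data.frame with columns \code{cell_id}, \code{frame},
#'   \code{t_min}, \code{nuclear_mean}, \code{cyto_mean} (one row per cell and
#'   frame), as from \code{\link{measureField}}.
#' @return data.frame in long format: \code{cell_id}, \code{frame},
#'   \code{t_min}, \code{na}, \code{nc_ratio}, \code{raw_nc}, \code{ni}.
#' @export
buildCellTraces <- function(measurements) {
  need <- c("cell_id", "frame", "t_min", "nuclear_mean", "cyto_mean")
  if (!all(need %in% names(measurements)))
    stop("missing columns: ", paste(setdiff(need, names(measurements)),
                                    collapse = ", "))
  measurements <- measurements[order(measurements$cell_id,
                                     measurements$frame), ]
  parts <- split(measurements, measurements$cell_id)
  out <- lapply(parts, function(df) {
    nm <- df$nuclear_mean; cm <- df$cyto_mean
    rawNC <- ifelse(cm > 0, nm / cm, NA_real_)
    data.frame(cell_id = df$cell_id, frame = df$frame, t_min = df$t_min,
      na = suppressWarnings(nuclearAccumulation(nm, nm[1])),
      nc_ratio = if (is.finite(rawNC[1]) && rawNC[1] > 0)
        rawNC / rawNC[1] else NA_real_,
      raw_nc = rawNC,
      ni = c(NA_real_,
             suppressWarnings(nuclearIncrement(nm[-1], nm[-length(nm)],
                                               nm[1]))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call responders from pre/post-treatment N:C ratios
#'
#' The threshold is the 95th percentile (linear interpolation between order
#' statistics) of the un-normalized pre-treatment N:C ratios: fewer than 5% of
#' unstimulated cells exceed it, so a cell whose end-point ratio does is
#' deemed to have responded.
#'
#' @param preRatios un-normalized N:C ratios of the pre-treatment population.
#' @param postRatios un-normalized end-point N:C ratios, one per cell.
#' @return list with \code{threshold} and logical \code{responder} (same
#'   order as \code{postRatios}).
#' @export
callResponders <- function(preRatios, postRatios) {
  preRatios <- preRatios[is.finite(preRatios)]
  if (length(preRatios) < 20L)
    warning("fewer than 20 pre-treatment cells: percentile is unstable")
  thr <- stats::quantile(preRatios, 0.95, type = 7, names = FALSE)
  list(threshold = thr, responder = postRatios > thr)
}

#' Time at which nuclear import reaches maximum speed
#'
#' The nuclear increment is more sensitive to noise than nuclear
#' accumulation, so it is re-computed on a 20-minute grid (differences over
#' \code{intervalMin / frame interval} frames, same first-frame denominator)
#' and the grid time with the maximal increment is returned, ties going to the
#' earliest. Times are reported as minutes elapsed since the first frame.
#'
#' @param nuclearMean per-frame nuclear means of one cell (>= 3 frames).
#' @param tMin acquisition times in minutes (equally spaced).
#' @param intervalMin grid spacing in minutes (default 20).
#' @return Elapsed minutes of maximal increment, or NA if undefined.
#' @export
timeToMaxSpeed <- function(nuclearMean, tMin, intervalMin = 20) {
  n <- length(nuclearMean)
  if (n < 3L) stop("at least 3 frames are required")
  if (length(tMin) != n) stop("'tMin' must match 'nuclearMean'")
  dt <- diff(tMin)[1]
  step <- max(1L, as.integer(round(intervalMin / dt)))
  idx <- seq(1L + step, n, by = step)
  if (!length(idx) || !is.finite(nuclearMean[1]) || nuclearMean[1] <= 0)
    return(NA_real_)
  ni <- (nuclearMean[idx] - nuclearMean[idx - step]) / nuclearMean[1]
  if (all(!is.finite(ni))) return(NA_real_)
  tGrid <- tMin[idx] - tMin[1]
  ## increments within a relative 1e-6 of the maximum count as tied, and the
  ## earliest tied grid time wins; this keeps the tie rule stable when an
  ## inflection sits exactly on a grid boundary
  best <- max(ni, na.rm = TRUE)
  tol <- 1e-6 * max(abs(best), 1e-12)
  tGrid[which(ni >= best - tol)[1]]
}

#' Population summaries per frame and stratum
#'
#' Median, 5th/95th percentiles, mean and s.d. of a descriptor per frame, for
#' all cells and separately for matched and mismatched-or-false cells as
#' labelled by the mask classifier.
#'
#' @param traces data.frame from \code{\link{buildCellTraces}}.
#' @param classes data.frame from \code{\link{classifyMasks}}; may be NULL, in
#'   which case only the \code{"all"} stratum is produced.
#' @param descriptor one of \code{"na"}, \code{"nc_ratio"}, \code{"ni"}.
#' @return data.frame with \code{stratum}, \code{frame}, \code{t_min},
#'   \code{median}, \code{p05}, \code{p95}, \code{mean}, \code{sd},
#'   \code{n_cells}.
#' @export
summarizePopulation <- function(traces, classes = NULL,
                                descriptor = c("na", "nc_ratio", "ni")) {
  descriptor <- match.arg(descriptor)
  strata <- list(all = unique(traces$cell_id))
  if (!is.null(classes)) {
    strata$matched_only <-
      classes$cell_id[classes$label == "matched"]
    strata$mismatched_or_false <-
      classes$cell_id[classes$label == "mismatched_or_false"]
  }
  out <- list()
  for (s in names(strata)) {
    sub <- traces[traces$cell_id %in% strata[[s]], ]
    if (!nrow(sub)) {
      message("stratum '", s, "' is empty; summary omitted")
      next
    }
    for (f in sort(unique(sub$frame))) {
      v <- sub[[descriptor]][sub$frame == f]
      v <- v[is.finite(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(stratum = s, frame = f,
        t_min = sub$t_min[sub$frame == f][1], median = q[2], p05 = q[1],
        p95 = q[3], mean = mean(v), sd = stats::sd(v), n_cells = length(v))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation with a two-sided p-value, used to test
#' whether cell-level factors (expression level, cell size, ...) correlate
#' with translocation descriptors.
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @return list with \code{rho} and \code{p}; \code{rho} is NA for constant
#'   input.
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 5L) stop("at least 5 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
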