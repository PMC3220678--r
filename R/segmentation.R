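## Nuclear and cytoplasmic segmentation from the fixed nuclear-stain image
## and the first registered target-protein frame. Morphology, distance
## transforms and watershed come from EBImage; the Otsu threshold is computed
## on the valid-pixel histogram only, so registration borders never bias it.

#' Otsu threshold of the valid-pixel histogram
#'
#' Returns the intensity threshold maximizing the between-class variance of
#' the histogram of valid pixels. Integer-valued images are binned at their
#' integer levels; continuous images into 256 equal-width bins. Foreground is
#' \code{pixels > threshold}. The result depends only on the histogram shape,
#' not on absolute counts.
#'
#' @param image \linkS4class{IntensityImage} or numeric matrix.
#' @return Numeric threshold.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' otsuThreshold(img)
#' @export
otsuThreshold <- function(image) {
  image <- .asIntensityImage(image)
  v <- image@pixels[image@valid]
  if (length(unique(v)) < 2L)
    stop("Otsu threshold undefined for a constant image")
  isInt <- all(v == round(v)) && diff(range(v)) <= 65535
  if (isInt) {
    lev <- seq(min(v), max(v))
    cnt <- tabulate(v - min(v) + 1L, nbins = length(lev))
  } else {
    br <- seq(min(v), max(v), length.out = 257)
    cnt <- graphics::hist(v, breaks = br, plot = FALSE)$counts
    lev <- br[-length(br)]
  }
  p <- cnt / sum(cnt)
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[length(mu)]
  k <- seq_len(length(lev) - 1L)
  sb <- (muT * omega[k] - mu[k])^2 / (omega[k] * (1 - omega[k]))
  sb[!is.finite(sb)] <- -Inf
  as.numeric(lev[which.max(sb)])
}

## Laplacian-of-Gaussian kernel, zero-sum
.logKernel <- function(sigma) {
  hw <- ceiling(3.5 * sigma)
  g <- seq(-hw, hw)
  xx <- outer(g^2, g^2, "+")
  k <- (xx - 2 * sigma^2) / sigma^4 * exp(-xx / (2 * sigma^2))
  k - mean(k)
}

.labelAreas <- function(lab) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) return(integer())
  stats::setNames(tabulate(lab, nbins = max(ids))[ids], ids)
}

## relabel 1..K preserving the order of the original label values
.relabel <- function(lab, keepIds) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keepIds)) out[lab == keepIds[i]] <- i
  out
}

#' Remove undersized label regions
#'
#' Removes regions whose area falls below \code{minAreaFraction} times the
#' mean area of all candidate regions, the rule used to discard noise-driven
#' artifact masks after watershed splitting. Surviving regions are relabelled
#' 1..K in the order of their original labels.
#'
#' @param map a \linkS4class{LabelMap}.
#' @param minAreaFraction fraction of the mean candidate area (default 0.5).
#' @return A \linkS4class{LabelMap}; metadata records the cutoff and removed
#'   labels.
#' @examples
#' ## areas 100, 100, 30: mean 76.67, cutoff 38.33, the 30-px region removed
#' lab <- matrix(0L, 40, 40)
#' lab[2:11, 2:11] <- 1L; lab[2:11, 21:30] <- 2L; lab[25:30, 25:29] <- 3L
#' sizeFilter(LabelMap(lab, "nuclear"))
#' @export
sizeFilter <- function(map, minAreaFraction = 0.5) {
  stopifnot(is(map, "LabelMap"))
  areas <- .labelAreas(map@labels)
  if (!length(areas)) return(map)
  cutoff <- minAreaFraction * mean(areas)
  keep <- as.integer(names(areas))[areas >= cutoff]
  removed <- setdiff(as.integer(names(areas)), keep)
  LabelMap(.relabel(map@labels, keep), map@kind,
           metadata = c(map@metadata,
                        list(sizeCutoff = cutoff, removedLabels = removed)))
}

#' Segment nuclei from the fixed nuclear-stain image
#'
#' Five-step pipeline: (1) Laplacian-of-Gaussian edge detection, whose
#' negative inner response band traces closed contours just inside each
#' nuclear edge; (2) a 1-px closing and flood fill of the contour interiors to
#' produce candidate masks; (3) intersection with the Otsu foreground of the
#' nuclear image to suppress noise-driven false masks; (4) distance-transform
#' watershed splitting of touching candidates; (5) removal of components
#' smaller than \code{minAreaFraction} times the mean candidate area.
#'
#' @param nuclearImage \linkS4class{IntensityImage} or matrix: the fixed
#'   nuclear-stain channel.
#' @param minAreaFraction size-filter fraction (default 0.5).
#' @param logSigma Laplacian-of-Gaussian scale in pixels (default 3).
#' @param edgeThreshold multiple of the robust spread of the LoG response used
#'   to binarize the inner edge band (default 2).
#' @param minCandidateArea absolute area floor in pixels: candidate components
#'   smaller than this are discarded as noise before the relative size filter
#'   (default 30, about a disk of radius 3).
#' @return A nuclear \linkS4class{LabelMap}. If no candidate nuclei are found
#'   an empty map is returned with a warning.
#' @export
segmentNuclei <- function(nuclearImage, minAreaFraction = 0.5, logSigma = 3,
                          edgeThreshold = 2, minCandidateArea = 30L) {
  nuclearImage <- .asIntensityImage(nuclearImage)
  img <- nuclearImage@pixels
  if (any(!nuclearImage@valid))
    img[!nuclearImage@valid] <- stats::median(img[nuclearImage@valid])
  resp <- EBImage::filter2(img, .logKernel(logSigma))
  thr <- edgeThreshold * stats::mad(as.vector(resp))
  ring <- resp < -thr
  ring <- EBImage::dilate(ring + 0, EBImage::makeBrush(3, "box")) > 0
  cand <- EBImage::fillHull(ring + 0) > 0
  fg <- img > otsuThreshold(nuclearImage)
  cand <- cand & fg & nuclearImage@valid
  ## a field without nuclear signal produces only noise-driven candidates:
  ## genuine nuclei must stand clearly above the rest of the image
  contrastOK <- any(cand) &&
    mean(img[cand]) > mean(img[!cand]) + 2 * stats::sd(img[!cand])
  if (!contrastOK) {
    warning("no candidate nuclei found")
    return(LabelMap(matrix(0L, nrow(img), ncol(img)), "nuclear",
                    metadata = list(logSigma = logSigma)))
  }
  dm <- EBImage::distmap(cand + 0)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 5)
  lab <- round(EBImage::imageData(ws))
  storage.mode(lab) <- "integer"
  ## absolute floor: noise-driven specks never enter the relative size filter
  areas <- .labelAreas(lab)
  keep <- as.integer(names(areas))[areas >= minCandidateArea]
  if (!length(keep)) {
    warning("no candidate nuclei found")
    return(LabelMap(matrix(0L, nrow(img), ncol(img)), "nuclear",
                    metadata = list(logSigma = logSigma)))
  }
  lab <- .relabel(lab, keep)
  out <- sizeFilter(LabelMap(lab, "nuclear",
                             metadata = list(logSigma = logSigma,
                                             edgeThreshold = edgeThreshold)),
                    minAreaFraction)
  if (!length(cellIds(out))) warning("no nuclei survived the size filter")
  out
}

#' Assign cytoplasm to segmented nuclei
#'
#' The first registered target-protein frame has the strongest cytoplasmic
#' signal, so its Otsu foreground defines the cell areas. The foreground is
#' partitioned among cells by seeded watershed with the nuclei as seeds; each
#' cell's final cytoplasm is the intersection of its nucleus dilated by
#' \code{d} pixels with its watershed territory and the foreground, minus
#' every nucleus.
#'
#' @param firstFrame \linkS4class{IntensityImage} or matrix: the first
#'   registered live frame.
#' @param nuclei nuclear \linkS4class{LabelMap}.
#' @param d integer dilation distance in pixels, 6..20.
#' @return A cytoplasmic \linkS4class{LabelMap} sharing the nuclear label
#'   space; cells with an empty cytoplasm are listed in
#'   \code{metadata$emptyCytoplasm}.
#' @export
assignCytoplasm <- function(firstFrame, nuclei, d) {
  firstFrame <- .asIntensityImage(firstFrame)
  stopifnot(is(nuclei, "LabelMap"))
  d <- as.integer(d)
  if (d < 6L || d > 20L) stop("'d' must be in 6..20")
  lab <- nuclei@labels
  if (!length(cellIds(nuclei))) stop("'nuclei' contains no labelled regions")
  if (!identical(dim(lab), dim(firstFrame@pixels)))
    stop("label map and image must share dimensions")

  img <- firstFrame@pixels
  fg <- img > otsuThreshold(firstFrame)
  fg[!firstFrame@valid] <- FALSE
  fg <- fg | lab > 0L
  terr <- EBImage::propagate(img, seeds = lab, mask = fg)
  terr <- round(EBImage::imageData(terr))

  dd <- dim(lab)
  out <- matrix(0L, dd[1], dd[2])
  empty <- integer()
  for (k in cellIds(nuclei)) {
    pos <- which(lab == k, arr.ind = TRUE)
    r0 <- max(1L, min(pos[, 1]) - d - 1L); r1 <- min(dd[1], max(pos[, 1]) + d + 1L)
    c0 <- max(1L, min(pos[, 2]) - d - 1L); c1 <- min(dd[2], max(pos[, 2]) + d + 1L)
    nucLocal <- lab[r0:r1, c0:c1] == k
    distToNuc <- EBImage::distmap((!nucLocal) + 0)
    sel <- distToNuc <= d & terr[r0:r1, c0:c1] == k & fg[r0:r1, c0:c1] &
      lab[r0:r1, c0:c1] == 0L & !nucLocal
    if (!any(sel)) empty <- c(empty, k)
    sub <- out[r0:r1, c0:c1]; sub[sel] <- k; out[r0:r1, c0:c1] <- sub
  }
  LabelMap(out, "cytoplasmic",
           metadata = list(d = d, emptyCytoplasm = empty))
}

#' Erode nuclear masks
#'
#' Each labelled region is eroded by a Euclidean disk of radius \code{e}
#' pixels, removing pixels adjacent to the nuclear boundary so that
#' cross-contamination between nuclear and cytoplasmic fluorescence does not
#' bias the nuclear statistics. Labels are preserved; regions eroded to
#' extinction are dropped and listed in \code{metadata$extinct}.
#'
#' @param nuclei nuclear \linkS4class{LabelMap}.
#' @param e integer erosion distance in pixels, 2..6.
#' @return An eroded nuclear \linkS4class{LabelMap}.
#' @export
erodeNuclei <- function(nuclei, e) {
  stopifnot(is(nuclei, "LabelMap"))
  e <- as.integer(e)
  if (e < 2L || e > 6L) stop("'e' must be in 2..6")
  lab <- nuclei@labels
  ids <- cellIds(nuclei)
  if (!length(ids))
    return(LabelMap(lab, nuclei@kind,
                    metadata = c(nuclei@metadata, list(e = e, extinct = integer()))))
  K <- max(ids)
  brush <- EBImage::makeBrush(2L * e + 1L, "disc")
  ## per-label erosion: a pixel survives iff the whole disk around it carries
  ## its own label, i.e. the min and max filters agree there; background is
  ## mapped to a sentinel distinct from every label so it breaks the equality
  x <- lab / (K + 2)
  x[lab == 0L] <- (K + 1) / (K + 2)
  mn <- EBImage::erode(x, brush)
  mx <- EBImage::dilate(x, brush)
  keep <- (mn == mx) & lab > 0L
  out <- lab
  out[!keep] <- 0L
  extinct <- setdiff(ids, unique(as.vector(out)))
  if (length(extinct))
    warning("region(s) eroded to extinction: ",
            paste(extinct, collapse = ", "))
  LabelMap(out, nuclei@kind,
           metadata = c(nuclei@metadata, list(e = e, extinct = extinct)))
}

#' Flag cells touching image edges or registration borders
#'
#' A cell is excluded from quantification if any pixel of its nucleus or
#' cytoplasm lies on (or is 8-adjacent to) the image border or a pixel that is
#' invalid in any registered frame, because such a cell was not fully observed
#' at some point of the time course.
#'
#' @param nuclei,cytoplasm \linkS4class{LabelMap}s sharing the label space.
#' @param registeredFrames list of registered \linkS4class{IntensityImage}.
#' @return Named logical vector: \code{TRUE} = excluded.
#' @export
excludeEdgeCells <- function(nuclei, cytoplasm, registeredFrames) {
  stopifnot(is(nuclei, "LabelMap"), is(cytoplasm, "LabelMap"))
  d <- dim(nuclei@labels)
  bad <- matrix(FALSE, d[1], d[2])
  bad[c(1, d[1]), ] <- TRUE
  bad[, c(1, d[2])] <- TRUE
  for (fr in registeredFrames) {
    fr <- .asIntensityImage(fr)
    if (!identical(dim(fr@valid), d))
      stop("frames and label maps must share dimensions")
    bad <- bad | !fr@valid
  }
  bad <- EBImage::dilate(bad + 0, EBImage::makeBrush(3, "box")) > 0
  ids <- sort(union(cellIds(nuclei), cellIds(cytoplasm)))
  res <- stats::setNames(logical(length(ids)), ids)
  for (k in ids) {
    region <- nuclei@labels == k | cytoplasm@labels == k
    res[as.character(k)] <- any(bad[region])
  }
  if (length(res) && all(res))
    warning("all cells touch an edge or registration border")
  res
}
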