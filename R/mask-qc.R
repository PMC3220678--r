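## Classification of nuclear masks into matched vs mismatched-or-false.
## A mask that slips off its nucleus straddles compartments of different
## brightness, which inflates the standard deviation of the enclosed pixels
## much more than their mean; a robust line of s.d. on mean fitted to a
## stationary control population, with a pointwise prediction band, therefore
## separates matched from mismatched or false masks.

#' Per-nucleus intensity statistics
#'
#' Mean and population standard deviation of the target-protein intensity over
#' the valid pixels of each (eroded) nuclear region, plus the coefficient of
#' variation and the pixel count. Regions with fewer than two valid pixels are
#' flagged and carry NA statistics.
#'
#' @param frame \linkS4class{IntensityImage} or matrix (a registered frame).
#' @param erodedNuclei nuclear \linkS4class{LabelMap} (typically eroded).
#' @return data.frame with columns \code{cell_id}, \code{mean_fi},
#'   \code{sd_fi}, \code{cv}, \code{area_px}, \code{flag}.
#' @export
measureMaskStats <- function(frame, erodedNuclei) {
  frame <- .asIntensityImage(frame)
  stopifnot(is(erodedNuclei, "LabelMap"))
  if (!identical(dim(frame@pixels), dim(erodedNuclei@labels)))
    stop("frame and label map must share dimensions")
  ids <- cellIds(erodedNuclei)
  res <- data.frame(cell_id = ids, mean_fi = NA_real_, sd_fi = NA_real_,
                    cv = NA_real_, area_px = 0L, flag = "")
  for (i in seq_along(ids)) {
    sel <- erodedNuclei@labels == ids[i] & frame@valid
    v <- frame@pixels[sel]
    res$area_px[i] <- length(v)
    if (length(v) < 2L) {
      res$flag[i] <- "too_few_pixels"
      next
    }
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))   # population s.d.
    res$mean_fi[i] <- m
    res$sd_fi[i] <- s
    res$cv[i] <- if (m > 0) s / m else NA_real_
  }
  res
}

#' Robust line fit of s.d. on mean (IRLS, bisquare)
#'
#' Fits \code{sd_fi ~ mean_fi} by iteratively reweighted least squares with
#' Tukey bisquare weights (tuning constant 4.685) and scale 1.4826 x MAD of
#' the residuals, iterating until the relative coefficient change is below
#' 1e-8 or 50 iterations. The stored residual scale is the weighted RMSE of
#' the robust residuals; together with n, the predictor mean and the
#' predictor sum of squares it determines the prediction band used for mask
#' classification.
#'
#' @param stats data.frame with \code{mean_fi} and \code{sd_fi} (rows with NA
#'   are dropped), as from \code{\link{measureMaskStats}} of a stationary
#'   control population.
#' @param alpha band tail probability (default 0.005 for a 99.5% band).
#' @return A \linkS4class{RobustFit}.
#' @export
fitRobustLine <- function(stats, alpha = 0.005) {
  x <- stats$mean_fi
  y <- stats$sd_fi
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least 3 points are required")
  if (stats::var(x) == 0) stop("degenerate predictor: all means equal")

  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  w <- rep(1, length(x))
  iter <- 0L
  converged <- FALSE
  for (iter in seq_len(50L)) {
    r <- y - X %*% beta
    s <- 1.4826 * stats::median(abs(r))
    if (s <= .Machine$double.eps * (1 + max(abs(y)))) {
      w <- as.numeric(abs(r) <= .Machine$double.eps * (1 + max(abs(y))))
      converged <- TRUE
      break
    }
    u <- r / (4.685 * s)
    w <- as.numeric((1 - u^2)^2 * (abs(u) < 1))
    fit <- stats::lm.wfit(X, y, w)
    betaNew <- stats::coef(fit)
    if (max(abs(betaNew - beta)) <= 1e-8 * max(1, max(abs(beta)))) {
      beta <- betaNew
      converged <- TRUE
      break
    }
    beta <- betaNew
  }
  r <- as.numeric(y - X %*% beta)
  sw <- sum(w)
  scale <- if (sw > 2) sqrt(sum(w * r^2) / (sw - 2)) else 0
  new("RobustFit", slope = unname(beta[2]), intercept = unname(beta[1]),
      residualScale = scale, n = length(x), xMean = mean(x),
      sxx = sum((x - mean(x))^2), alpha = alpha, iterations = iter,
      converged = converged)
}

#' Upper boundary of the prediction band
#'
#' Pointwise upper limit, at tail probability alpha, of the prediction band
#' for a new observation around the robust line:
#' \deqn{slope \cdot x + intercept + t_{1-\alpha/2, n-2}\, s
#'   \sqrt{1 + 1/n + (x - \bar{x})^2 / S_{xx}}.}
#' The band widens away from the predictor mean. A prediction band (not a
#' mean-response confidence band) is used because individual nuclei, not the
#' line itself, are admitted into it.
#'
#' @param fit a \linkS4class{RobustFit}.
#' @param x numeric vector of mean intensities.
#' @return Numeric vector of band upper limits.
#' @export
bandUpper <- function(fit, x) {
  stopifnot(is(fit, "RobustFit"))
  tq <- stats::qt(1 - fit@alpha / 2, df = fit@n - 2L)
  fit@slope * x + fit@intercept +
    tq * fit@residualScale * sqrt(1 + 1 / fit@n + (x - fit@xMean)^2 / fit@sxx)
}

#' Classify nuclear masks as matched vs mismatched-or-false
#'
#' A mask is matched iff its s.d. lies at or below the band upper boundary at
#' its mean; only the upper boundary gates the decision, since mismatch
#' inflates the s.d. Classification uses the statistics of the first
#' registered frame, which best represents the segmentation effect (masks
#' derive from the end point, so mismatch accumulates toward the first frame);
#' later frames inherit the first-frame label. Cells without statistics are
#' labelled mismatched-or-false with a reason code.
#'
#' @param stats data.frame from \code{\link{measureMaskStats}} on the first
#'   registered frame.
#' @param fit \linkS4class{RobustFit} built from a stationary control
#'   population.
#' @return data.frame with \code{cell_id}, \code{label} (\code{"matched"} or
#'   \code{"mismatched_or_false"}) and \code{reason}.
#' @export
classifyMasks <- function(stats, fit) {
  stopifnot(is(fit, "RobustFit"))
  lab <- character(nrow(stats))
  reason <- character(nrow(stats))
  ok <- is.finite(stats$mean_fi) & is.finite(stats$sd_fi)
  up <- bandUpper(fit, stats$mean_fi[ok])
  inside <- stats$sd_fi[ok] <= up
  lab[ok] <- ifelse(inside, "matched", "mismatched_or_false")
  reason[ok] <- ifelse(inside, "within_band", "above_band")
  lab[!ok] <- "mismatched_or_false"
  reason[!ok] <- "no_stats"
  data.frame(cell_id = stats$cell_id, label = lab, reason = reason)
}

#' Artificially mismatch a mask
#'
#' Rigidly transforms a mask region (rotation by \code{theta} degrees about
#' its centroid, then translation by (dr, dc)) to emulate a mask that slipped
#' off its nucleus, and intersects the result with the original region to
#' emulate a mask smaller than the real nucleus. Used to validate the
#' s.d.-vs-mean classifier against controlled mismatches.
#'
#' @param mask logical matrix (one region) or a region of a
#'   \linkS4class{LabelMap} converted to logical.
#' @param dr,dc integer translation in pixels.
#' @param theta rotation in degrees.
#' @return list with \code{mismatched}, \code{intersected} (both logical
#'   matrices) and \code{emptyIntersection}.
#' @export
makeMismatch <- function(mask, dr = 0L, dc = 0L, theta = 0) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("'mask' is empty")
  d <- dim(mask)
  pos <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pos)
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

  ## bounds check on the forward-transformed region
  fwd <- sweep(pos, 2, ctr) %*% t(R)
  fwd <- sweep(fwd, 2, ctr + c(dr, dc), "+")
  if (any(round(fwd[, 1]) < 1 | round(fwd[, 1]) > d[1] |
          round(fwd[, 2]) < 1 | round(fwd[, 2]) > d[2]))
    stop("transformed region leaves the image bounds")

  ## inverse mapping over the target bounding box avoids rasterization holes
  r0 <- max(1L, floor(min(fwd[, 1]))); r1 <- min(d[1], ceiling(max(fwd[, 1])))
  c0 <- max(1L, floor(min(fwd[, 2]))); c1 <- min(d[2], ceiling(max(fwd[, 2])))
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  back <- sweep(grid, 2, ctr + c(dr, dc)) %*% R   # t(R^-1) = R
  back <- round(sweep(back, 2, ctr, "+"))
  inb <- back[, 1] >= 1 & back[, 1] <= d[1] & back[, 2] >= 1 & back[, 2] <= d[2]
  hit <- inb
  hit[inb] <- mask[back[inb, , drop = FALSE]]
  mis <- matrix(FALSE, d[1], d[2])
  mis[grid[hit, , drop = FALSE]] <- TRUE
  inter <- mis & mask
  list(mismatched = mis, intersected = inter,
       emptyIntersection = !any(inter))
}

## contour chain length of each labelled object (perimeter estimate)
.perimeters <- function(lab) {
  oc <- EBImage::ocontour(lab)
  vapply(oc, function(ct) {
    if (is.null(ct) || nrow(ct) < 2) return(0)
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    sum(sqrt(rowSums((ct - nxt)^2)))
  }, 0)
}

## area of the convex hull of pixel centers, with a half-perimeter + 1
## boundary correction so a digital region's hull area is comparable to its
## pixel-count area
.hullArea <- function(pos) {
  if (nrow(pos) < 3) return(nrow(pos))
  h <- grDevices::chull(pos)
  hp <- pos[h, , drop = FALSE]
  nxt <- rbind(hp[-1, , drop = FALSE], hp[1, , drop = FALSE])
  a <- abs(sum(hp[, 1] * nxt[, 2] - nxt[, 1] * hp[, 2])) / 2
  per <- sum(sqrt(rowSums((hp - nxt)^2)))
  a + per / 2 + 1
}

#' Shape- and intensity-based segmentation quality control
#'
#' Computes per-cell nuclear perimeter, nuclear solidity (area divided by
#' convex-hull area), whole-cell perimeter, and mean/s.d. of the nuclear-stain
#' and target-protein intensities, then flags cells whose value for any
#' parameter deviates from the population median by more than 3 robust
#' standard deviations (1.4826 x MAD). Deviated values indicate segmentation
#' errors.
#'
#' @param nuclei,cytoplasm \linkS4class{LabelMap}s sharing the label space.
#' @param nuclearImage fixed nuclear-stain \linkS4class{IntensityImage}.
#' @param targetImage target-protein \linkS4class{IntensityImage} (first
#'   registered frame or fixed target).
#' @return data.frame with the per-cell parameters, a \code{flagged} logical
#'   and a comma-separated \code{flagged_params} column.
#' @export
shapeQC <- function(nuclei, cytoplasm, nuclearImage, targetImage) {
  stopifnot(is(nuclei, "LabelMap"), is(cytoplasm, "LabelMap"))
  nuclearImage <- .asIntensityImage(nuclearImage)
  targetImage <- .asIntensityImage(targetImage)
  ids <- cellIds(nuclei)
  comb <- nuclei@labels
  sel <- cytoplasm@labels > 0L
  comb[sel] <- cytoplasm@labels[sel]
  nucPer <- .perimeters(nuclei@labels)
  cellPer <- .perimeters(comb)

  res <- data.frame(cell_id = ids, nuclear_perimeter = NA_real_,
                    nuclear_solidity = NA_real_, cell_perimeter = NA_real_,
                    nuclear_stain_mean = NA_real_, nuclear_stain_sd = NA_real_,
                    target_mean = NA_real_, target_sd = NA_real_)
  for (i in seq_along(ids)) {
    k <- ids[i]
    nsel <- nuclei@labels == k
    pos <- which(nsel, arr.ind = TRUE)
    res$nuclear_perimeter[i] <- if (k <= length(nucPer)) nucPer[k] else NA
    res$nuclear_solidity[i] <- min(1, nrow(pos) / .hullArea(pos))
    res$cell_perimeter[i] <- if (k <= length(cellPer)) cellPer[k] else NA
    vN <- nuclearImage@pixels[nsel & nuclearImage@valid]
    csel <- (nsel | cytoplasm@labels == k) & targetImage@valid
    vT <- targetImage@pixels[csel]
    if (length(vN)) {
      res$nuclear_stain_mean[i] <- mean(vN)
      res$nuclear_stain_sd[i] <- stats::sd(vN)
    }
    if (length(vT)) {
      res$target_mean[i] <- mean(vT)
      res$target_sd[i] <- stats::sd(vT)
    }
  }
  params <- setdiff(names(res), "cell_id")
  flagMat <- sapply(params, function(p) {
    v <- res[[p]]
    med <- stats::median(v, na.rm = TRUE)
    sc <- 1.4826 * stats::mad(v, constant = 1, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0)
      abs(v - med) > 1e-8 * (abs(med) + 1)
    else
      abs(v - med) > 3 * sc
  })
  flagMat[is.na(flagMat)] <- TRUE
  res$flagged <- apply(flagMat, 1, any)
  res$flagged_params <- apply(flagMat, 1, function(z)
    paste(params[z], collapse = ","))
  res
}
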