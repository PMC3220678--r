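#' @import methods
NULL

#' Intensity image with a validity mask
#'
#' A single-channel fluorescence image. Pixels are non-negative intensities in
#' arbitrary units (typically 12-bit camera counts); \code{valid} marks pixels
#' that carry real data. Border regions exposed by registration shifts are
#' marked invalid rather than filled with a sentinel intensity, so that they
#' are excluded from every downstream statistic.
#'
#' Coordinates are 0-based (row, col) in the documentation of shifts; storage
#' is an ordinary R matrix indexed from 1.
#'
#' @slot pixels numeric matrix of non-negative intensities.
#' @slot valid logical matrix of the same shape; \code{TRUE} where the pixel
#'   carries real data.
#' @export
setClass("IntensityImage",
  representation(pixels = "matrix", valid = "matrix"))

setValidity("IntensityImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  if (!is.logical(object@valid))
    msg <- c(msg, "'valid' must be a logical matrix")
  if (!identical(dim(object@pixels), dim(object@valid)))
    msg <- c(msg, "'pixels' and 'valid' must have identical dimensions")
  if (anyNA(object@valid))
    msg <- c(msg, "'valid' must not contain NA")
  v <- object@pixels[object@valid]
  if (length(v) && (anyNA(v) || any(v < 0)))
    msg <- c(msg, "valid pixels must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param valid optional logical matrix; defaults to all-\code{TRUE}.
#' @return An \linkS4class{IntensityImage}.
#' @examples
#' img <- IntensityImage(matrix(0, 8, 10))
#' dim(pixels(img))
#' @export
IntensityImage <- function(pixels, valid = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(valid))
    valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("IntensityImage", pixels = pixels, valid = valid)
}

#' An imaging field: live series plus fixed end-point references
#'
#' One imaging position of a translocation experiment: an ordered series of
#' live-cell target-protein frames (frame i acquired at i x interval minutes,
#' by convention), followed by two images of the same field taken after
#' fixation and nuclear staining: the target-protein channel and the
#' nuclear-stain channel. All images share pixel dimensions.
#'
#' @slot fieldId character identifier.
#' @slot liveFrames list of \linkS4class{IntensityImage}, acquisition order.
#' @slot fixedTarget \linkS4class{IntensityImage}, fixed-cell target channel.
#' @slot fixedNuclear \linkS4class{IntensityImage}, fixed-cell nuclear stain.
#' @slot frameIntervalMin positive number, minutes between live frames.
#' @slot bitDepth integer, camera bit depth (default 12; max value 4095).
#' @export
setClass("Field",
  representation(fieldId = "character", liveFrames = "list",
    fixedTarget = "IntensityImage", fixedNuclear = "IntensityImage",
    frameIntervalMin = "numeric", bitDepth = "integer"))

setValidity("Field", function(object) {
  msg <- character()
  if (length(object@liveFrames) < 1L)
    msg <- c(msg, "at least one live frame is required")
  if (!all(vapply(object@liveFrames, is, TRUE, class2 = "IntensityImage")))
    msg <- c(msg, "'liveFrames' must be a list of IntensityImage")
  dims <- lapply(object@liveFrames, function(x) dim(x@pixels))
  dims <- c(dims, list(dim(object@fixedTarget@pixels)),
            list(dim(object@fixedNuclear@pixels)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    msg <- c(msg, paste0("all images must share dimensions; got ",
      paste(unique(vapply(dims, paste, "", collapse = "x")), collapse = ", ")))
  if (length(object@frameIntervalMin) != 1L || object@frameIntervalMin <= 0)
    msg <- c(msg, "'frameIntervalMin' must be a positive scalar")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    msg <- c(msg, "'bitDepth' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a Field
#'
#' @param liveFrames list of \linkS4class{IntensityImage} (or numeric
#'   matrices), in acquisition order.
#' @param fixedTarget,fixedNuclear \linkS4class{IntensityImage} or numeric
#'   matrix: the end-point fixed-cell target-protein and nuclear-stain images.
#' @param fieldId character identifier.
#' @param frameIntervalMin minutes between consecutive live frames.
#' @param bitDepth camera bit depth.
#' @return A \linkS4class{Field}.
#' @export
Field <- function(liveFrames, fixedTarget, fixedNuclear, fieldId = "field",
                  frameIntervalMin = 10, bitDepth = 12L) {
  asII <- function(x) if (is(x, "IntensityImage")) x else IntensityImage(x)
  new("Field", fieldId = fieldId,
      liveFrames = lapply(liveFrames, asII),
      fixedTarget = asII(fixedTarget), fixedNuclear = asII(fixedNuclear),
      frameIntervalMin = frameIntervalMin, bitDepth = as.integer(bitDepth))
}

#' Pipeline configuration
#'
#' Tunable parameters of the retrospective pipeline. The dilation distance
#' \code{d} (pixels) bounds how far cytoplasm is claimed around each nucleus;
#' the erosion distance \code{e} (pixels) trims nuclear masks to limit
#' nuclear/cytoplasmic cross-contamination. \code{alpha} is the tail
#' probability of the classifier's prediction band (0.005 gives a 99.5% band).
#'
#' @slot d integer dilation distance, allowed 6..20.
#' @slot e integer erosion distance, allowed 2..6.
#' @slot alpha band tail probability in (0, 0.5).
#' @slot maxShift integer registration search radius in pixels.
#' @slot minAreaFraction fraction of the mean candidate nuclear area below
#'   which masks are removed.
#' @slot logSigma Laplacian-of-Gaussian scale (pixels) for nuclear edge
#'   detection.
#' @slot seed integer RNG seed.
#' @export
setClass("PipelineConfig",
  representation(d = "integer", e = "integer", alpha = "numeric",
    maxShift = "integer", minAreaFraction = "numeric", logSigma = "numeric",
    seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@d < 6L || object@d > 20L)
    msg <- c(msg, "'d' must be in 6..20")
  if (object@e < 2L || object@e > 6L)
    msg <- c(msg, "'e' must be in 2..6")
  if (object@alpha <= 0 || object@alpha >= 0.5)
    msg <- c(msg, "'alpha' must be in (0, 0.5)")
  if (object@maxShift < 1L)
    msg <- c(msg, "'maxShift' must be >= 1")
  if (object@minAreaFraction <= 0 || object@minAreaFraction >= 1)
    msg <- c(msg, "'minAreaFraction' must be in (0, 1)")
  if (object@logSigma <= 0)
    msg <- c(msg, "'logSigma' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param d integer dilation distance in pixels (6..20).
#' @param e integer erosion distance in pixels (2..6).
#' @param alpha band tail probability (default 0.005, a 99.5% band).
#' @param maxShift registration search radius in pixels.
#' @param minAreaFraction nuclear size-filter fraction.
#' @param logSigma Laplacian-of-Gaussian scale in pixels.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(d = 8L, e = 3L, alpha = 0.005, maxShift = 20L,
                           minAreaFraction = 0.5, logSigma = 3, seed = 1L) {
  new("PipelineConfig", d = as.integer(d), e = as.integer(e), alpha = alpha,
      maxShift = as.integer(maxShift), minAreaFraction = minAreaFraction,
      logSigma = logSigma, seed = as.integer(seed))
}

#' Rigid integer-pixel translation
#'
#' The translation aligning a moving image to a reference, as recovered by
#' normalized cross-correlation. Positive \code{dr}/\code{dc} move content
#' down/right.
#'
#' @slot dr integer row shift in pixels.
#' @slot dc integer column shift in pixels.
#' @slot peakCorrelation normalized cross-correlation at the optimum, in
#'   [-1, 1].
#' @export
setClass("ShiftTransform",
  representation(dr = "integer", dc = "integer", peakCorrelation = "numeric"))

setValidity("ShiftTransform", function(object) {
  pc <- object@peakCorrelation
  if (length(pc) == 1L && !is.na(pc) && (pc < -1 - 1e-9 || pc > 1 + 1e-9))
    "'peakCorrelation' must lie in [-1, 1]" else TRUE
})

#' Construct a ShiftTransform
#' @param dr,dc integer shifts in pixels (positive = down/right).
#' @param peakCorrelation correlation at the optimum.
#' @return A \linkS4class{ShiftTransform}.
#' @export
ShiftTransform <- function(dr = 0L, dc = 0L, peakCorrelation = NA_real_) {
  new("ShiftTransform", dr = as.integer(dr), dc = as.integer(dc),
      peakCorrelation = as.numeric(peakCorrelation))
}

#' Integer-labelled pixel regions
#'
#' A label map assigning pixels to cells: 0 is background, label k > 0 the
#' compartment of cell k. Nuclear and cytoplasmic maps of the same field share
#' the label space, and for each cell the two compartments are disjoint.
#'
#' @slot labels integer matrix of labels.
#' @slot kind \code{"nuclear"} or \code{"cytoplasmic"}.
#' @slot metadata list of provenance (parameters used, flagged cells).
#' @export
setClass("LabelMap",
  representation(labels = "matrix", kind = "character", metadata = "list"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (!is.numeric(object@labels) || anyNA(object@labels) ||
      any(object@labels < 0))
    msg <- c(msg, "'labels' must be non-negative integers")
  if (!object@kind %in% c("nuclear", "cytoplasmic"))
    msg <- c(msg, "'kind' must be 'nuclear' or 'cytoplasmic'")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#' @param labels integer matrix (0 = background, k > 0 = cell k).
#' @param kind \code{"nuclear"} or \code{"cytoplasmic"}.
#' @param metadata list of provenance.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels, kind = c("nuclear", "cytoplasmic"),
                     metadata = list()) {
  kind <- match.arg(kind)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, kind = kind, metadata = metadata)
}

#' Robust line fit of per-nucleus s.d. on mean
#'
#' The result of iteratively reweighted least squares (bisquare weights) of
#' nuclear-fluorescence standard deviation on mean over a stationary control
#' population, together with the design quantities needed to evaluate a
#' pointwise prediction band for a new nucleus.
#'
#' @slot slope,intercept fitted line coefficients.
#' @slot residualScale weighted RMSE of the robust residuals.
#' @slot n number of points used.
#' @slot xMean mean of the predictor (nuclear mean intensity).
#' @slot sxx sum of squared predictor deviations.
#' @slot alpha band tail probability.
#' @slot iterations IRLS iterations performed.
#' @slot converged logical.
#' @export
setClass("RobustFit",
  representation(slope = "numeric", intercept = "numeric",
    residualScale = "numeric", n = "integer", xMean = "numeric",
    sxx = "numeric", alpha = "numeric", iterations = "integer",
    converged = "logical"))

setValidity("RobustFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "'n' must be >= 3")
  if (object@residualScale < 0) msg <- c(msg, "'residualScale' must be >= 0")
  if (object@sxx <= 0) msg <- c(msg, "'sxx' must be > 0")
  if (object@alpha <= 0 || object@alpha >= 0.5)
    msg <- c(msg, "'alpha' must be in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Synthetic-field generator configuration
#'
#' Parameters of the ground-truthed simulator. Cells are rendered as
#' concentric nuclear/cytoplasmic ellipses with per-cell log-normal expression
#' and a cytoplasm-dominant baseline (nuclear:cytoplasmic intensity ratio
#' below 1). Responders follow a delayed-logistic nuclear accumulation
#' NA(t) = 1 + (F - 1) / (1 + exp(-k (t - lag - tHalf))) with conservative
#' cytoplasm depletion (total cell fluorescence constant). A configurable
#' fraction of cells move or rotate during the time course; global stage drift
#' and uneven fixation dimming of the end-point target image are optional.
#' Two-component length parameters are (mean, sd) of per-cell draws.
#'
#' @slot nCells integer number of cells.
#' @slot imageShape integer (rows, cols), default c(512, 672).
#' @slot nFrames integer number of live frames, default 13.
#' @slot frameIntervalMin minutes between frames, default 10.
#' @slot nuclearRadius,cytoRadius numeric (mean, sd) in pixels.
#' @slot expressionMeanlog,expressionSdlog log-normal parameters of per-cell
#'   baseline cytoplasmic intensity (camera counts).
#' @slot baselineNCRatio baseline nuclear:cytoplasmic intensity ratio (< 1,
#'   cytoplasm-dominant).
#' @slot responderFraction fraction of cells that translocate.
#' @slot lagMin,tHalfMin,rateK,plateauFold numeric (mean, sd) of per-cell
#'   kinetic parameters: lag (min), half-rise time after the lag (min),
#'   logistic rate (1/min) and plateau fold-change F (>= 1).
#' @slot moverFraction fraction of motile cells.
#' @slot moverDriftPxPerFrame,rotationDegPerFrame motile-cell motion per frame.
#' @slot noiseSdAdd additive Gaussian noise s.d. (counts).
#' @slot noiseGain signal-dependent (Poisson-like) variance gain: variance
#'   contribution gain x intensity.
#' @slot textureCv multiplicative intensity texture coefficient of variation.
#' @slot cytoGradient relative perinuclear-to-edge cytoplasmic intensity drop.
#' @slot gradientShift how strongly the perinuclear pool depletes first in
#'   responders: the gradient weight falls from 1 to 1 - gradientShift as
#'   accumulation approaches its plateau (0 = static spatial distribution).
#' @slot background background level (counts).
#' @slot fixationDimFactor mean multiplicative dimming of the fixed target
#'   image (< 1); \code{fixationDimSd} sets its smooth spatial unevenness.
#' @slot fixationDimSd relative s.d. of the smooth dimming field.
#' @slot stageDriftPxPerFrame numeric (dr, dc) global drift per frame.
#' @slot bitDepth camera bit depth.
#' @slot quantize logical; round rendered intensities to integer counts.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(nCells = "integer", imageShape = "integer",
    nFrames = "integer", frameIntervalMin = "numeric",
    nuclearRadius = "numeric", cytoRadius = "numeric",
    expressionMeanlog = "numeric", expressionSdlog = "numeric",
    baselineNCRatio = "numeric", responderFraction = "numeric",
    lagMin = "numeric", tHalfMin = "numeric", rateK = "numeric",
    plateauFold = "numeric", moverFraction = "numeric",
    moverDriftPxPerFrame = "numeric", rotationDegPerFrame = "numeric",
    noiseSdAdd = "numeric", noiseGain = "numeric", textureCv = "numeric",
    cytoGradient = "numeric", gradientShift = "numeric",
    background = "numeric",
    fixationDimFactor = "numeric", fixationDimSd = "numeric",
    stageDriftPxPerFrame = "numeric", bitDepth = "integer",
    quantize = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nCells < 1L) msg <- c(msg, "'nCells' must be >= 1")
  if (length(object@imageShape) != 2L || any(object@imageShape < 32L))
    msg <- c(msg, "'imageShape' must be two values >= 32")
  if (object@nFrames < 1L) msg <- c(msg, "'nFrames' must be >= 1")
  for (s in c("responderFraction", "moverFraction")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste0("'", s, "' must be in [0, 1]"))
  }
  if (object@nuclearRadius[1] <= 0 || object@cytoRadius[1] <= 0)
    msg <- c(msg, "radii must be positive")
  if (object@cytoRadius[1] <= object@nuclearRadius[1])
    msg <- c(msg, "'cytoRadius' mean must exceed 'nuclearRadius' mean")
  if (object@plateauFold[1] < 1)
    msg <- c(msg, "'plateauFold' mean must be >= 1")
  if (object@baselineNCRatio <= 0 || object@baselineNCRatio >= 1)
    msg <- c(msg, "'baselineNCRatio' must be in (0, 1)")
  if (object@fixationDimFactor <= 0)
    msg <- c(msg, "'fixationDimFactor' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate a stimulated STAT-like translocation experiment: 13
#' frames at 10-minute intervals on a 512 x 672 12-bit camera, cytoplasm-
#' dominant baseline, a ~20-minute lag then a logistic rise to a ~3-fold
#' nuclear plateau in responders, and a few percent of motile cells.
#'
#' @param nCells number of cells.
#' @param imageShape integer (rows, cols).
#' @param nFrames number of live frames.
#' @param frameIntervalMin minutes between frames.
#' @param nuclearRadius,cytoRadius (mean, sd) in pixels.
#' @param expressionMeanlog,expressionSdlog per-cell expression log-normal.
#' @param baselineNCRatio baseline nuclear:cytoplasmic ratio (< 1).
#' @param responderFraction fraction of responding cells.
#' @param lagMin,tHalfMin,rateK,plateauFold (mean, sd) kinetic parameters.
#' @param moverFraction fraction of motile cells.
#' @param moverDriftPxPerFrame,rotationDegPerFrame motile-cell motion.
#' @param noiseSdAdd,noiseGain,textureCv noise model components.
#' @param cytoGradient relative cytoplasmic radial intensity drop.
#' @param gradientShift perinuclear-first depletion strength in responders.
#' @param background background counts.
#' @param fixationDimFactor,fixationDimSd fixed-target dimming field.
#' @param stageDriftPxPerFrame (dr, dc) global stage drift per frame.
#' @param bitDepth camera bit depth.
#' @param quantize round intensities to integer counts.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(nCells = 10, imageShape = c(160, 200), seed = 7)
#' cfg
#' @export
SimConfig <- function(nCells = 50L, imageShape = c(512L, 672L),
    nFrames = 13L, frameIntervalMin = 10,
    nuclearRadius = c(10, 1), cytoRadius = c(18, 1.5),
    expressionMeanlog = log(900), expressionSdlog = 0.35,
    baselineNCRatio = 0.9, responderFraction = 0.8,
    lagMin = c(20, 5), tHalfMin = c(40, 10), rateK = c(0.12, 0.02),
    plateauFold = c(3, 0.5), moverFraction = 0.035,
    moverDriftPxPerFrame = 2, rotationDegPerFrame = 3,
    noiseSdAdd = 8, noiseGain = 1, textureCv = 0.05,
    cytoGradient = 0.35, gradientShift = 1.2, background = 40,
    fixationDimFactor = 0.7, fixationDimSd = 0.1,
    stageDriftPxPerFrame = c(0, 0), bitDepth = 12L, quantize = TRUE,
    seed = 1L) {
  new("SimConfig", nCells = as.integer(nCells),
      imageShape = as.integer(imageShape), nFrames = as.integer(nFrames),
      frameIntervalMin = frameIntervalMin,
      nuclearRadius = as.numeric(nuclearRadius),
      cytoRadius = as.numeric(cytoRadius),
      expressionMeanlog = expressionMeanlog,
      expressionSdlog = expressionSdlog,
      baselineNCRatio = baselineNCRatio,
      responderFraction = responderFraction,
      lagMin = as.numeric(lagMin), tHalfMin = as.numeric(tHalfMin),
      rateK = as.numeric(rateK), plateauFold = as.numeric(plateauFold),
      moverFraction = moverFraction,
      moverDriftPxPerFrame = moverDriftPxPerFrame,
      rotationDegPerFrame = rotationDegPerFrame,
      noiseSdAdd = noiseSdAdd, noiseGain = noiseGain, textureCv = textureCv,
      cytoGradient = cytoGradient, gradientShift = gradientShift,
      background = background,
      fixationDimFactor = fixationDimFactor, fixationDimSd = fixationDimSd,
      stageDriftPxPerFrame = as.numeric(stageDriftPxPerFrame),
      bitDepth = as.integer(bitDepth), quantize = quantize,
      seed = as.integer(seed))
}

## show methods -------------------------------------------------------------

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IntensityImage %d x %d, %.1f%% valid, range [%g, %g]\n",
      d[1], d[2], 100 * mean(object@valid),
      suppressWarnings(min(object@pixels[object@valid])),
      suppressWarnings(max(object@pixels[object@valid]))))
})

setMethod("show", "Field", function(object) {
  d <- dim(object@fixedTarget@pixels)
  cat(sprintf(
    "Field '%s': %d live frame(s) @ %g min, %d x %d px, %d-bit\n",
    object@fieldId, length(object@liveFrames), object@frameIntervalMin,
    d[1], d[2], object@bitDepth))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: d=%d e=%d alpha=%g maxShift=%d minAreaFraction=%g logSigma=%g seed=%d\n",
    object@d, object@e, object@alpha, object@maxShift,
    object@minAreaFraction, object@logSigma, object@seed))
})

setMethod("show", "ShiftTransform", function(object) {
  cat(sprintf("ShiftTransform (dr=%d, dc=%d), peak NCC = %.4f\n",
      object@dr, object@dc, object@peakCorrelation))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  k <- length(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf("LabelMap (%s): %d x %d px, %d labelled region(s)\n",
      object@kind, d[1], d[2], k))
})

setMethod("show", "RobustFit", function(object) {
  cat(sprintf(
    "RobustFit: sd = %.5g * mean + %.5g  (scale %.4g, n = %d, alpha = %g)\n",
    object@slope, object@intercept, object@residualScale, object@n,
    object@alpha))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d cells, %d x %d px, %d frame(s) @ %g min, seed %d\n",
    object@nCells, object@imageShape[1], object@imageShape[2],
    object@nFrames, object@frameIntervalMin, object@seed))
  cat(sprintf(
    "  responders %.0f%%, movers %.1f%%, baseline N:C %.2f, plateau fold %.2g +/- %.2g\n",
    100 * object@responderFraction, 100 * object@moverFraction,
    object@baselineNCRatio, object@plateauFold[1], object@plateauFold[2]))
})
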