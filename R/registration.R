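## Rigid-translation registration by masked normalized cross-correlation.
## All candidate integer shifts within the search radius are scored by the
## Pearson correlation over the mutually valid overlap; the sums entering the
## correlation are obtained for every shift at once with FFT cross-
## correlations of the images and of their validity masks.

.asIntensityImage <- function(x) {
  if (is(x, "IntensityImage")) x else IntensityImage(x)
}

## cross-correlation of two zero-padded real matrices:
## C[dr, dc] = sum_{i,j} A[i, j] * B[i + dr, j + dc]
.xcorrFFT <- function(fA, fB, P) {
  Re(stats::fft(Conj(fA) * fB, inverse = TRUE)) / prod(P)
}

#' Recover the integer translation aligning an image to a reference
#'
#' Exhaustively scores every integer shift (dr, dc) with |dr|, |dc| <=
#' \code{maxShift} by the normalized cross-correlation of the two images over
#' their mutually valid overlap, and returns the shift with the highest
#' correlation. Positive shifts move the moving image's content down/right.
#' Invalid pixels (e.g. borders from earlier registrations) are excluded from
#' the correlation at every candidate shift, and candidate shifts whose
#' overlap covers less than 25% of the image are not considered. Ties in the
#' peak are broken by the smallest |dr| + |dc|, then row-major order, so the
#' result is deterministic.
#'
#' @param moving,reference \linkS4class{IntensityImage} (or numeric matrices)
#'   of identical shape.
#' @param maxShift integer search radius in pixels.
#' @return A \linkS4class{ShiftTransform}: applying it to \code{moving} (see
#'   \code{\link{applyShift}}) aligns it to \code{reference}.
#' @examples
#' ref <- matrix(stats::runif(60 * 80), 60, 80)
#' mov <- applyShift(IntensityImage(ref), ShiftTransform(3, -5))
#' nccShift(mov, ref, maxShift = 8)  # recovers the aligning shift (-3, 5)
#' @export
nccShift <- function(moving, reference, maxShift = 20L) {
  moving <- .asIntensityImage(moving)
  reference <- .asIntensityImage(reference)
  if (!identical(dim(moving@pixels), dim(reference@pixels)))
    stop("images must share dimensions")
  maxShift <- as.integer(maxShift)
  if (maxShift < 1L) stop("'maxShift' must be >= 1")
  d <- dim(moving@pixels)
  if (maxShift >= min(d)) stop("'maxShift' must be smaller than the image")

  x <- moving@pixels;    mx <- moving@valid
  y <- reference@pixels; my <- reference@valid
  if (stats::var(x[mx]) == 0 || stats::var(y[my]) == 0)
    stop("normalized cross-correlation undefined for a constant image")
  x[!mx] <- 0; y[!my] <- 0
  mxn <- mx + 0; myn <- my + 0

  P <- c(stats::nextn(d[1] + maxShift, c(2, 3, 5)),
         stats::nextn(d[2] + maxShift, c(2, 3, 5)))
  pad <- function(m) {
    out <- matrix(0, P[1], P[2]); out[seq_len(d[1]), seq_len(d[2])] <- m; out
  }
  fX  <- stats::fft(pad(x * mxn));  fM  <- stats::fft(pad(mxn))
  fX2 <- stats::fft(pad(x^2 * mxn))
  fY  <- stats::fft(pad(y * myn));  fN  <- stats::fft(pad(myn))
  fY2 <- stats::fft(pad(y^2 * myn))

  ## with A = moving-side quantity, B = reference-side: the value at wrapped
  ## index (dr, dc) sums A[i, j] * B[i + dr, j + dc] over the overlap
  nOv <- .xcorrFFT(fM, fN, P)
  sX  <- .xcorrFFT(fX, fN, P)
  sY  <- .xcorrFFT(fM, fY, P)
  sXX <- .xcorrFFT(fX2, fN, P)
  sYY <- .xcorrFFT(fM, fY2, P)
  sXY <- .xcorrFFT(fX, fY, P)

  sh <- seq(-maxShift, maxShift)
  ri <- (sh %% P[1]) + 1L
  ci <- (sh %% P[2]) + 1L
  n   <- round(nOv[ri, ci])
  Sx  <- sX[ri, ci];  Sy  <- sY[ri, ci]
  Sxx <- sXX[ri, ci]; Syy <- sYY[ri, ci]; Sxy <- sXY[ri, ci]

  minOverlap <- 0.25 * prod(d)
  num <- Sxy - Sx * Sy / n
  vx <- pmax(Sxx - Sx^2 / n, 0)
  vy <- pmax(Syy - Sy^2 / n, 0)
  ## guard against round-off pseudo-variance in (near-)constant overlaps
  eps <- 1e-9 * (max(abs(Sxx)) + max(abs(Syy)) + 1)
  den <- sqrt(vx * vy)
  ok <- n >= minOverlap & is.finite(num) & vx > eps & vy > eps & den > 0
  ok[is.na(ok)] <- FALSE
  ncc <- matrix(-Inf, nrow(n), ncol(n))
  ncc[ok] <- num[ok] / den[ok]
  if (!any(is.finite(ncc)))
    stop("no candidate shift with sufficient valid overlap")

  best <- max(ncc)
  cand <- which(ncc >= best - 1e-9, arr.ind = TRUE)
  drs <- sh[cand[, 1]]; dcs <- sh[cand[, 2]]
  ord <- order(abs(drs) + abs(dcs), drs, dcs)
  ShiftTransform(drs[ord[1]], dcs[ord[1]],
                 peakCorrelation = max(-1, min(1, best)))
}

#' Translate an image by an integer shift
#'
#' Moves the content by (dr, dc) pixels (positive = down/right). Rows and
#' columns exposed at the borders carry no data and are marked invalid in the
#' result's validity mask; an invalid input pixel stays invalid wherever it
#' lands.
#'
#' @param image \linkS4class{IntensityImage} or numeric matrix.
#' @param t \linkS4class{ShiftTransform}.
#' @return A shifted \linkS4class{IntensityImage}.
#' @export
applyShift <- function(image, t) {
  image <- .asIntensityImage(image)
  d <- dim(image@pixels)
  dr <- t@dr; dc <- t@dc
  if (abs(dr) >= d[1] || abs(dc) >= d[2])
    stop("shift magnitude must be smaller than the image size")
  px <- matrix(0, d[1], d[2])
  vm <- matrix(FALSE, d[1], d[2])
  srcR <- max(1, 1 - dr):min(d[1], d[1] - dr)
  srcC <- max(1, 1 - dc):min(d[2], d[2] - dc)
  px[srcR + dr, srcC + dc] <- image@pixels[srcR, srcC]
  vm[srcR + dr, srcC + dc] <- image@valid[srcR, srcC]
  new("IntensityImage", pixels = px, valid = vm)
}

#' Register a live series to the fixed-cell reference
#'
#' The last live frame is registered to the fixed target-protein image; each
#' earlier frame is then registered to the already-registered next frame,
#' because adjacent frames are the most similar. Since every reference in the
#' chain is already in the fixed image's coordinates, the shift found for
#' frame i is its cumulative shift into the fixed frame of reference.
#'
#' @param field a \linkS4class{Field}.
#' @param maxShift integer search radius in pixels per registration.
#' @return A list with \code{frames} (the registered
#'   \linkS4class{IntensityImage} list) and \code{shifts} (a data.frame with
#'   columns \code{frame}, \code{dr}, \code{dc}, \code{peak_correlation}).
#' @export
registerSeries <- function(field, maxShift = 20L) {
  stopifnot(is(field, "Field"))
  n <- nFrames(field)
  regs <- vector("list", n)
  sh <- data.frame(frame = seq_len(n), dr = NA_integer_, dc = NA_integer_,
                   peak_correlation = NA_real_)
  ref <- fixedTarget(field)
  for (i in n:1) {
    t <- nccShift(field@liveFrames[[i]], ref, maxShift = maxShift)
    regs[[i]] <- applyShift(field@liveFrames[[i]], t)
    sh$dr[i] <- t@dr; sh$dc[i] <- t@dc
    sh$peak_correlation[i] <- t@peakCorrelation
    ref <- regs[[i]]
  }
  list(frames = regs, shifts = sh)
}
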