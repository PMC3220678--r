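## Ground-truthed synthetic fields emulating a stimulated nuclear-
## translocation experiment: cells rendered as concentric nuclear/cytoplasmic
## ellipses with per-cell log-normal expression, cytoplasm-dominant baseline,
## delayed-logistic nuclear accumulation with conservative cytoplasm
## depletion, a small fraction of motile cells, optional global stage drift,
## and an end-point fixed-cell pair (dimmed, unevenly, in the target channel;
## high-contrast in the nuclear stain).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## rasterize one cell's nucleus and cytoplasm into label matrices and
## return the local pixel selections
.rasterizeCell <- function(shape, ctr, phi, nucAB, cytoAB) {
  hw <- ceiling(max(cytoAB) + 2)
  r0 <- max(1L, floor(ctr[1] - hw)); r1 <- min(shape[1], ceiling(ctr[1] + hw))
  c0 <- max(1L, floor(ctr[2] - hw)); c1 <- min(shape[2], ceiling(ctr[2] + hw))
  dr <- (r0:r1) - ctr[1]
  dc <- (c0:c1) - ctr[2]
  DX <- matrix(dr, length(dr), length(dc))
  DY <- matrix(dc, length(dr), length(dc), byrow = TRUE)
  xr <- DX * cos(phi) + DY * sin(phi)
  yr <- -DX * sin(phi) + DY * cos(phi)
  rhoN <- sqrt((xr / nucAB[1])^2 + (yr / nucAB[2])^2)
  rhoC <- sqrt((xr / cytoAB[1])^2 + (yr / cytoAB[2])^2)
  nuc <- rhoN <= 1
  cyto <- rhoC <= 1 & !nuc
  list(rows = r0:r1, cols = c0:c1, nuc = nuc, cyto = cyto, rhoC = rhoC)
}

## smooth radial cytoplasmic profile, normalized to mean 1 over the
## cytoplasmic pixels so that total fluorescence is conserved exactly;
## 'weight' < 1 flattens (or inverts) the perinuclear excess as the
## perinuclear pool is imported first
.cytoProfile <- function(ras, gradient, weight = 1) {
  rho <- ras$rhoC[ras$cyto]
  if (gradient == 0 || length(rho) < 2 || diff(range(rho)) == 0)
    return(rep(1, length(rho)))
  reld <- (rho - min(rho)) / (max(rho) - min(rho))
  g <- pmax(1 + gradient * weight * (0.5 - reld), 0.05)
  g / mean(g)
}

.addNoise <- function(m, cfg) {
  if (cfg@noiseSdAdd > 0)
    m <- m + stats::rnorm(length(m), sd = cfg@noiseSdAdd)
  if (cfg@noiseGain > 0)
    m <- m + stats::rnorm(length(m)) * sqrt(cfg@noiseGain * pmax(m, 0))
  if (cfg@textureCv > 0)
    m <- m * (1 + cfg@textureCv * stats::rnorm(length(m)))
  m <- pmin(pmax(m, 0), 2^cfg@bitDepth - 1)
  if (cfg@quantize) m <- round(m)
  m
}

#' Simulate a ground-truthed imaging field
#'
#' Generates a \linkS4class{Field} (live series plus fixed-cell pair) together
#' with the ground truth needed to validate every pipeline stage: true
#' nuclear/cytoplasmic label maps per frame and at the fixed end point, the
#' true per-cell nuclear-accumulation trajectories, per-frame true
#' registration shifts, and all per-cell parameters drawn.
#'
#' Responder kinetics follow a delayed logistic,
#' NA(t) = 1 + (F - 1) / (1 + exp(-k (t - lag - tHalf))), with the cytoplasm
#' depleted so that each cell's total fluorescence above background is
#' constant across frames (plateau folds are truncated per cell so the
#' cytoplasm cannot be driven negative). The fixed-cell target image is the
#' final frame's geometry under a smooth multiplicative dimming field; the
#' fixed nuclear stain is a high-contrast rendering of the nuclei. The output
#' is deterministic given \code{cfg@seed}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{field} (a \linkS4class{Field}) and \code{truth}, a
#'   list with elements \code{cells} (per-cell parameter data.frame),
#'   \code{naTrajectory} (cells x frames), \code{nuclearPixelValue} (rendered
#'   nuclear pixel value incl. background, cells x frames), \code{trueShifts}
#'   (data.frame frame/dr/dc: the shift registration should recover),
#'   \code{nuclearLabels}/\code{cytoLabels} (fixed-geometry
#'   \linkS4class{LabelMap}s), \code{frameNuclearLabels}/
#'   \code{frameCytoLabels} (per-frame label matrices) and \code{dimField}.
#' @examples
#' sim <- simulateField(SimConfig(nCells = 6, imageShape = c(128, 160),
#'   nFrames = 3, moverFraction = 0, seed = 2))
#' sim$field
#' @export
simulateField <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  .withSeed(cfg@seed, {
    shape <- cfg@imageShape
    n <- cfg@nFrames
    tEl <- (seq_len(n) - 1) * cfg@frameIntervalMin
    drift <- cfg@stageDriftPxPerFrame

    ## --- placement ---------------------------------------------------------
    moverTot <- if (cfg@moverFraction > 0)
      ceiling(cfg@moverDriftPxPerFrame * (n - 1)) else 0
    margin <- ceiling(cfg@cytoRadius[1] + 3 * cfg@cytoRadius[2] +
                      max(abs(drift)) * n + moverTot + 2)
    if (2 * margin + 8 > min(shape))
      stop("image too small for the configured cells and motion")
    ctrs <- matrix(NA_real_, cfg@nCells, 2)
    nucAB <- matrix(NA_real_, cfg@nCells, 2)
    cytoAB <- matrix(NA_real_, cfg@nCells, 2)
    phis <- numeric(cfg@nCells)
    tries <- 0L
    for (j in seq_len(cfg@nCells)) {
      placed <- FALSE
      while (!placed) {
        tries <- tries + 1L
        if (tries > 400L * cfg@nCells)
          stop("cannot place ", cfg@nCells,
               " cells without overlap; reduce 'nCells'")
        ctr <- c(stats::runif(1, margin + 1, shape[1] - margin),
                 stats::runif(1, margin + 1, shape[2] - margin))
        nr <- max(4, stats::rnorm(1, cfg@nuclearRadius[1], cfg@nuclearRadius[2]))
        cr <- max(nr + 3, stats::rnorm(1, cfg@cytoRadius[1], cfg@cytoRadius[2]))
        ecc <- stats::runif(1, 0.85, 1)
        phi <- stats::runif(1, 0, pi)
        cyA <- cr / sqrt(ecc)
        if (j > 1) {
          dd <- sqrt(rowSums((ctrs[seq_len(j - 1), , drop = FALSE] -
                              matrix(ctr, j - 1, 2, byrow = TRUE))^2))
          if (any(dd <= cyA + pmax(cytoAB[seq_len(j - 1), 1],
                                   cytoAB[seq_len(j - 1), 2]) + 1)) next
        }
        ctrs[j, ] <- ctr
        nucAB[j, ] <- c(nr / sqrt(ecc), nr * sqrt(ecc))
        cytoAB[j, ] <- c(cyA, cr * sqrt(ecc))
        phis[j] <- phi
        placed <- TRUE
      }
    }

    ## --- per-cell biology --------------------------------------------------
    expr <- stats::rlnorm(cfg@nCells, cfg@expressionMeanlog,
                          cfg@expressionSdlog)
    responder <- stats::runif(cfg@nCells) < cfg@responderFraction
    mover <- stats::runif(cfg@nCells) < cfg@moverFraction
    moverDir <- stats::runif(cfg@nCells, 0, 2 * pi)
    lag <- pmax(0, stats::rnorm(cfg@nCells, cfg@lagMin[1], cfg@lagMin[2]))
    tHalf <- pmax(5, stats::rnorm(cfg@nCells, cfg@tHalfMin[1], cfg@tHalfMin[2]))
    kRate <- pmax(0.03, stats::rnorm(cfg@nCells, cfg@rateK[1], cfg@rateK[2]))
    fold <- pmax(1, stats::rnorm(cfg@nCells, cfg@plateauFold[1],
                                 cfg@plateauFold[2]))

    ## --- fixed-geometry rasterization and areas ----------------------------
    ## fixed geometry: stage offset 0; movers at their final-frame position
    nucLab <- matrix(0L, shape[1], shape[2])
    cytoLab <- matrix(0L, shape[1], shape[2])
    rasFixed <- vector("list", cfg@nCells)
    for (j in seq_len(cfg@nCells)) {
      ras <- .rasterizeCell(shape, ctrs[j, ], phis[j], nucAB[j, ], cytoAB[j, ])
      rasFixed[[j]] <- ras
      sub <- nucLab[ras$rows, ras$cols]; sub[ras$nuc] <- j
      nucLab[ras$rows, ras$cols] <- sub
      sub <- cytoLab[ras$rows, ras$cols]; sub[ras$cyto] <- j
      cytoLab[ras$rows, ras$cols] <- sub
    }
    aNuc <- vapply(rasFixed, function(r) sum(r$nuc), 0L)
    aCyto <- vapply(rasFixed, function(r) sum(r$cyto), 0L)
    if (any(aCyto == 0)) stop("degenerate cell with empty cytoplasm")

    ## cap fold so the conserved cytoplasm stays positive
    foldMax <- 1 + 0.95 * aCyto / (cfg@baselineNCRatio * aNuc)
    fold <- pmin(fold, foldMax)

    naTraj <- matrix(1, cfg@nCells, n)
    for (j in which(responder))
      naTraj[j, ] <- 1 + (fold[j] - 1) *
        stats::plogis(kRate[j] * (tEl - lag[j] - tHalf[j]))

    ## --- render ------------------------------------------------------------
    renderMeans <- function(frameIdx, offset) {
      img <- matrix(cfg@background, shape[1], shape[2])
      nl <- matrix(0L, shape[1], shape[2])
      cl <- matrix(0L, shape[1], shape[2])
      for (j in seq_len(cfg@nCells)) {
        ctr <- ctrs[j, ] + offset
        phi <- phis[j]
        if (mover[j]) {
          step <- cfg@moverDriftPxPerFrame * (frameIdx - n)
          ctr <- ctr + step * c(cos(moverDir[j]), sin(moverDir[j]))
          phi <- phi + cfg@rotationDegPerFrame * (frameIdx - n) * pi / 180
        }
        if (!mover[j] && all(offset == 0)) {
          ras <- rasFixed[[j]]
        } else {
          ras <- .rasterizeCell(shape, ctr, phi, nucAB[j, ], cytoAB[j, ])
        }
        nVal <- cfg@baselineNCRatio * expr[j] * naTraj[j, frameIdx]
        cVal <- expr[j] *
          (1 + cfg@baselineNCRatio * aNuc[j] * (1 - naTraj[j, frameIdx]) /
             aCyto[j])
        gw <- if (responder[j] && fold[j] > 1)
          1 - cfg@gradientShift * (naTraj[j, frameIdx] - 1) / (fold[j] - 1)
        else 1
        sub <- img[ras$rows, ras$cols]
        sub[ras$nuc] <- cfg@background + nVal
        sub[ras$cyto] <- cfg@background +
          cVal * .cytoProfile(ras, cfg@cytoGradient, gw)
        img[ras$rows, ras$cols] <- sub
        sub <- nl[ras$rows, ras$cols]; sub[ras$nuc] <- j
        nl[ras$rows, ras$cols] <- sub
        sub <- cl[ras$rows, ras$cols]; sub[ras$cyto] <- j
        cl[ras$rows, ras$cols] <- sub
      }
      list(img = img, nucLab = nl, cytoLab = cl)
    }

    frames <- vector("list", n)
    frameNucLab <- vector("list", n)
    frameCytoLab <- vector("list", n)
    trueShift <- matrix(0L, n, 2)
    for (i in seq_len(n)) {
      off <- round((i - n - 1) * drift)
      trueShift[i, ] <- as.integer(-off)
      rm_ <- renderMeans(i, off)
      frames[[i]] <- IntensityImage(.addNoise(rm_$img, cfg))
      frameNucLab[[i]] <- rm_$nucLab
      frameCytoLab[[i]] <- rm_$cytoLab
    }

    fixedRender <- renderMeans(n, c(0, 0))
    if (cfg@fixationDimSd > 0) {
      w <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
      sm <- EBImage::gblur(w, sigma = max(8, min(shape) / 12))
      sm <- (sm - mean(sm)) / stats::sd(sm)
      dimField <- cfg@fixationDimFactor * (1 + cfg@fixationDimSd * sm)
      dimField <- pmin(pmax(dimField, 0.05), 1.5)
    } else {
      dimField <- matrix(cfg@fixationDimFactor, shape[1], shape[2])
    }
    fixedTarget <- IntensityImage(.addNoise(fixedRender$img * dimField, cfg))
    nucImg <- matrix(30, shape[1], shape[2])
    nucImg[fixedRender$nucLab > 0L] <- 2800
    fixedNuclear <- IntensityImage(.addNoise(nucImg, cfg))

    field <- Field(frames, fixedTarget, fixedNuclear,
                   fieldId = paste0("sim", cfg@seed),
                   frameIntervalMin = cfg@frameIntervalMin,
                   bitDepth = cfg@bitDepth)
    cells <- data.frame(cell_id = seq_len(cfg@nCells),
      row = ctrs[, 1], col = ctrs[, 2],
      nuc_a = nucAB[, 1], nuc_b = nucAB[, 2],
      cyto_a = cytoAB[, 1], cyto_b = cytoAB[, 2], phi = phis,
      expression = expr, responder = responder, mover = mover,
      mover_dir = moverDir, lag_min = lag, t_half_min = tHalf,
      rate_k = kRate, plateau_fold = fold,
      nuc_area = aNuc, cyto_area = aCyto)
    nuclearPixelValue <- cfg@background +
      cfg@baselineNCRatio * expr * naTraj
    truth <- list(cells = cells, naTrajectory = naTraj,
      nuclearPixelValue = nuclearPixelValue,
      trueShifts = data.frame(frame = seq_len(n), dr = trueShift[, 1],
                              dc = trueShift[, 2]),
      nuclearLabels = LabelMap(fixedRender$nucLab, "nuclear"),
      cytoLabels = LabelMap(fixedRender$cytoLab, "cytoplasmic"),
      frameNuclearLabels = frameNucLab, frameCytoLabels = frameCytoLab,
      dimField = dimField)
    list(field = field, truth = truth)
  })
}

#' Simulate a cell-movement control
#'
#' Cells imaged once live and then fixed: a single live frame plus the
#' fixed-cell pair, the design used to build the stationary-cell control
#' population for the s.d.-vs-mean classifier.
#'
#' @param cfg a \linkS4class{SimConfig}; \code{nFrames} is forced to 1.
#' @return As \code{\link{simulateField}}.
#' @export
simulateControl <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  cfg@nFrames <- 1L
  methods::validObject(cfg)
  simulateField(cfg)
}
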