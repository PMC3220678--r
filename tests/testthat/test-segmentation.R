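# Nuclear/cytoplasmic segmentation from the fixed-cell images.

# independent oracle: exhaustive between-class-variance maximization over
# integer thresholds
otsuOracle <- function(v) {
  lev <- sort(unique(v))
  best <- -Inf; thr <- lev[1]
  for (t in lev[-length(lev)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; thr <- t }
  }
  thr
}

test_that("Otsu separates a two-level image and depends only on the histogram shape", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- otsuThreshold(img)
  expect_gte(t, 10); expect_lt(t, 200)
  expect_identical(otsuThreshold(rbind(img, img)), t)  # duplicated histogram
  expect_error(otsuThreshold(matrix(7, 5, 5)), "constant")
})

test_that("Otsu on a bimodal mixture matches the exhaustive oracle", {
  set.seed(21)
  v <- c(round(rnorm(3000, 50, 10)), round(rnorm(3000, 180, 10)))
  v <- pmax(v, 0)
  img <- matrix(v, 60, 100)
  t <- otsuThreshold(img)
  expect_identical(t, otsuOracle(as.vector(v)))
  expect_gte(t, 80); expect_lte(t, 150)
})

test_that("well-separated nuclei are recovered with the right count and areas", {
  centers <- as.matrix(expand.grid(row = c(40, 100, 160, 220),
                                   col = c(40, 100, 160, 220, 280)))
  img <- diskImage(c(260, 320), centers, r = 12, noiseSd = 20, seed = 2)
  nuc <- segmentNuclei(img)
  expect_identical(length(cellIds(nuc)), nrow(centers))
  # oracle: connected components of the ground-truth foreground
  gt <- diskImage(c(260, 320), centers, r = 12, fg = 1, bg = 0)
  expect_identical(max(EBImage::bwlabel(gt)), nrow(centers))
  areas <- tabulate(labelMatrix(nuc))
  expect_true(all(abs(areas / (pi * 12^2) - 1) < 0.15))
})

test_that("touching nuclei are split by the watershed", {
  # two disks overlapping by ~30% of a radius
  ctr <- rbind(c(60, 50), c(60, 50 + round(2 * 12 - 0.3 * 12)))
  img <- diskImage(c(120, 120), ctr, r = 12, noiseSd = 10, seed = 3)
  nuc <- segmentNuclei(img)
  expect_identical(length(cellIds(nuc)), 2L)
})

test_that("the size filter removes masks below half the mean candidate area", {
  lab <- matrix(0L, 40, 40)
  lab[2:11, 2:11] <- 1L          # 100 px
  lab[2:11, 21:30] <- 2L         # 100 px
  lab[25:30, 25:29] <- 3L        # 30 px
  out <- sizeFilter(LabelMap(lab, "nuclear"), 0.5)
  expect_equal(out@metadata$sizeCutoff, mean(c(100, 100, 30)) / 2)
  expect_equal(out@metadata$sizeCutoff, 38.3333, tolerance = 1e-4)
  expect_identical(out@metadata$removedLabels, 3L)
  expect_identical(length(cellIds(out)), 2L)
  a <- tabulate(labelMatrix(out))
  expect_true(all(a >= 0.5 * mean(a)))   # self-consistency after filtering
})

test_that("an empty image yields an empty map with a warning, not an error", {
  img <- matrix(30, 80, 80) + matrix(runif(6400), 80, 80)
  expect_warning(nuc <- segmentNuclei(img), "no")
  expect_identical(length(cellIds(nuc)), 0L)
})

test_that("cytoplasm is an annulus within d of its nucleus, disjoint from it", {
  shape <- c(80, 80)
  nucMask <- diskMask(shape, c(40, 40), 8)
  cellMask <- diskMask(shape, c(40, 40), 23)       # annulus width 15
  img <- matrix(30, shape[1], shape[2])
  img[cellMask] <- 900
  img[nucMask] <- 810
  nuclei <- LabelMap(nucMask * 1L, "nuclear")
  cyto <- assignCytoplasm(img, nuclei, d = 10)
  cm <- labelMatrix(cyto) > 0L
  expect_true(any(cm))
  expect_false(any(cm & nucMask))
  # every cytoplasmic pixel lies within distance d of the nucleus
  dist <- EBImage::distmap((!nucMask) + 0)
  expect_true(all(dist[cm] <= 10))
  expect_true(all((cellMask | nucMask)[cm]))   # inside the foreground
})

test_that("adjacent cells receive disjoint cytoplasm and dilation is monotone", {
  shape <- c(90, 150)
  img <- matrix(30, shape[1], shape[2])
  n1 <- diskMask(shape, c(45, 50), 8); n2 <- diskMask(shape, c(45, 95), 8)
  c1 <- diskMask(shape, c(45, 50), 23); c2 <- diskMask(shape, c(45, 95), 23)
  img[c1 | c2] <- 900
  img[n1] <- 820; img[n2] <- 800
  nuclei <- LabelMap(n1 * 1L + n2 * 2L, "nuclear")
  cy6 <- assignCytoplasm(img, nuclei, d = 6)
  cy20 <- assignCytoplasm(img, nuclei, d = 20)
  for (cy in list(cy6, cy20)) {
    m <- labelMatrix(cy)
    expect_false(any(m == 1L & m == 2L))
    expect_false(any((m > 0L) & (labelMatrix(nuclei) > 0L)))
  }
  # monotonicity: cytoplasm at d = 6 is contained in cytoplasm at d = 20
  for (k in 1:2)
    expect_true(all(labelMatrix(cy20)[labelMatrix(cy6) == k] == k))
  expect_error(assignCytoplasm(img, nuclei, d = 5), "6..20")
  expect_error(assignCytoplasm(img, nuclei, d = 21), "6..20")
})

test_that("nuclear erosion shrinks regions, preserves labels, flags extinction", {
  lab <- matrix(0L, 40, 40)
  lab[diskMask(c(40, 40), c(20, 20), 12)] <- 1L
  orig <- sum(lab)
  e2 <- erodeNuclei(LabelMap(lab, "nuclear"), 2)
  a2 <- sum(labelMatrix(e2) > 0L)
  expect_lt(a2, orig)
  expect_equal(a2 / (pi * 10^2), 1, tolerance = 0.15)
  expect_true(all(lab[labelMatrix(e2) == 1L] == 1L))   # anti-extensive

  small <- matrix(0L, 20, 20)
  small[diskMask(c(20, 20), c(10, 10), 5)] <- 1L
  expect_warning(e6 <- erodeNuclei(LabelMap(small, "nuclear"), 6),
                 "extinction")
  expect_identical(e6@metadata$extinct, 1L)
  expect_identical(sum(labelMatrix(e6)), 0L)

  expect_error(erodeNuclei(LabelMap(lab, "nuclear"), 1), "2..6")
  expect_error(erodeNuclei(LabelMap(lab, "nuclear"), 7), "2..6")
})

test_that("edge and registration-border cells are excluded", {
  shape <- c(60, 60)
  nin <- diskMask(shape, c(30, 30), 6)      # interior
  nedge <- diskMask(shape, c(5, 30), 6)     # near the top border
  nuclei <- LabelMap(nin * 1L + nedge * 2L, "nuclear")
  cyto <- LabelMap(matrix(0L, 60, 60), "cytoplasmic")
  frameOK <- IntensityImage(matrix(100, 60, 60))

  excl <- excludeEdgeCells(nuclei, cyto, list(frameOK))
  expect_false(excl[["1"]])
  expect_true(excl[["2"]])

  # a (5, 0) shift invalidates the top rows; the edge cell overlaps them
  shifted <- applyShift(frameOK, ShiftTransform(5, 0))
  excl2 <- excludeEdgeCells(nuclei, cyto, list(frameOK, shifted))
  expect_true(excl2[["2"]])
  expect_false(excl2[["1"]])

  onlyEdge <- LabelMap(nedge * 1L, "nuclear")
  expect_warning(excludeEdgeCells(onlyEdge, cyto, list(frameOK)), "all cells")
})

test_that("simulated nuclei are recovered with high IoU and compartments stay disjoint", {
  sim <- simulateField(smallSimConfig(nCells = 12L, nFrames = 2L, seed = 14))
  nuc <- segmentNuclei(fixedNuclear(sim$field))
  ious <- matchIoU(labelMatrix(sim$truth$nuclearLabels), labelMatrix(nuc))
  expect_gte(mean(ious >= 0.7), 0.9)
  cyto <- assignCytoplasm(liveFrames(sim$field)[[1]], nuc, d = 8)
  overlap <- labelMatrix(nuc) > 0L & labelMatrix(cyto) > 0L
  expect_false(any(overlap))
})
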