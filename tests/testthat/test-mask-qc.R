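# Robust s.d.-vs-mean mask classification and quality control.

test_that("mask statistics: constant region, two-point arithmetic, scale equivariance", {
  img <- matrix(0, 10, 10)
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L; img[2:4, 2:4] <- 100          # uniform
  lab[7, 2:3] <- 2L; img[7, 2] <- 90; img[7, 3] <- 110
  st <- measureMaskStats(img, LabelMap(lab, "nuclear"))
  expect_equal(st$mean_fi, c(100, 100), tolerance = 1e-12)
  expect_equal(st$sd_fi, c(0, 10), tolerance = 1e-12)   # population s.d.
  expect_equal(st$cv, c(0, 0.1), tolerance = 1e-12)

  st2 <- measureMaskStats(2 * img, LabelMap(lab, "nuclear"))
  expect_equal(st2$mean_fi, 2 * st$mean_fi, tolerance = 1e-12)
  expect_equal(st2$sd_fi, 2 * st$sd_fi, tolerance = 1e-12)
  expect_equal(st2$cv, st$cv, tolerance = 1e-12)

  lab[9, 9] <- 3L                                     # single-pixel region
  st3 <- measureMaskStats(img, LabelMap(lab, "nuclear"))
  expect_identical(st3$flag[3], "too_few_pixels")
  expect_true(is.na(st3$mean_fi[3]))
})

test_that("the robust line reproduces exact linear data and known coefficients", {
  x <- seq(100, 2000, length.out = 50)
  f <- fitRobustLine(data.frame(mean_fi = x, sd_fi = 2 * x + 1))
  expect_equal(f@slope, 2, tolerance = 1e-9)
  expect_equal(f@intercept, 1, tolerance = 1e-9)
  expect_equal(f@residualScale, 0, tolerance = 1e-9)

  # coefficients of a typical stationary-control fit are recovered from
  # points generated on that line
  f2 <- fitRobustLine(data.frame(mean_fi = x, sd_fi = 0.07821 * x - 16.83))
  expect_equal(f2@slope, 0.07821, tolerance = 1e-6)
  expect_equal(f2@intercept, -16.83, tolerance = 1e-4)
})

test_that("the robust fit resists gross outliers (OLS-on-clean oracle)", {
  set.seed(31)
  x <- seq(200, 1500, length.out = 50)
  y <- 2 * x + 1
  ols <- coef(lm(y ~ x))                       # oracle on the clean subset
  xc <- c(x, 800); yc <- c(y, 10 * (2 * 800 + 1))
  f <- fitRobustLine(data.frame(mean_fi = xc, sd_fi = yc))
  expect_lt(abs(f@slope / ols[2] - 1), 0.01)
  expect_lt(abs(f@slope / 2 - 1), 0.01)

  # cross-check against an independent IRLS implementation on noisy data
  yn <- y + rnorm(50, sd = 15)
  yn[c(5, 25)] <- yn[c(5, 25)] + 400
  f2 <- fitRobustLine(data.frame(mean_fi = x, sd_fi = yn))
  rr <- MASS::rlm(yn ~ x, psi = MASS::psi.bisquare)
  expect_equal(f2@slope, unname(coef(rr)[2]), tolerance = 0.02)

  expect_error(fitRobustLine(data.frame(mean_fi = rep(5, 10),
                                        sd_fi = 1:10)), "degenerate")
  expect_error(fitRobustLine(data.frame(mean_fi = 1:2, sd_fi = 1:2)),
               "3 points")
})

test_that("the prediction band has the right limits and alpha monotonicity", {
  x <- seq(100, 2000, length.out = 50)
  fz <- fitRobustLine(data.frame(mean_fi = x, sd_fi = 2 * x + 1))
  # zero-noise limit: the band collapses onto the line
  expect_equal(bandUpper(fz, c(150, 1000)), 2 * c(150, 1000) + 1,
               tolerance = 1e-6)

  set.seed(5)
  n <- 10000
  xb <- runif(n, 100, 2000)
  yb <- 0.08 * xb + rnorm(n, sd = 3)
  fb <- fitRobustLine(data.frame(mean_fi = xb, sd_fi = yb), alpha = 0.005)
  # large n at the predictor mean: band ~ line + z_{1-alpha/2} * scale
  zref <- fb@slope * fb@xMean + fb@intercept +
    qnorm(0.9975) * fb@residualScale
  expect_equal(bandUpper(fb, fb@xMean), zref, tolerance = 0.001)
  # band widens away from the mean
  expect_gt(bandUpper(fb, fb@xMean + 800) -
            (fb@slope * (fb@xMean + 800) + fb@intercept),
            bandUpper(fb, fb@xMean) - (fb@slope * fb@xMean + fb@intercept))
  # smaller alpha gives a wider band everywhere
  fb5 <- fb; fb5@alpha <- 0.05
  xs <- c(150, 700, 1900)
  expect_true(all(bandUpper(fb, xs) > bandUpper(fb5, xs)))
})

test_that("classification gates on the upper band only", {
  # a fit in the style of a stationary-control population
  fit <- new("RobustFit", slope = 0.07821, intercept = -16.83,
             residualScale = 1.364, n = 310L, xMean = 1000,
             sxx = 310 * 300^2, alpha = 0.005, iterations = 5L,
             converged = TRUE)
  onLine <- data.frame(cell_id = 1L, mean_fi = 1000,
                       sd_fi = 0.07821 * 1000 - 16.83)  # 61.38
  expect_identical(classifyMasks(onLine, fit)$label, "matched")

  far <- data.frame(cell_id = 2L, mean_fi = 1000,
                    sd_fi = 0.07821 * 1000 - 16.83 + 10 * 1.364)
  expect_identical(classifyMasks(far, fit)$label, "mismatched_or_false")

  below <- data.frame(cell_id = 3L, mean_fi = 1000, sd_fi = 0)
  expect_identical(classifyMasks(below, fit)$label, "matched")

  miss <- data.frame(cell_id = 4L, mean_fi = NA_real_, sd_fi = NA_real_)
  cl <- classifyMasks(miss, fit)
  expect_identical(cl$label, "mismatched_or_false")
  expect_identical(cl$reason, "no_stats")
})

test_that("classification is invariant under a common affine intensity rescaling", {
  set.seed(17)
  ctl <- data.frame(mean_fi = runif(200, 300, 1500))
  ctl$sd_fi <- 0.06 * ctl$mean_fi + rnorm(200, sd = 2)
  tst <- data.frame(cell_id = 1:50, mean_fi = runif(50, 300, 1500))
  tst$sd_fi <- 0.06 * tst$mean_fi + rnorm(50, sd = 8)

  fit1 <- fitRobustLine(ctl)
  lab1 <- classifyMasks(tst, fit1)$label

  a <- 2.5; b <- 100   # mean -> a*mean + b, sd -> a*sd
  ctl2 <- data.frame(mean_fi = a * ctl$mean_fi + b, sd_fi = a * ctl$sd_fi)
  tst2 <- data.frame(cell_id = tst$cell_id,
                     mean_fi = a * tst$mean_fi + b, sd_fi = a * tst$sd_fi)
  lab2 <- classifyMasks(tst2, fitRobustLine(ctl2))$label
  expect_identical(lab1, lab2)
})

test_that("decreasing alpha enlarges the matched set monotonically", {
  set.seed(23)
  ctl <- data.frame(mean_fi = runif(300, 300, 1500))
  ctl$sd_fi <- 0.06 * ctl$mean_fi + rnorm(300, sd = 2)
  tst <- data.frame(cell_id = 1:100, mean_fi = runif(100, 300, 1500))
  tst$sd_fi <- 0.06 * tst$mean_fi + rnorm(100, sd = 6)
  mSets <- lapply(c(0.1, 0.02, 0.005), function(a) {
    cl <- classifyMasks(tst, fitRobustLine(ctl, alpha = a))
    cl$cell_id[cl$label == "matched"]
  })
  expect_true(all(mSets[[1]] %in% mSets[[2]]))
  expect_true(all(mSets[[2]] %in% mSets[[3]]))
})

test_that("artificial mismatches behave as set algebra demands", {
  mask <- diskMask(c(60, 60), c(30, 30), 8)   # width 16

  idm <- makeMismatch(mask, 0, 0, 0)
  expect_identical(idm$mismatched, mask)
  expect_identical(idm$intersected, mask)

  mm <- makeMismatch(mask, dr = 8, dc = 0)
  expect_lt(sum(mm$intersected), sum(mask))
  expect_true(all(mask[mm$intersected]))         # intersected in original
  expect_true(all(mm$mismatched[mm$intersected]))
  expect_equal(sum(mm$mismatched), sum(mask), tolerance = 0.05)

  rot <- makeMismatch(mask, 0, 0, theta = 30)
  expect_equal(sum(rot$mismatched), sum(mask), tolerance = 0.05)

  far <- makeMismatch(mask, dr = 18, dc = 0)
  expect_true(far$emptyIntersection)

  expect_error(makeMismatch(mask, dr = 40, dc = 0), "bounds")
})

test_that("shape QC flags the deviating cell and measures the disk perimeter", {
  shape <- c(140, 140)
  ctrs <- as.matrix(expand.grid(row = c(30, 70, 110), col = c(30, 70, 110)))
  nuc <- matrix(0L, shape[1], shape[2])
  img <- matrix(30, shape[1], shape[2])
  for (i in seq_len(nrow(ctrs))) {
    m <- diskMask(shape, ctrs[i, ], 12)
    if (i == 5) m <- m & !diskMask(shape, ctrs[i, ] + c(0, 6), 9)  # bitten
    nuc[m] <- i
    img[m] <- 800
  }
  cyto <- LabelMap(matrix(0L, shape[1], shape[2]), "cytoplasmic")
  qc <- shapeQC(LabelMap(nuc, "nuclear"), cyto, img, img)

  # oracle: direct robust z-score on solidity
  v <- qc$nuclear_solidity
  z <- abs(v - median(v)) / (1.4826 * mad(v, constant = 1))
  expect_true(qc$flagged[5])
  expect_gt(z[5], 3)
  expect_true(grepl("solidity", qc$flagged_params[5]))
  expect_lt(qc$nuclear_solidity[5], min(qc$nuclear_solidity[-5]))
  # digital disk of r = 12: chain-length perimeter within 15% of 2*pi*12
  expect_equal(qc$nuclear_perimeter[1], 2 * pi * 12, tolerance = 0.15)
})

test_that("identical synthetic cells raise no QC flags", {
  shape <- c(100, 100)
  ctrs <- as.matrix(expand.grid(row = c(25, 75), col = c(25, 75)))
  nuc <- matrix(0L, shape[1], shape[2])
  img <- matrix(30, shape[1], shape[2])
  for (i in seq_len(nrow(ctrs))) {
    m <- diskMask(shape, ctrs[i, ], 10)
    nuc[m] <- i; img[m] <- 500
  }
  qc <- shapeQC(LabelMap(nuc, "nuclear"),
                LabelMap(matrix(0L, shape[1], shape[2]), "cytoplasmic"),
                img, img)
  expect_false(any(qc$flagged))
})
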