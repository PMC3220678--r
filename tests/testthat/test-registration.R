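# Masked normalized cross-correlation registration.

# independent oracle: direct correlation over the shift grid, computed with
# plain submatrix extraction and cor()
nccOracle <- function(mov, ref, maxShift) {
  d <- dim(mov)
  best <- -Inf; bestShift <- c(NA, NA)
  for (dr in -maxShift:maxShift) for (dc in -maxShift:maxShift) {
    sr <- max(1, 1 - dr):min(d[1], d[1] - dr)
    sc <- max(1, 1 - dc):min(d[2], d[2] - dc)
    a <- mov[sr, sc]
    b <- ref[sr + dr, sc + dc]
    if (length(a) < 0.25 * prod(d)) next
    if (sd(a) == 0 || sd(b) == 0) next
    v <- cor(as.vector(a), as.vector(b))
    if (v > best + 1e-12) { best <- v; bestShift <- c(dr, dc) }
  }
  list(shift = bestShift, peak = best)
}

test_that("self-correlation yields the zero shift with peak 1", {
  img <- texturedFrame(c(60, 80), seed = 4)
  t <- nccShift(img, img, maxShift = 8)
  expect_identical(c(t@dr, t@dc), c(0L, 0L))
  expect_equal(t@peakCorrelation, 1, tolerance = 1e-6)
})

test_that("a pure translation is recovered exactly, in both directions", {
  ref <- texturedFrame(c(80, 100), seed = 7)
  mov <- applyShift(IntensityImage(ref), ShiftTransform(3, -5))
  t <- nccShift(mov, ref, maxShift = 10)
  expect_identical(c(t@dr, t@dc), c(-3L, 5L))
  t2 <- nccShift(ref, mov, maxShift = 10)
  expect_identical(c(t2@dr, t2@dc), c(3L, -5L))
  expect_gt(t@peakCorrelation, 0.999)
})

test_that("translation recovery under noise matches the exhaustive oracle", {
  set.seed(42)
  ref <- texturedFrame(c(70, 90), seed = 9, scale = 1000)
  mov0 <- pixels(applyShift(IntensityImage(ref), ShiftTransform(-4, 6)))
  noiseSd <- sd(ref) / 10            # SNR 10
  mov <- pmax(mov0 + rnorm(length(mov0), sd = noiseSd), 0)
  refN <- pmax(ref + rnorm(length(ref), sd = noiseSd), 0)
  t <- nccShift(mov, refN, maxShift = 10)
  orc <- nccOracle(mov, refN, 10)
  expect_identical(c(t@dr, t@dc), as.integer(orc$shift))
  expect_identical(c(t@dr, t@dc), c(4L, -6L))
  expect_equal(t@peakCorrelation, orc$peak, tolerance = 1e-6)
})

test_that("the correlation is invariant under affine intensity rescaling", {
  ref <- texturedFrame(c(60, 80), seed = 11)
  mov <- applyShift(IntensityImage(ref), ShiftTransform(2, 3))
  t1 <- nccShift(mov, ref, maxShift = 6)
  t2 <- nccShift(IntensityImage(2.7 * pixels(mov) + 55, validMask(mov)),
                 ref, maxShift = 6)
  t3 <- nccShift(mov, 0.5 * ref + 10, maxShift = 6)
  expect_identical(c(t1@dr, t1@dc), c(t2@dr, t2@dc))
  expect_identical(c(t1@dr, t1@dc), c(t3@dr, t3@dc))
  expect_equal(t1@peakCorrelation, t2@peakCorrelation, tolerance = 1e-6)
})

test_that("applyShift geometry: identity, border invalidation, composition", {
  img <- IntensityImage(matrix(runif(100), 10, 10))
  id <- applyShift(img, ShiftTransform(0, 0))
  expect_identical(pixels(id), pixels(img))
  expect_identical(validMask(id), validMask(img))

  sh <- applyShift(img, ShiftTransform(2, 0))
  expect_false(any(validMask(sh)[1:2, ]))
  expect_true(all(validMask(sh)[3:10, ]))
  expect_identical(pixels(sh)[3:10, ], pixels(img)[1:8, ])

  fwd <- applyShift(img, ShiftTransform(3, -5))
  back <- applyShift(fwd, ShiftTransform(-3, 5))
  both <- validMask(back)
  expect_true(any(both))
  expect_identical(pixels(back)[both], pixels(img)[both])
  # valid area never grows
  expect_lte(sum(validMask(back)), sum(validMask(fwd)))
  expect_lte(sum(validMask(fwd)), sum(validMask(img)))
})

test_that("degenerate inputs are rejected", {
  expect_error(nccShift(matrix(5, 20, 20), matrix(runif(400), 20, 20), 4),
               "constant")
  expect_error(nccShift(matrix(runif(400), 20, 20),
                        matrix(runif(100), 10, 10), 4), "dimensions")
  expect_error(applyShift(matrix(runif(100), 10, 10), ShiftTransform(10, 0)),
               "smaller")
})

test_that("chained registration recovers a per-frame stage drift", {
  sim <- simulateField(smallSimConfig(nFrames = 5L,
    stageDriftPxPerFrame = c(1, 1), seed = 3))
  reg <- registerSeries(sim$field, maxShift = 10)
  expect_identical(reg$shifts$dr, sim$truth$trueShifts$dr)
  expect_identical(reg$shifts$dc, sim$truth$trueShifts$dc)
  expect_identical(reg$shifts$dr, 5:1)

  # chain agrees with direct-to-reference registration within 1 px per axis
  for (i in seq_len(5)) {
    td <- nccShift(liveFrames(sim$field)[[i]], fixedTarget(sim$field),
                   maxShift = 10)
    expect_lte(abs(td@dr - reg$shifts$dr[i]), 1)
    expect_lte(abs(td@dc - reg$shifts$dc[i]), 1)
  }
})

test_that("a single-frame series registers directly against the fixed image", {
  sim <- simulateControl(smallSimConfig(seed = 8,
    stageDriftPxPerFrame = c(2, -1)))
  expect_identical(nFrames(sim$field), 1L)
  reg <- registerSeries(sim$field, maxShift = 10)
  expect_identical(nrow(reg$shifts), 1L)
  expect_identical(reg$shifts$dr, sim$truth$trueShifts$dr)
  expect_identical(reg$shifts$dc, sim$truth$trueShifts$dc)
})

test_that("registered series keeps enough valid area (border-loss bound)", {
  sim <- simulateField(smallSimConfig(nFrames = 4L,
    stageDriftPxPerFrame = c(1, 2), seed = 5))
  reg <- registerSeries(sim$field, maxShift = 10)
  d <- dim(pixels(fixedTarget(sim$field)))
  for (fr in reg$frames)
    expect_gte(sum(validMask(fr)), prod(d) - 4 * 10 * (d[1] + d[2]))
})
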