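# Synthetic image builders shared across tests. All fixtures are generated
# in code; no image files are stored.

# logical disk mask
diskMask <- function(shape, center, r) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

# image of bright disks on a dark background
diskImage <- function(shape, centers, r, fg = 3000, bg = 30, noiseSd = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(bg, shape[1], shape[2])
  for (i in seq_len(nrow(centers)))
    img[diskMask(shape, centers[i, ], r)] <- fg
  if (noiseSd > 0) img <- pmax(img + rnorm(length(img), sd = noiseSd), 0)
  img
}

# a textured, smooth random frame (cell-free) for registration tests
texturedFrame <- function(shape, seed = 1, scale = 1000) {
  set.seed(seed)
  w <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  sm <- EBImage::gblur(w, sigma = 4)
  sc <- (sm - min(sm)) / diff(range(sm))
  sc * scale
}

# small, fast simulator configuration for unit tests
smallSimConfig <- function(...) {
  args <- list(...)
  defaults <- list(nCells = 10L, imageShape = c(192L, 240L), nFrames = 5L,
    nuclearRadius = c(8, 0.8), cytoRadius = c(14, 1), moverFraction = 0,
    stageDriftPxPerFrame = c(0, 0), seed = 1L)
  do.call(SimConfig, utils::modifyList(defaults, args))
}

# intersection-over-union of two logical masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# match each true nucleus to the segmented label with maximal overlap and
# return the per-cell IoU
matchIoU <- function(trueLab, segLab) {
  ids <- sort(setdiff(unique(as.vector(trueLab)), 0L))
  vapply(ids, function(k) {
    tm <- trueLab == k
    ov <- table(segLab[tm & segLab > 0L])
    if (!length(ov)) return(0)
    best <- as.integer(names(ov)[which.max(ov)])
    iou(tm, segLab == best)
  }, 0)
}
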