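test_that("segmentation recovers the true lumen and rejects degenerate
           input", {
  cfg <- smallConfig()
  ft <- seq(0, 10, by = 2)
  img <- generatePhantom(cfg, frameTimes = ft)
  mask <- segmentLumen(img)
  truth <- lumenMask(cfg, ft)
  expect_gte(dice(mask, truth), 0.95)
  expect_error(segmentLumen(new("ImageSeries",
                                values = array(0, c(8, 8, 1, 2)),
                                voxelSize = c(1, 1, 1), frameTimes = c(0, 1),
                                provenance = "z")), "segmentation")
  ## threshold 0 on a positive image flags the whole foreground
  pos <- new("ImageSeries", values = array(1, c(6, 6, 1, 1)) , voxelSize =
               c(1, 1, 1), frameTimes = 0, provenance = "p")
  expect_true(all(segmentLumen(pos, threshold = 0)))
})

test_that("the antral axis tracks the tube centreline", {
  cfg <- phantomConfig()
  ft <- seq(0, 10, by = 2)
  mask <- lumenMask(cfg, ft)
  truthAx <- antralAxisTruth(cfg)
  hints <- truthAx[c(1, nrow(truthAx)), ]
  ax <- antralAxis(mask, cfg@voxelSize, hints = hints)
  ## within one in-plane voxel of the true centreline
  expect_lt(max(abs(ax[, 1] - cfg@antrumCenter[1])), 0.5)
  expect_lt(max(abs(ax[, 2] - cfg@antrumCenter[2])), 0.5)
  ## arc length within 5% of the tube length
  arc <- attr(ax, "arclength")
  expect_lt(abs(arc[length(arc)] - 6) / 6, 0.05)
  expect_error(antralAxis(mask, cfg@voxelSize,
                          hints = rbind(c(1, 1, 1), c(1, 1, 1))), "differ")
})

test_that("cross-sectional areas match the circle analytics", {
  cfg <- phantomConfig(contractionAmplitude = 0)
  ft <- c(0, 2)
  mask <- lumenMask(cfg, ft)
  ax <- antralAxis(mask, cfg@voxelSize,
                   hints = antralAxisTruth(cfg)[c(1, 9), ])
  ats <- crossSectionAreas(mask, ax, c(0.75, 2.25), cfg@voxelSize, ft)
  ## static tube of radius 3 mm: area ~ pi * 9 within 10% (voxelization)
  for (s in ats)
    expect_lt(max(abs(areas(s) - pi * 9)) / (pi * 9), 0.10)
  ## occluded radius scaled by 1 - A: area ratio (1 - A)^2
  cfgA <- phantomConfig()
  maskA <- lumenMask(cfgA, seq(0, 20, by = 0.5))
  axA <- antralAxis(maskA, cfgA@voxelSize,
                    hints = antralAxisTruth(cfgA)[c(1, 9), ])
  aA <- areas(crossSectionAreas(maskA, axA, 2.25, cfgA@voxelSize,
                                seq(0, 20, by = 0.5))[[1]])
  expect_equal(min(aA) / max(aA), (1 - 0.231)^2, tolerance = 0.08)
  ## a frame with an empty mask yields area 0
  m0 <- maskA
  m0[, , , 3] <- FALSE
  a0 <- areas(crossSectionAreas(m0, axA, 2.25, cfgA@voxelSize,
                                seq(0, 20, by = 0.5))[[1]])
  expect_equal(a0[3], 0)
  expect_error(crossSectionAreas(maskA, axA, 99, cfgA@voxelSize, ft),
               "outside")
})

test_that("extrema detection counts cycles and survives mild noise", {
  tt <- seq(0, 120 - 0.5, by = 0.5)
  a <- 20 + 5 * sin(2 * pi * tt / 12)      # 10 cycles
  s <- new("AreaTimeSeries", position = 0, times = tt, areas = a)
  det <- detectExtrema(s)
  expect_length(peakIndices(det), 10L)
  expect_length(valleyIndices(det), 10L)
  ## alternation
  idx <- sort(c(peakIndices(det), valleyIndices(det)))
  typ <- idx %in% peakIndices(det)
  expect_true(all(typ[-1] != typ[-length(typ)]))
  expect_error(detectExtrema(new("AreaTimeSeries", position = 0,
                                 times = tt, areas = rep(1, length(tt)))),
               "extrema")
  set.seed(9)
  noisy <- s
  noisy@areas <- a + rnorm(length(a), sd = diff(range(a)) / 20)
  detN <- detectExtrema(noisy)
  expect_length(peakIndices(detN), 10L)
  expect_length(valleyIndices(detN), 10L)
})

test_that("contraction amplitude is the peak-normalized excursion", {
  a <- c(7.5, 10, 7.5, 10, 7.5, 10, 7.5)   # symmetric peaks and valleys
  s <- new("AreaTimeSeries", position = 0, times = seq_along(a),
           areas = a, peaks = c(2L, 4L, 6L), valleys = c(3L, 5L))
  expect_equal(contractionAmplitude(s), 0.25)
  flat <- new("AreaTimeSeries", position = 0, times = 1:4,
              areas = c(9, 10, 10, 9), peaks = 2L, valleys = 3L)
  expect_equal(contractionAmplitude(flat), 0)
  noPair <- new("AreaTimeSeries", position = 0, times = 1:4,
                areas = c(9, 10, 9, 8), peaks = 2L, valleys = integer())
  expect_error(contractionAmplitude(noPair), "pair")
})

test_that("dominant frequency lands on the expected FFT bin", {
  ## 5 cpm sampled every 2 s for 4 min: exact bin
  tt <- seq(0, 238, by = 2)
  s5 <- new("AreaTimeSeries", position = 0, times = tt,
            areas = 10 + sin(2 * pi * tt * 5 / 60))
  expect_equal(contractionFrequency(s5), 5)
  ## 5.3 cpm over 10 min: within one bin width (0.1 cpm)
  t10 <- seq(0, 598, by = 2)
  s53 <- new("AreaTimeSeries", position = 0, times = t10,
             areas = 10 + sin(2 * pi * t10 * 5.3 / 60))
  expect_lt(abs(contractionFrequency(s53) - 5.3), 0.1 + 1e-9)
  ## scale invariance
  s2 <- s53; s2@areas <- 17 * s53@areas
  expect_equal(contractionFrequency(s2), contractionFrequency(s53))
  expect_error(contractionFrequency(
    new("AreaTimeSeries", position = 0, times = tt,
        areas = rep(3, length(tt)))), "non-DC")
  expect_error(contractionFrequency(
    new("AreaTimeSeries", position = 0, times = 1:4, areas = 1:4)), "8")
})

test_that("irregular gated frame times are resampled before the FFT", {
  set.seed(4)
  tt <- cumsum(runif(200, 1.6, 2.4))
  s <- new("AreaTimeSeries", position = 0, times = tt,
           areas = 10 + sin(2 * pi * tt * 5 / 60))
  expect_lt(abs(contractionFrequency(s) - 5), 0.25)
})

test_that("propagation velocity recovers an imposed fractional delay", {
  tt <- seq(0, 118, by = 2)
  f <- function(t) 20 + 5 * sin(2 * pi * t / 11.32)
  sA <- new("AreaTimeSeries", position = 0, times = tt, areas = f(tt))
  sB <- new("AreaTimeSeries", position = 3, times = tt,
            areas = f(tt - 5.357))
  v <- propagationVelocity(sA, sB)
  expect_equal(v, 3 / 5.357, tolerance = 0.03)
  expect_error(propagationVelocity(sA, sA, distance = 3), "zero")
  set.seed(2)
  nA <- sA; nA@areas <- rnorm(length(tt))
  nB <- sB; nB@areas <- rnorm(length(tt))
  expect_error(propagationVelocity(nA, nB, distance = 3))
})

test_that("luminal volume arithmetic is exact", {
  mask <- array(FALSE, c(40, 40, 10, 2))
  mask[seq_len(13867)] <- TRUE             # frame 1 only
  vol <- gastricVolume(mask, c(0.5, 0.5, 1.5))
  expect_equal(vol$perFrame[1], 13867 * 0.375 / 1000)
  expect_equal(round(vol$perFrame[1], 2), 5.2)
  expect_equal(vol$perFrame[2], 0)
  vol2 <- gastricVolume(mask, c(0.5, 0.5, 3.0))
  expect_equal(vol2$perFrame[1], 2 * vol$perFrame[1])
})

test_that("the full motility analysis recovers the phantom ground truth", {
  cfg <- phantomConfig()
  img <- generatePhantom(cfg, frameTimes = defaultFrameTimes(45))
  hints <- antralAxisTruth(cfg)[c(1, 9), ]
  m <- measureMotility(img, hints = hints, positions = c(0.75, 2.25, 3.75))
  expect_lt(abs(m@amplitudeRadius - 0.231), 0.02)
  expect_lt(abs(m@frequency - 5.3), 60 / 90 + 1e-9)  # one bin of a 90 s record
  expect_lt(abs(m@velocity - 0.56) / 0.56, 0.10)
  ana <- mean(lumenVolume(cfg, times = defaultFrameTimes(9, dt = 10)))
  expect_lt(abs(m@volume - ana) / ana, 0.05)
})
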