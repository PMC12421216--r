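test_that("kernel geometry has R - 1 shapes with the expected sources", {
  g3 <- ktKernelGeometry(3L)
  expect_length(g3@shapes, 2L)                 # two shapes at R = 3
  g2 <- ktKernelGeometry(2L)
  expect_length(g2@shapes, 1L)
  g4 <- ktKernelGeometry(4L)
  expect_length(g4@shapes, 3L)
  for (sh in g4@shapes) {
    expect_gte(nrow(sh$sources), 4L)
    expect_gte(length(unique(sh$sources[, 2L])), 2L)
  }
  ## translation-invariant stencil: only sampled lattice offsets appear
  for (sh in g3@shapes)
    expect_true(all((sh$sources[, 1L] - sh$sources[, 2L] + sh$d) %% 3L == 0L))
  expect_error(ktKernelGeometry(3L, tWindow = 1L), "window")
  expect_error(ktKernelGeometry(1L), "reduction")
})

test_that("data generated by the kernel model are recovered exactly", {
  ## DFT-periodic plane waves obey every shift-invariant k-t model
  for (cse in list(list(R = 2L, ny = 16L), list(R = 3L, ny = 18L))) {
    ks <- planeWaveKspace(16L, cse$ny, 6L)
    ku <- applyMask(ks, samplingPattern(cse$ny, 6L, cse$R))
    cal <- suppressWarnings(calibrateKernels(ku, ktKernelGeometry(cse$R)))
    expect_lt(max(cal$report$residual), 1e-10)
    kf <- interpolateKspace(ku, cal$kernels)
    expect_lt(kspaceRE(kspaceData(kf), kspaceData(ks)), 1e-8)
    ## data consistency: sampled entries are untouched bit-exactly
    m <- samplingMask(ku)[, 1, 3]
    expect_identical(kspaceData(kf)[, m, , 3], kspaceData(ku)[, m, , 3])
  }
})

test_that("calibration matches an independent normal-equations oracle", {
  k <- randomKspace(16, 16, 1, 6)
  p <- samplingPattern(16L, 8L, 3L)
  ku <- applyMask(k, p)
  geom <- ktKernelGeometry(3L)
  cal <- calibrateKernels(ku, geom)
  acsRows <- acsLines(p)
  nT <- 6L
  for (key in names(geom@shapes)) {
    sh <- cal$kernels@shapes[[key]]
    frames <- which(seq_len(nT) + sh$dts[1] >= 1 &
                      seq_len(nT) + sh$dts[length(sh$dts)] <= nT)
    w0 <- oracleKernelWeights(kspaceData(ku), sh$sources, 2L, acsRows,
                              frames)
    expect_lt(max(Mod(sh$weights[, 1] - w0)) / max(Mod(w0)), 1e-8)
  }
})

test_that("calibration is deterministic and reports sane diagnostics", {
  k <- randomKspace(16, 18, 2, 6, seed = 21L)
  ku <- applyMask(k, samplingPattern(18L, 8L, 3L))
  a <- calibrateKernels(ku, ktKernelGeometry(3L))
  b <- calibrateKernels(ku, ktKernelGeometry(3L))
  expect_identical(a$kernels@shapes, b$kernels@shapes)
  expect_true(all(a$report$residual >= 0))
  expect_true(all(a$report$nEquations >= a$report$nWeights))
  ## per-slice calibration yields one weight column per slice
  ps <- calibrateKernels(ku, ktKernelGeometry(3L), perSlice = TRUE)
  expect_equal(ncol(ps$kernels@shapes[[1]]$weights), 2L)
})

test_that("degenerate calibration inputs fail loudly", {
  k <- randomKspace(8, 12, 1, 2)
  ku <- applyMask(k, samplingPattern(12L, 6L, 3L))
  ## frame count below the temporal window
  expect_error(calibrateKernels(ku, ktKernelGeometry(3L)), "window")
  ## too few ACS lines for the stencil span
  k2 <- randomKspace(8, 12, 1, 6)
  ku2 <- applyMask(k2, samplingPattern(12L, 2L, 3L))
  expect_error(calibrateKernels(ku2, ktKernelGeometry(3L)))
})

test_that("interpolation respects the mask contract", {
  ks <- planeWaveKspace(16L, 18L, 6L)
  ku <- applyMask(ks, samplingPattern(18L, 6L, 3L))
  cal <- suppressWarnings(calibrateKernels(ku, ktKernelGeometry(3L)))
  ## fully sampled input is returned unchanged
  same <- interpolateKspace(ks, cal$kernels)
  expect_identical(kspaceData(same), kspaceData(ks))
  ## inconsistent mask (a line the phase rule says is sampled) is rejected
  bad <- ku
  bad@mask[8, , 2] <- FALSE    # ACS row: phase 0 at frame 2
  bad@data[, 8, , 2] <- 0+0i
  expect_error(interpolateKspace(bad, cal$kernels), "phase rule")
})

test_that("image reconstruction round-trips and handles degenerate input", {
  img <- generatePhantom(smallConfig(), frameTimes = c(0, 2))
  rec <- reconstructImages(phantomToKspace(img))
  expect_lt(max(abs(intensities(rec) - intensities(img))), 1e-10)
  z <- new("KSpaceSeries", data = array(0+0i, c(8, 8, 1, 1)),
           mask = array(TRUE, c(8, 1, 1)), voxelSize = c(1, 1, 1),
           frameTimes = 0, acqParams = list())
  expect_true(all(intensities(reconstructImages(z)) == 0))
  dcOnly <- z
  dcOnly@data[5, 5, 1, 1] <- 64+0i
  vals <- intensities(reconstructImages(dcOnly))
  expect_equal(max(vals) - min(vals), 0)
  expect_equal(vals[1, 1, 1, 1], 1)
})

test_that("reconstruction degrades with higher undersampling on a small
           dynamic phantom", {
  ref <- generatePhantom(smallConfig(), frameTimes = defaultFrameTimes(24))
  kfull <- phantomToKspace(ref)
  res <- vapply(c(3L, 8L), function(R) {
    ku <- applyMask(kfull, samplingPattern(32L, 8L, R))
    cal <- suppressWarnings(calibrateKernels(ku, ktKernelGeometry(R)))
    rec <- reconstructImages(interpolateKspace(ku, cal$kernels))
    relativeError(normalize01(rec), normalize01(ref))
  }, numeric(1))
  expect_lt(res[1], res[2])
})
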