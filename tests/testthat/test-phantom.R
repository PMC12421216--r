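test_that("saturation recovery follows the closed form and its bounds", {
  expect_equal(saturationRecoveryFraction(127, 800), 1 - exp(-127 / 800))
  expect_equal(saturationRecoveryFraction(127, 800), 0.1468, tolerance = 1e-3)
  expect_lt(saturationRecoveryFraction(127, 800), 0.20)  # tissue barely recovers
  expect_equal(saturationRecoveryFraction(127, 17), 0.99943, tolerance = 1e-4)
  expect_identical(saturationRecoveryFraction(0, 800), 0)
  expect_error(saturationRecoveryFraction(127, 0), "t1")
  expect_error(saturationRecoveryFraction(-1, 17), "tRec")
  ## monotone in tRec, antitone in t1
  tr <- seq(0, 500, by = 25)
  expect_true(all(diff(saturationRecoveryFraction(tr, 300)) > 0))
  t1 <- seq(10, 900, by = 50)
  expect_true(all(diff(saturationRecoveryFraction(127, t1)) < 0))
})

test_that("test-meal dilution arithmetic", {
  expect_equal(dilutionConcentration(182, 1, 25), 7)
  expect_equal(dilutionConcentration(123, 2, 0), 123)
  expect_equal(dilutionConcentration(100, 1, 1), 50)
  expect_error(dilutionConcentration(100, 0, 0), "volume")
})

test_that("tissue properties enforce the contrast premise", {
  expect_error(tissueProperties(t1Lumen = 900, t1Tissue = 800), "t1Lumen")
  expect_error(tissueProperties(tRec = -1), "times")
  expect_s4_class(tissueProperties(), "TissueProperties")
})

test_that("phantom config rejects non-physical parameters", {
  expect_error(phantomConfig(contractionAmplitude = 1), "contractionAmplitude")
  expect_error(phantomConfig(contractionFrequency = 0), "contractionFrequency")
  expect_error(phantomConfig(voxelSize = c(0.5, -1, 1.5)), "voxel")
  ## geometry must fit inside the grid
  expect_error(phantomConfig(grid = c(16L, 16L, 2L)), "too small")
})

test_that("a static noiseless phantom has identical frames and the
           lumen/tissue ratio of the recovery fractions", {
  cfg <- smallConfig(contractionAmplitude = 0)
  ti <- tissueProperties()
  img <- generatePhantom(cfg, ti, frameTimes = seq(0, 8, by = 2))
  v <- intensities(img)
  for (t in 2:dim(v)[4])
    expect_identical(v[, , , t], v[, , , 1])
  ## median of the sub-lumen foreground is the tissue plateau (partial-
  ## volume boundary voxels are rare)
  ratio <- max(v) / stats::median(v[v < 0.5 & v > 0.05])
  expect_equal(ratio,
               saturationRecoveryFraction(ti@tRec, ti@t1Lumen) /
                 (ti@tissueBase *
                    saturationRecoveryFraction(ti@tRec, ti@t1Tissue)),
               tolerance = 1e-10)
})

test_that("identical seeds give identical noisy phantoms", {
  cfg <- smallConfig(noiseSigma = 0.05, seed = 42L)
  a <- generatePhantom(cfg, frameTimes = c(0, 2, 4))
  b <- generatePhantom(cfg, frameTimes = c(0, 2, 4))
  expect_identical(intensities(a), intensities(b))
  cfg2 <- smallConfig(noiseSigma = 0.05, seed = 43L)
  c2 <- generatePhantom(cfg2, frameTimes = c(0, 2, 4))
  expect_false(identical(intensities(a), intensities(c2)))
})

test_that("the occlusion wave is periodic at the configured frequency and
           arrives later downstream", {
  cfg <- phantomConfig()   # A = 0.231, f = 5.3 cpm, v = 0.56 mm/s
  ft <- defaultFrameTimes(60)   # 2 s frames, 2 min record
  occ <- lumenMask(cfg, ft)
  ## in-plane area of the tube at two slices (1.5 mm apart in z)
  a1 <- apply(occ[, , 1, ], 3, sum)
  a2 <- apply(occ[, , 3, ], 3, sum)   # 3 mm downstream
  s1 <- new("AreaTimeSeries", position = 0.75, times = ft, areas = a1 * 0.25)
  s2 <- new("AreaTimeSeries", position = 3.75, times = ft, areas = a2 * 0.25)
  ## period 60 / 5.3 = 11.32 s within one FFT bin (0.5 cpm)
  expect_lt(abs(contractionFrequency(s1) - 5.3), 0.5 + 1e-9)
  ## lag 3 mm / 0.56 mm/s = 5.36 s: recovered velocity within 10%
  v <- propagationVelocity(s1, s2, distance = 3)
  expect_lt(abs(v - 0.56) / 0.56, 0.10)
})

test_that("respiration traces have one burst per cycle and are
           deterministic under a seed", {
  tr <- simulateRespiration(60, 10, samplingRate = 100)
  bursts <- sum(diff(tr@pressure > 0.5) == 1)
  expect_equal(bursts, 10)
  tr2 <- simulateRespiration(30, 60, samplingRate = 100)
  expect_equal(sum(diff(tr2@pressure > 0.5) == 1), 30)
  ja <- simulateRespiration(45, 20, jitter = 0.05, seed = 5L)
  jb <- simulateRespiration(45, 20, jitter = 0.05, seed = 5L)
  expect_identical(ja@pressure, jb@pressure)
  expect_error(simulateRespiration(60, 10, samplingRate = 3), "sampling rate")
})

test_that("the forward Fourier model round-trips, concentrates constants at
           DC, and satisfies Parseval", {
  cfg <- smallConfig()
  img <- generatePhantom(cfg, frameTimes = c(0, 2))
  k <- phantomToKspace(img)
  rec <- reconstructImages(k)
  expect_lt(max(abs(intensities(rec) - intensities(img))), 1e-10)
  ## constant image: all energy in the centred DC sample
  cimg <- new("ImageSeries", values = array(3, c(8, 8, 1, 1)),
              voxelSize = c(1, 1, 1), frameTimes = 0, provenance = "c")
  kc <- kspaceData(phantomToKspace(cimg))[, , 1, 1]
  expect_equal(Mod(kc[5, 5]), 3 * 64)
  expect_lt(max(Mod(kc[-(4 * 8 + 5)])), 1e-10)
  ## Parseval under the stated convention
  e_img <- sum(intensities(img)[, , 1, 1]^2)
  e_k <- sum(Mod(kspaceData(k)[, , 1, 1])^2) / (32 * 32)
  expect_equal(e_img, e_k)
})

test_that("respiration displacement shifts the lumen through-plane", {
  ## contraction disabled so only respiration can move the lumen; corpus
  ## placed so its in-plane footprint extends beyond the tube
  cfg <- smallConfig(respirationDisplacement = 1.5, respirationRate = 30,
                     contractionAmplitude = 0, corpusCenter = c(6, 8, 3))
  ## frame at burst peak vs quiescent frame
  m <- lumenMask(cfg, frameTimes = c(0.2, 1.0))
  expect_false(identical(m[, , , 1], m[, , , 2]))
  cfg0 <- smallConfig(contractionAmplitude = 0, corpusCenter = c(6, 8, 3))
  m0 <- lumenMask(cfg0, frameTimes = c(0.2, 1.0))
  expect_identical(m0[, , , 1], m0[, , , 2])
})
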