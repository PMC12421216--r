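test_that("line masks follow the interleaving rule with a centred ACS", {
  p <- samplingPattern(9L, 3L, 3L)
  expect_identical(acsLines(p), 4:6)          # 0-based rows {3,4,5}
  expect_identical(which(buildMask(p, 1L)), c(1L, 4L, 5L, 6L, 7L))
  ## union of R consecutive frames covers every line
  u <- buildMask(p, 1L) | buildMask(p, 2L) | buildMask(p, 3L)
  expect_true(all(u))
  ## R = 1 samples everything each frame
  p1 <- samplingPattern(9L, 3L, 1L)
  expect_true(all(buildMask(p1, 1L)))
  ## even nACS: DC line is the upper-middle ACS line
  p2 <- samplingPattern(64L, 12L, 3L)
  expect_identical(acsLines(p2), 27:38)       # DC (33) is the 7th of 12
  expect_true((64L %/% 2L + 1L) %in% acsLines(p2))
  expect_error(samplingPattern(9L, 12L, 3L), "nACS")
})

test_that("mask coverage holds for any pattern and acceleration is
           constant for R-aligned patterns", {
  ## union of R consecutive frames is always full
  for (R in c(2L, 3L, 4L, 7L)) {
    for (nACS in c(6L, 12L)) {
      p <- samplingPattern(48L, nACS, R)
      u <- rep(FALSE, 48L)
      for (f in seq_len(R)) u <- u | buildMask(p, f)
      expect_true(all(u))
    }
  }
  ## per-frame line counts are constant when R divides nPE and nACS
  ## (the protocol case: 84 lines, 12 ACS, R = 3)
  for (R in c(2L, 3L, 4L, 6L)) {
    p <- samplingPattern(48L, 12L, R)
    counts <- vapply(seq_len(R), function(f) sum(buildMask(p, f)),
                     integer(1))
    expect_length(unique(counts), 1L)
  }
  p84 <- samplingPattern(84L, 12L, 3L)
  expect_equal(unique(vapply(1:3, function(f) sum(buildMask(p84, f)),
                             integer(1))), 36L)
})

test_that("retrospective undersampling zeroes skipped lines and is
           idempotent", {
  k <- randomKspace(16, 84, 1, 6)
  p <- samplingPattern(84L, 12L, 3L)
  ku <- applyMask(k, p)
  ## 12 ACS + 24 matching peripheral lines retained per frame
  expect_equal(sum(samplingMask(ku)[, 1, 1]), 36L)
  m1 <- buildMask(p, 1L)
  expect_identical(kspaceData(ku)[, m1, , 1], kspaceData(k)[, m1, , 1])
  expect_true(all(kspaceData(ku)[, !m1, , 1] == 0))
  ku2 <- applyMask(ku, p)
  expect_identical(kspaceData(ku2), kspaceData(ku))
  ## R = 1 leaves everything untouched
  kid <- applyMask(k, samplingPattern(84L, 12L, 1L))
  expect_identical(kspaceData(kid), kspaceData(k))
  expect_true(all(samplingMask(kid)))
  expect_error(applyMask(k, samplingPattern(64L, 12L, 3L)), "nPE")
})

test_that("volume acquisition time is packets x lines x TR", {
  params <- acquisitionParams()   # 6 packets, 24 lines, TR 10.6 ms
  expect_equal(volumeAcquisitionTime(params), 1.5264)
  expect_equal(round(volumeAcquisitionTime(params), 1), 1.5)
  tiny <- acquisitionParams(tr = 10, nSlices = 1L, slicesPerPacket = 1L,
                            nPackets = 1L, linesPerSlicePerFrame = 1L)
  expect_equal(volumeAcquisitionTime(tiny), 0.01)
  dbl <- acquisitionParams(linesPerSlicePerFrame = 48L)
  expect_equal(volumeAcquisitionTime(dbl), 2 * volumeAcquisitionTime(params))
  expect_error(acquisitionParams(nSlices = 23L), "slicesPerPacket")
})

test_that("triggers sit at the burst falling edge, one per cycle", {
  tr <- simulateRespiration(60, 10, samplingRate = 100)
  trig <- detectTriggers(tr)
  expect_length(trig, 10L)
  expect_true(all(diff(trig) > 0))
  expect_equal(diff(trig), rep(1, 9), tolerance = 0.05)
  ## triggers fall after the burst peak (quiescent onset)
  expect_gt(trig[1], 0.1)
  flat <- new("RespirationTrace", times = seq(0, 1, 0.01),
              pressure = rep(2, 101), rateNominal = 60)
  expect_length(detectTriggers(flat), 0L)
  expect_length(detectTriggers(tr, threshold = 10), 0L)
})

test_that("volume scheduling matches the gating arithmetic", {
  trig <- seq(0, 20, by = 1)            # 1 s cycle
  sc <- scheduleVolumes(trig, 1.5)
  expect_equal(sc@effectiveResolution[1], 2)   # ceil(1.5 / 1) * 1
  sc2 <- scheduleVolumes(seq(0, 20, by = 1.5), 1.5)
  expect_equal(sc2@effectiveResolution[1], 1.5)
  ## worst case over physiologic cycles 1-2 s stays at or below 3 s
  worst <- vapply(seq(1, 2, by = 0.05), function(cyc) {
    s <- scheduleVolumes(seq(0, 30, by = cyc), 1.5)
    max(s@effectiveResolution, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(worst <= 3 + 1e-9))
  ## re-triggering is ignored while a volume is running
  sc3 <- scheduleVolumes(c(0, 0.5, 1, 1.6, 2.2), 1.5)
  expect_equal(sc3@volumeStart[1:2], c(0, 1.6))
  ## truncation warns
  expect_warning(scheduleVolumes(c(0, 2), 1.5, nVolumes = 5), "scheduled")
})
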