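## Shared fixtures: desk-scale phantom configs, exactly linear-predictive
## k-space builders, and an independent normal-equations calibration oracle.

## compact phantom on a 32 x 32 x 2 grid (16 x 16 x 3 mm)
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(grid = c(32L, 32L, 2L), voxelSize = c(0.5, 0.5, 1.5),
         antrumCenter = c(6, 8), antrumRadius = 2,
         corpusCenter = c(6, 8, 4.5), corpusSemiaxes = c(4, 3.5, 2.5),
         bodyCenter = c(8, 8), bodyRadius = 7),
    list(...))
  do.call(phantomConfig, args)
}

## k-space that exactly obeys a shift-invariant k-t linear model: a sum of
## DFT-periodic plane waves (integer spatial frequencies) with arbitrary
## temporal phases. Any single source predicts each mode exactly, so a
## zero-residual kernel fit exists for every stencil.
planeWaveKspace <- function(nx, ny, nt, nModes = 3L, seed = 3L,
                            voxelSize = c(1, 1, 1)) {
  set.seed(seed)
  k <- array(0+0i, c(nx, ny, 1L, nt))
  for (m in seq_len(nModes)) {
    al <- 2 * pi * sample(0:(nx - 1L), 1L) / nx
    be <- 2 * pi * sample(0:(ny - 1L), 1L) / ny
    om <- stats::runif(1L, -pi, pi)
    a <- complex(real = stats::rnorm(1L), imaginary = stats::rnorm(1L))
    for (t in seq_len(nt))
      k[, , 1L, t] <- k[, , 1L, t] +
        a * exp(1i * al * seq_len(nx)) %o% exp(1i * be * seq_len(ny)) *
        exp(1i * om * t)
  }
  new("KSpaceSeries", data = k, mask = array(TRUE, c(ny, 1L, nt)),
      voxelSize = voxelSize, frameTimes = seq_len(nt) - 1,
      acqParams = list())
}

## generic smooth random k-space (full rank calibration problems)
randomKspace <- function(nx, ny, ns, nt, seed = 11L) {
  set.seed(seed)
  img <- array(0, c(nx, ny, ns, nt))
  for (t in seq_len(nt))
    for (s in seq_len(ns)) {
      base <- matrix(stats::rnorm(nx * ny), nx, ny)
      ## smooth: damp high frequencies so k-space decays like an image
      sm <- base
      for (i in 1:2)
        sm <- (sm + sm[c(2:nx, 1), ] + sm[, c(2:ny, 1)] +
                 sm[c(nx, 1:(nx - 1)), ] + sm[, c(ny, 1:(ny - 1))]) / 5
      img[, , s, t] <- sm + 0.2 * t / nt
    }
  phantomToKspace(new("ImageSeries", values = img,
                      voxelSize = c(1, 1, 1),
                      frameTimes = seq_len(nt) - 1,
                      provenance = "random"))
}

## independent brute-force calibration oracle: assembles the fit equations
## with plain nested loops and solves the normal equations directly.
oracleKernelWeights <- function(kdata, sources, kxHalfWidth, acsRows,
                                frames) {
  nx <- dim(kdata)[1L]
  nS <- dim(kdata)[3L]
  lo <- min(acsRows); hi <- max(acsRows)
  kyT <- acsRows[acsRows + min(sources[, 1L]) >= lo &
                 acsRows + max(sources[, 1L]) <= hi]
  taps <- seq.int(-kxHalfWidth, kxHalfWidth)
  nCoef <- nrow(sources) * length(taps)
  A <- NULL; b <- complex()
  for (t in frames) for (s in seq_len(nS)) for (ky in kyT)
    for (kx in seq_len(nx)) {
      row <- complex(nCoef)
      j <- 0L
      for (i in seq_len(nrow(sources))) for (dkx in taps) {
        j <- j + 1L
        kxi <- ((kx + dkx - 1L) %% nx) + 1L
        row[j] <- kdata[kxi, ky + sources[i, 1L], s, t + sources[i, 2L]]
      }
      A <- rbind(A, row)
      b <- c(b, kdata[kx, ky, s, t])
    }
  drop(solve(Conj(t(A)) %*% A, Conj(t(A)) %*% b))
}

kspaceRE <- function(test, ref) {
  sqrt(sum(Mod(test - ref)^2) / sum(Mod(ref)^2))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
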