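## FFT helpers. Convention: the DC sample sits at the centred position
## floor(n/2) + 1 along each in-plane axis; the forward transform is the
## unnormalized DFT, the inverse carries the 1/(nx*ny) factor, so image
## energy equals k-space energy / (nx*ny).

.fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(d[1L] %/% 2L + 1L, d[1L]), seq_len(d[1L] %/% 2L))
  j <- c(seq.int(d[2L] %/% 2L + 1L, d[2L]), seq_len(d[2L] %/% 2L))
  m[i, j, drop = FALSE]
}

.ifftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(d[1L] - d[1L] %/% 2L + 1L, d[1L]),
         seq_len(d[1L] - d[1L] %/% 2L))
  j <- c(seq.int(d[2L] - d[2L] %/% 2L + 1L, d[2L]),
         seq_len(d[2L] - d[2L] %/% 2L))
  m[i, j, drop = FALSE]
}

## centred 2D DFT of one image plane
.fft2c <- function(img) .fftshift2(stats::fft(.ifftshift2(img)))

## centred inverse; returns complex plane
.ifft2c <- function(k) {
  d <- dim(k)
  .fftshift2(stats::fft(.ifftshift2(k), inverse = TRUE)) / prod(d)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)
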