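# Centred FFT helpers. All boxes are even, so fftshift and its inverse
# coincide (swap of half-blocks). Real-space and frequency origins both
# sit at 0-based index n/2, matching the C++ projector convention.

shift_half <- function(n) c((n / 2 + 1):n, 1:(n / 2))

fftshift2 <- function(m) {
  s <- shift_half(nrow(m))
  m[s, s, drop = FALSE]
}

fftshift3 <- function(a) {
  s <- shift_half(dim(a)[1])
  a[s, s, s, drop = FALSE]
}

# Centred 2D transform of one image (matrix in, complex matrix out).
fft2c <- function(x, inverse = FALSE) {
  out <- fftshift2(fft(fftshift2(x), inverse = inverse))
  if (inverse) out / length(x) else out
}

# Batched centred 2D transform over an n x n x K stack, built from two
# passes of mvfft (columns), which is much faster than K calls to fft().
batch_fft2 <- function(a, inverse = FALSE) {
  d <- dim(a)
  n <- d[1]
  k <- if (length(d) == 3) d[3] else 1L
  s <- shift_half(n)
  a <- array(a, c(n, n, k))[s, s, , drop = FALSE]
  dim(a) <- c(n, n * k)
  a <- mvfft(a, inverse = inverse)
  dim(a) <- c(n, n, k)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(n, n * k)
  a <- mvfft(a, inverse = inverse)
  dim(a) <- c(n, n, k)
  a <- aperm(a, c(2, 1, 3))
  a <- a[s, s, , drop = FALSE]
  if (inverse) a / (n * n) else a
}

# Centred 3D transform of a cubic volume via three mvfft passes.
fft3c <- function(a, inverse = FALSE) {
  n <- dim(a)[1]
  s <- shift_half(n)
  a <- a[s, s, s]
  for (pass in 1:3) {
    dim(a) <- c(n, n * n)
    a <- mvfft(a, inverse = inverse)
    dim(a) <- c(n, n, n)
    a <- aperm(a, c(2, 3, 1))
  }
  a <- a[s, s, s]
  if (inverse) a / n^3 else a
}

# Centred frequency index grids (kx, ky), each n x n, values in
# [-n/2, n/2).
freq_grid2 <- function(n) {
  k <- seq_len(n) - 1 - n / 2
  list(kx = matrix(k, n, n), ky = matrix(k, n, n, byrow = TRUE))
}

# Phase ramp that moves image content by +(dx, dy) pixels when
# multiplied onto the centred transform. The unpaired Nyquist row and
# column of the even-sized grid get the real (cosine) factor so that
# shifted real images stay real.
phase_ramp1 <- function(n, d) {
  k <- seq_len(n) - 1 - n / 2
  r <- exp(-2i * pi * k * d / n)
  r[1] <- cos(2 * pi * (n / 2) * d / n)  # k = -n/2 (Nyquist)
  r
}

phase_ramp2 <- function(n, dx, dy) {
  outer(phase_ramp1(n, dx), phase_ramp1(n, dy))
}

# Run code with a private RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
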