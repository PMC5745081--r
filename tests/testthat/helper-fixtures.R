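# Shared fixtures, all generated in code.

# Smooth Gaussian blob volume (closed-form projections make it the
# standard oracle for the projector).
gaussian_volume <- function(n = 48, sigma = 3, centre = c(0, 0, 0),
                            pixel_size = 1) {
  co <- seq_len(n) - 1 - n / 2
  g <- exp(-(outer(outer((co - centre[1])^2, (co - centre[2])^2, `+`),
                   (co - centre[3])^2, `+`)) / (2 * sigma^2))
  fx_volume(g, pixel_size)
}

# Analytic projection of the Gaussian blob along z (any orientation
# gives the same isotropic 2D Gaussian, scaled by sqrt(2 pi) sigma).
gaussian_projection <- function(n = 48, sigma = 3, pixel_size = 1) {
  co <- seq_len(n) - 1 - n / 2
  sqrt(2 * pi) * sigma * exp(-outer(co^2, co^2, `+`) / (2 * sigma^2))
}

# Two-sphere soft phantom for reconstruction tests.
two_sphere_volume <- function(n = 48, pixel_size = 1) {
  co <- seq_len(n) - 1 - n / 2
  sph <- function(c0, r) {
    d2 <- outer(outer((co - c0[1])^2, (co - c0[2])^2, `+`),
                (co - c0[3])^2, `+`)
    1 / (1 + exp((sqrt(d2) - r)))
  }
  fx_volume(sph(c(0, 0, 8), 6) + sph(c(5, -3, -8), 9), pixel_size)
}

# Ring of `order` Gaussian blobs: the canonical Cn test image.
ring_image <- function(n = 64, order = 13, radius = 18, sigma = 2,
                       noise = 0, seed = NULL) {
  co <- seq_len(n) - 1 - n / 2
  img <- matrix(0, n, n)
  for (b in seq_len(order)) {
    phi <- 2 * pi * (b - 1) / order
    img <- img + exp(-(outer((co - radius * cos(phi))^2,
                             (co - radius * sin(phi))^2, `+`)) /
                       (2 * sigma^2))
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + noise * max(img) * matrix(rnorm(n^2), n)
  }
  img
}

# Band-limited random image (exactly representable by the Fourier
# shift operator).
bandlimited_image <- function(n = 32, kmax = 10, seed = 1) {
  set.seed(seed)
  f <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  k <- seq_len(n) - 1 - n / 2
  km <- sqrt(outer(k^2, k^2, `+`))
  f[km > kmax] <- 0
  Re(flexalign:::fft2c(f, inverse = TRUE))
}

random_eulers <- function(n, seed = 1) {
  set.seed(seed)
  cbind(rot = runif(n, -180, 180),
        tilt = acos(runif(n, -1, 1)) * 180 / pi,
        psi = runif(n, -180, 180))
}

# A small flexible phantom (smaller box) for cheap pipeline-flavoured
# unit tests; the full-size standard phantom is reserved for the
# acceptance suite.
small_phantom_spec <- function(hinge_sigma = 8) {
  phantom_spec(box = 64, ring_z = c(-24, -20, -12, -8, -1, 7),
               ring_radii = c(10, 10, 11, 11, 10, 12),
               barrel_z = 15, barrel_radius = 13, barrel_half_len = 5,
               hinge_z = 4, hinge_sigma = hinge_sigma)
}
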