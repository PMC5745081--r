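test_that("FSC of a map with itself is 1 and symmetric in arguments", {
  v <- two_sphere_volume(48, pixel_size = 2)
  cv <- fsc(v, v)
  expect_true(all(abs(cv$fsc - 1) < 1e-9))
  expect_equal(resolution_at(cv), 2 * 2, tolerance = 1e-9)  # Nyquist
  set.seed(1)
  w <- fx_volume(v$grid + array(rnorm(48^3), c(48, 48, 48)), 2)
  expect_equal(fsc(v, w)$fsc, fsc(w, v)$fsc, tolerance = 1e-12)
  expect_error(fsc(v, fx_volume(array(0, c(32, 32, 32)), 2)),
               "grid mismatch")
})

test_that("independent noise maps decorrelate within the counting bound", {
  set.seed(2)
  n <- 48
  a <- fx_volume(array(rnorm(n^3), c(n, n, n)))
  b <- fx_volume(array(rnorm(n^3), c(n, n, n)))
  cv <- fsc(a, b)
  expect_true(all(abs(cv$fsc) < 3 / sqrt(cv$n_voxels)))
})

test_that("FSC of signal plus noise follows SNR/(1+SNR) per shell", {
  # white signal and white noise at a known variance ratio; several
  # replicate noise pairs average down the estimator variance
  set.seed(3)
  n <- 64
  snr <- 9
  sig <- array(rnorm(n^3), c(n, n, n))
  acc <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    m1 <- fx_volume(sig + array(rnorm(n^3, 0, 1 / sqrt(snr)),
                                c(n, n, n)))
    m2 <- fx_volume(sig + array(rnorm(n^3, 0, 1 / sqrt(snr)),
                                c(n, n, n)))
    acc <- acc + fsc(m1, m2)$fsc
  }
  fbar <- acc / reps
  expect_true(all(abs(fbar - snr / (1 + snr)) < 0.05))
})

test_that("resolution_at interpolates the threshold crossing", {
  curve <- data.frame(shell = 1:10, freq = (1:10) / 100,
                      fsc = c(1, 1, 0.9, 0.8, 0.6, 0.4, 0.2, 0.1,
                              0.05, 0))
  # crossing of 0.143 between shells 7 (0.2) and 8 (0.1)
  frac <- (0.2 - 0.143) / (0.2 - 0.1)
  expect_equal(resolution_at(curve, 0.143),
               1 / (0.07 + frac * 0.01), tolerance = 1e-12)
  expect_equal(resolution_at(curve, 0.5), 1 / (0.05 + 0.5 * 0.01),
               tolerance = 1e-12)
})

test_that("global_cc matches the direct covariance formula", {
  v1 <- two_sphere_volume(32)
  expect_equal(global_cc(v1, v1), 1)
  neg <- fx_volume(-v1$grid)
  expect_equal(global_cc(v1, neg), -1)
  set.seed(4)
  a <- array(rnorm(32^3), c(32, 32, 32))
  b <- array(rnorm(32^3), c(32, 32, 32))
  direct <- mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) *
    length(a) / (length(a) - 1)
  expect_equal(global_cc(fx_volume(a), fx_volume(b)), direct,
               tolerance = 1e-10)
  const <- fx_volume(array(1, c(32, 32, 32)))
  expect_error(global_cc(const, fx_volume(a)), "zero variance")
})

test_that("local_cc equals the windowed-Pearson oracle at sampled voxels", {
  set.seed(5)
  n <- 24
  a <- fx_volume(array(rnorm(n^3), c(n, n, n)))
  b <- fx_volume(array(rnorm(n^3), c(n, n, n)) + 0.5 * a$grid)
  lc <- local_cc(a, b, 5)
  idx <- cbind(sample(3:(n - 2), 20, TRUE), sample(3:(n - 2), 20, TRUE),
               sample(3:(n - 2), 20, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    wa <- a$grid[(i[1] - 2):(i[1] + 2), (i[2] - 2):(i[2] + 2),
                 (i[3] - 2):(i[3] + 2)]
    wb <- b$grid[(i[1] - 2):(i[1] + 2), (i[2] - 2):(i[2] + 2),
                 (i[3] - 2):(i[3] + 2)]
    expect_equal(lc$cc$grid[i[1], i[2], i[3]],
                 cor(as.numeric(wa), as.numeric(wb)),
                 tolerance = 1e-8)
  }
})

test_that("local_cc is scale/offset invariant and flags flat windows", {
  v <- two_sphere_volume(24)
  lc <- local_cc(v, fx_volume(2 * v$grid + 5), 5)
  inform <- lc$flag == 1
  expect_true(all(abs(lc$cc$grid[inform] - 1) < 1e-6))
  flat <- fx_volume(array(0, c(24, 24, 24)))
  lc0 <- local_cc(flat, v, 5)
  expect_true(all(lc0$flag == 0))
  expect_true(all(lc0$cc$grid == 0))
  expect_error(local_cc(v, v, 4), "odd")
  expect_error(local_cc(v, v, 25), "window")
})

test_that("local_cc mean tracks global_cc on smooth phantoms", {
  v <- two_sphere_volume(32)
  set.seed(6)
  w <- fx_volume(v$grid + 0.1 * array(rnorm(32^3), c(32, 32, 32)))
  mask <- v$grid > 0.2
  lc <- local_cc(v, w, 7)
  expect_lt(abs(mean(lc$cc$grid[mask & lc$flag == 1]) -
                  global_cc(v, w, mask)), 0.1)
})

test_that("B-factor sharpening applies the expected gain and inverts", {
  n <- 48
  px <- 1.0
  # single-frequency test volume: cosine along x at s ~ 0.1/A
  kx <- round(0.1 * n * px)
  vv <- array(rep(cos(2 * pi * kx * (0:(n - 1)) / n), times = n * n),
              c(n, n, n))
  v <- fx_volume(vv, px)
  sh <- sharpen_bfactor(v, -250)
  gain <- exp(-(-250) * (kx / (n * px))^2 / 4)
  expect_equal(max(abs(sh$grid)) / max(abs(v$grid)), gain,
               tolerance = 1e-3)
  # invertibility (at the acquisition pixel size, 3.26 A)
  w <- two_sphere_volume(32, pixel_size = 3.26)
  back <- sharpen_bfactor(sharpen_bfactor(w, -250), 250)
  expect_lt(max(abs(back$grid - w$grid)), 1e-6)
  expect_identical(sharpen_bfactor(w, 0), w)
})

test_that("lowpass removes structure beyond the cutoff", {
  set.seed(7)
  n <- 32
  v <- fx_volume(array(rnorm(n^3), c(n, n, n)), 1)
  lp <- lowpass(v, cutoff_A = 4)     # keep s <= 0.25
  f <- flexalign:::fft3c(lp$grid)
  sh <- flexalign:::shell_index(n)
  cut_shell <- 0.25 * n * 1
  expect_lt(max(abs(f[sh > cut_shell + 2.5])) / max(abs(f)), 1e-10)
  keep <- abs(f[sh <= cut_shell - 1])
  f0 <- flexalign:::fft3c(v$grid)
  expect_equal(f[sh <= cut_shell - 1], f0[sh <= cut_shell - 1],
               tolerance = 1e-9)
})

test_that("MTF curves are read and divided out with a floor", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("0.0 1.0", "0.25 0.8", "0.5 0.6", "0.75 0.4",
               "1.0 0.2"), path)
  mtf <- read_mtf(path)
  expect_equal(mtf$mtf, c(1, 0.8, 0.6, 0.4, 0.2))
  v <- two_sphere_volume(32)
  corr <- apply_mtf_correction(v, mtf)
  f0 <- flexalign:::fft3c(v$grid)
  f1 <- flexalign:::fft3c(corr$grid)
  sh <- flexalign:::shell_index(32)
  # at half-Nyquist (shell 8 of 16) the gain is 1/0.6
  sel <- sh == 8
  expect_equal(median(Mod(f1[sel]) / Mod(f0[sel])), 1 / 0.6,
               tolerance = 1e-6)
})
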