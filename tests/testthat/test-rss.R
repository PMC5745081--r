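test_that("make_soft_mask binarises, dilates and soft-edges", {
  v <- make_initial_reference("sphere", 48, 10, edge_px = 0)
  m0 <- make_soft_mask(v, 0.5, extend_px = 0, soft_edge_px = 0)
  expect_true(all(m0$grid %in% c(0, 1)))        # binary when edge 0
  # dilation by 3 grows the 0.5-level radius by 3
  m3 <- make_soft_mask(v, 0.5, extend_px = 3, soft_edge_px = 2)
  co <- seq_len(48) - 1 - 24
  prof0 <- m0$grid[25:48, 25, 25]
  prof3 <- m3$grid[25:48, 25, 25]
  r0 <- which(prof0 < 0.5)[1]
  r3 <- which(prof3 < 0.5)[1]
  expect_equal(r3 - r0, 3, tolerance = 1)
  expect_true(all(m3$grid >= 0 & m3$grid <= 1))
  # threshold below the minimum makes everything interior
  mall <- make_soft_mask(fx_volume(v$grid + 1), 0.5, 0, 0)
  expect_true(all(mall$grid == 1))
  expect_error(make_soft_mask(v, 2), "empty mask")
})

make_rss_case <- function(n_particles = 6, snr = Inf, seed = 21) {
  a <- gaussian_volume(48, sigma = 3, centre = c(0, 0, 9))
  b <- gaussian_volume(48, sigma = 4, centre = c(0, 0, -9))
  ref <- fx_volume(a$grid + b$grid)
  keep <- make_soft_mask(a, 0.05, extend_px = 2, soft_edge_px = 0)
  keep$grid[, , 1:24] <- 0              # confine keep strictly to A side
  es <- random_eulers(n_particles, seed = seed)
  set.seed(seed)
  tab <- particle_table(n_particles, rot = es[, 1], tilt = es[, 2],
                        psi = es[, 3],
                        origin_x = runif(n_particles, -3, 3),
                        origin_y = runif(n_particles, -3, 3),
                        defocus_u = runif(n_particles, 12000, 30000))
  rmax <- flexalign:::support_radius(ref$grid)
  st <- array(0, c(48, 48, n_particles))
  for (i in seq_len(n_particles)) {
    img <- project_volume(ref, es[i, ],
                          c(tab$origin_x[i], tab$origin_y[i]),
                          rmax = rmax)
    img <- apply_ctf(img, flexalign:::ctf_from_record(tab, i), 1)
    if (is.finite(snr))
      img <- img + matrix(rnorm(48^2, 0, sd(img) / sqrt(snr)), 48)
    st[, , i] <- img
  }
  list(stack = fx_stack(st), table = tab, ref = ref, keep = keep,
       a = a, b = b)
}

test_that("noise-free subtraction leaves exactly the kept module", {
  cs <- make_rss_case()
  out <- subtract_signal(cs$stack, cs$table, cs$ref, cs$keep)
  rmax <- flexalign:::support_radius(cs$ref$grid)
  for (i in seq_len(n <- dim(out$stack$data)[3])) {
    keep_only <- project_volume(
      fx_volume(cs$keep$grid * cs$ref$grid),
      c(cs$table$rot[i], cs$table$tilt[i], cs$table$psi[i]),
      c(cs$table$origin_x[i], cs$table$origin_y[i]), rmax = rmax)
    keep_only <- apply_ctf(keep_only,
                           flexalign:::ctf_from_record(cs$table, i), 1)
    resid <- out$stack$data[, , i] - keep_only
    expect_lt(sqrt(mean(resid^2)) / sqrt(mean(keep_only^2)), 1e-3)
  }
})

test_that("all-ones keep mask is the identity", {
  cs <- make_rss_case(3)
  ones <- fx_volume(array(1, dim(cs$ref$grid)))
  out <- subtract_signal(cs$stack, cs$table, cs$ref, ones)
  expect_equal(out$stack$data, cs$stack$data, tolerance = 1e-12)
})

test_that("subtraction is linear in the mask decomposition", {
  cs <- make_rss_case(3)
  # complementary split of the subtracted region into two halves
  half1 <- cs$keep; half2 <- cs$keep
  n <- dim(cs$keep$grid)[1]
  sub_region <- 1 - cs$keep$grid
  half1$grid <- 1 - sub_region * rep(c(1, 0), each = n * n * n / 2)
  half2$grid <- 1 - sub_region * rep(c(0, 1), each = n * n * n / 2)
  out_union <- subtract_signal(cs$stack, cs$table, cs$ref, cs$keep)
  step1 <- subtract_signal(cs$stack, cs$table, cs$ref, half1)
  step2 <- subtract_signal(step1$stack, cs$table, cs$ref, half2)
  # subtracting the two halves in sequence equals subtracting the union
  expect_equal(step2$stack$data, out_union$stack$data,
               tolerance = 1e-6)
})

test_that("noisy subtraction brings the removed region to the noise floor", {
  cs <- make_rss_case(8, snr = 0.1, seed = 31)
  out <- subtract_signal(cs$stack, cs$table, cs$ref, cs$keep)
  rmax <- flexalign:::support_radius(cs$ref$grid)
  ratio <- numeric(8)
  for (i in 1:8) {
    # footprint of the subtracted (B) projection
    pb <- project_volume(fx_volume((1 - cs$keep$grid) * cs$ref$grid),
                         c(cs$table$rot[i], cs$table$tilt[i],
                           cs$table$psi[i]),
                         c(cs$table$origin_x[i], cs$table$origin_y[i]),
                         rmax = rmax)
    fp <- abs(pb) > 0.1 * max(abs(pb))
    # compare residual power in the footprint against the noise power
    # estimated far outside the particle
    noise_var <- var(out$stack$data[, , i][
      abs(pb) == 0 & gaussian_projection(48, 3) < 1e-6])
    ratio[i] <- var(out$stack$data[, , i][fp]) / noise_var
  }
  expect_equal(median(ratio), 1, tolerance = 0.35)
})

test_that("lsq scale mode recovers a global amplitude factor", {
  cs <- make_rss_case(3)
  scaled <- cs$stack
  scaled$data <- scaled$data * 1.7
  none <- fx_volume(array(0, dim(cs$ref$grid)))   # subtract everything
  out <- subtract_signal(scaled, cs$table, cs$ref, none,
                         scale_mode = "lsq")
  for (i in 1:3)
    expect_lt(sqrt(mean(out$stack$data[, , i]^2)) /
                sqrt(mean(scaled$data[, , i]^2)), 0.02)
  # fixed scale leaves the amplitude mismatch behind
  fixed <- subtract_signal(scaled, cs$table, cs$ref, none,
                           scale_mode = "fixed")
  expect_gt(sqrt(mean(fixed$stack$data[, , 1]^2)),
            5 * sqrt(mean(out$stack$data[, , 1]^2)))
  # a flat (zero-variance) footprint falls back to s = 1
  blank <- fx_stack(array(0, c(48, 48, 1)))
  tab1 <- cs$table[1, ]
  zero_ref <- fx_volume(array(0, dim(cs$ref$grid)))
  expect_warning(subtract_signal(blank, tab1, zero_ref, none,
                                 scale_mode = "lsq"),
                 "zero-variance")
})
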