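test_that("project_point maps reference points into the image frame", {
  pp <- project_point(c(0, 0, 0), c(33, 77, 12), origin = c(2, -3))
  expect_equal(c(pp$px, pp$py, pp$z_offset), c(2, -3, 0))
  # Ry(90) maps z onto x
  pp <- project_point(c(0, 0, 10), c(0, 90, 0))
  expect_equal(c(pp$px, pp$py, pp$z_offset), c(10, 0, 0),
               tolerance = 1e-12)
})

test_that("project_point agrees with the delta-projection oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    pt <- runif(3, -10, 10)
    e <- c(runif(1, -180, 180), acos(runif(1, -1, 1)) * 180 / pi,
           runif(1, -180, 180))
    o <- runif(2, -4, 4)
    v <- gaussian_volume(64, sigma = 1.5, centre = pt)
    img <- project_volume(v, e, o)
    pk <- which(img == max(img), arr.ind = TRUE)[1, ]
    # parabolic sub-pixel peak
    sub <- c(0, 0)
    for (ax in 1:2) {
      idx <- pk; idx[ax] <- pk[ax] - 1; sm <- img[idx[1], idx[2]]
      idx[ax] <- pk[ax] + 1; sp <- img[idx[1], idx[2]]
      sub[ax] <- flexalign:::parabolic_offset(sm, img[pk[1], pk[2]], sp)
    }
    pp <- project_point(pt, e, o)
    err <- max(abs(pk - 1 - 32 + sub - c(pp$px, pp$py)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.5)
})

test_that("module_centers_from_mask is the voxel-weighted centroid", {
  v <- make_initial_reference("sphere", 48, 8)
  expect_equal(module_centers_from_mask(v), c(0, 0, 0),
               tolerance = 1e-9)
  vz <- gaussian_volume(48, sigma = 3, centre = c(0, 0, 10))
  expect_equal(module_centers_from_mask(vz), c(0, 0, 10),
               tolerance = 1e-4)
  two <- fx_volume(gaussian_volume(48, 2, c(0, 0, 8))$grid +
                     gaussian_volume(48, 2, c(0, 0, -4))$grid)
  # voxel-sum oracle
  g <- two$grid
  co <- seq_len(48) - 1 - 24
  oracle <- c(sum(apply(g, 1, sum) * co),
              sum(apply(g, 2, sum) * co),
              sum(apply(g, 3, sum) * co)) / sum(g)
  expect_equal(module_centers_from_mask(two), oracle,
               tolerance = 1e-12)
  expect_error(module_centers_from_mask(fx_volume(array(0, c(8, 8, 8)))),
               "empty mask")
})

test_that("marker re-extraction centres the peak in >=99% of 1000 particles", {
  set.seed(7)
  n_par <- 1000
  pt <- c(4, -6, 11)
  v <- gaussian_volume(64, sigma = 1.8, centre = pt)
  es <- random_eulers(n_par, seed = 8)
  ox <- runif(n_par, -10, 10)
  oy <- runif(n_par, -10, 10)
  st <- array(0, c(64, 64, n_par))
  for (i in seq_len(n_par))
    st[, , i] <- project_volume(v, es[i, ], c(ox[i], oy[i]))
  tab <- particle_table(n_par, rot = es[, 1], tilt = es[, 2],
                        psi = es[, 3], origin_x = ox, origin_y = oy)
  rec <- recenter_stack(fx_stack(st), tab, recenter_spec(pt, 32))
  err <- numeric(n_par)
  for (i in seq_len(n_par)) {
    img <- rec$stack$data[, , i]
    pk <- which(img == max(img), arr.ind = TRUE)[1, ]
    sub <- c(0, 0)
    if (all(pk > 1 & pk < 32)) {
      sub[1] <- flexalign:::parabolic_offset(img[pk[1] - 1, pk[2]],
                                             img[pk[1], pk[2]],
                                             img[pk[1] + 1, pk[2]])
      sub[2] <- flexalign:::parabolic_offset(img[pk[1], pk[2] - 1],
                                             img[pk[1], pk[2]],
                                             img[pk[1], pk[2] + 1])
    }
    pos <- pk - 1 - 16 + sub
    err[i] <- max(abs(pos - c(rec$table$origin_x[i],
                              rec$table$origin_y[i])))
  }
  expect_gte(mean(err < 0.5), 0.99)
  # sub-pixel residual carried in metadata stays within half a pixel
  expect_lte(max(abs(rec$table$origin_x)), 0.5 + 1e-9)
})

test_that("identity recentering spec is a no-op", {
  set.seed(3)
  st <- fx_stack(array(rnorm(48 * 48 * 4), c(48, 48, 4)))
  tab <- particle_table(4, rot = c(0, 45, 90, 120), tilt = 30)
  out <- recenter_stack(st, tab, recenter_spec(c(0, 0, 0), 48))
  expect_equal(out$stack$data, st$data)
  expect_equal(out$table$origin_x, tab$origin_x)
  # recentering twice with the origin spec keeps coordinates unchanged
  out2 <- recenter_stack(out$stack, out$table,
                         recenter_spec(c(0, 0, 0), 48))
  expect_equal(out2$table$origin_x, out$table$origin_x)
  expect_equal(out2$table$defocus_u, out$table$defocus_u)
})

test_that("recentering updates defocus by the depth offset", {
  v <- gaussian_volume(64, 2, c(0, 0, 12))
  tab <- particle_table(1, rot = 0, tilt = 0, psi = 0,
                        defocus_u = 20000, pixel_size = 3.26)
  st <- fx_stack(array(project_volume(v, c(0, 0, 0)), c(64, 64, 1)),
                 3.26)
  out <- recenter_stack(st, tab, recenter_spec(c(0, 0, 12), 32))
  # tilt 0: the point sits 12 px above the centre along the beam
  expect_equal(out$table$defocus_u, 20000 + 12 * 3.26,
               tolerance = 1e-9)
  out2 <- recenter_stack(st, tab, recenter_spec(c(0, 0, 12), 32),
                         z_sign = -1)
  expect_equal(out2$table$defocus_u, 20000 - 12 * 3.26,
               tolerance = 1e-9)
})

test_that("window sizes follow the spec and bounds are enforced", {
  st <- fx_stack(array(0, c(64, 64, 2)))
  tab <- particle_table(2)
  for (nb in c(40, 32, 16)) {
    out <- recenter_stack(st, tab, recenter_spec(c(2, 1, 0), nb))
    expect_equal(dim(out$stack$data)[1:2], c(nb, nb))
  }
  expect_error(recenter_stack(st, tab, recenter_spec(c(0, 0, 0), 128)),
               "exceeds")
  expect_error(recenter_spec(c(0, 0, 0), 17), "even")
})

test_that("out-of-bounds windows are edge-padded and flagged", {
  set.seed(5)
  st <- fx_stack(array(rnorm(64 * 64 * 1, mean = 7), c(64, 64, 1)))
  tab <- particle_table(1, rot = 0, tilt = 90, psi = 0)
  # point near the box edge: window extends outside
  out <- recenter_stack(st, tab, recenter_spec(c(0, 0, 28), 32),
                        edge = "mean")
  expect_equal(out$table$fa_edge_padded, 1)
  # padded values equal the edge-annulus mean of the source image
  n <- 64
  xy <- seq_len(n) - 1 - 32
  rr <- sqrt(outer(xy^2, xy^2, `+`))
  fill <- mean(st$data[, , 1][rr >= 0.45 * n & rr <= 0.5 * n])
  expect_equal(out$stack$data[32, 16, 1], fill, tolerance = 1e-9)
})
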