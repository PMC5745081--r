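test_that("featureless references have the right geometry", {
  sph <- make_initial_reference("sphere", 48, 12, edge_px = 6)
  # rotational invariance of sphere projections
  p1 <- project_volume(sph, c(12, 34, 56))
  p2 <- project_volume(sph, c(301, 121, 17))
  expect_lt(max(abs(p1 - p2)) / max(p1), 1e-3)
  # voxel count close to the analytic volume (edge counted at half)
  vol <- sum(sph$grid)
  expect_equal(vol, 4 / 3 * pi * 15^3, tolerance = 0.05)

  cyl <- make_initial_reference("cylinder", 48, 10, length = 24)
  top <- project_volume(cyl, c(0, 0, 0))     # disc silhouette
  side <- project_volume(cyl, c(0, 90, 0))   # rectangle silhouette
  co <- seq_len(48) - 1 - 24
  disc <- sqrt(outer(co^2, co^2, `+`)) <= 10
  expect_gt(min(top[disc]), 0.5 * max(top))
  rectr <- abs(matrix(co, 48, 48)) <= 11 &
    abs(matrix(co, 48, 48, byrow = TRUE)) <= 9
  expect_gt(min(side[rectr]), 0.5 * max(side))
  expect_error(make_initial_reference("sphere", 48, 30), "radius")
})

test_that("library size follows the angular step and symmetry", {
  ref <- make_initial_reference("sphere", 32, 8)
  lib <- build_library(ref, 30, symmetry = 1)
  n30 <- dim(lib$images)[3]
  expect_equal(n30, 41253 / 30^2 * (360 / 30), tolerance = 0.2)
  # C13 restriction: rot spans one asymmetric unit
  lib13 <- build_library(ref, 10, symmetry = 13)
  expect_lt(max(lib13$eulers[, "rot"]), 360 / 13)
  # halving the step multiplies entries by ~8
  lib15 <- build_library(ref, 15, symmetry = 1)
  expect_equal(dim(lib15$images)[3] / n30, 8, tolerance = 0.25)
})

test_that("on-grid projections are recovered exactly", {
  spec <- small_phantom_spec(hinge_sigma = 0)
  ph <- build_phantom(spec)
  lib <- build_library(ph$full, 12, symmetry = 13)
  k <- dim(lib$images)[3]
  idx <- round(seq(3, k - 2, length.out = 15))
  rmax <- flexalign:::support_radius(ph$full$grid)
  st <- array(0, c(64, 64, length(idx)))
  for (j in seq_along(idx))
    st[, , j] <- project_volume(ph$full, lib$eulers[idx[j], ],
                                rmax = rmax)
  est <- assign_orientations(fx_stack(st), lib, shift_max = 0)
  d <- vapply(seq_along(idx), function(j)
    angular_distance(lib$eulers[idx[j], ],
                     c(est$rot[j], est$tilt[j], est$psi[j]), 13), 0)
  expect_lt(max(d), 1e-4)
})

test_that("off-grid projections land within the grid resolution", {
  spec <- small_phantom_spec(hinge_sigma = 0)
  ph <- build_phantom(spec)
  lib <- build_library(ph$full, 8, symmetry = 13)
  es <- random_eulers(12, seed = 14)
  rmax <- flexalign:::support_radius(ph$full$grid)
  st <- array(0, c(64, 64, 12))
  for (j in 1:12) st[, , j] <- project_volume(ph$full, es[j, ],
                                              rmax = rmax)
  est <- assign_orientations(fx_stack(st), lib, shift_max = 0)
  d <- vapply(1:12, function(j)
    angular_distance(es[j, ], c(est$rot[j], est$tilt[j], est$psi[j]),
                     13), 0)
  expect_lte(median(d), 8)
})

test_that("scores are invariant to image offset and scale", {
  spec <- small_phantom_spec(hinge_sigma = 0)
  ph <- build_phantom(spec)
  lib <- build_library(ph$full, 15, symmetry = 13)
  img <- project_volume(ph$full, lib$eulers[5, ])
  est1 <- assign_orientations(fx_stack(img), lib, shift_max = 0)
  est2 <- assign_orientations(fx_stack(3.7 * img + 11), lib,
                              shift_max = 0)
  expect_equal(est1$rot, est2$rot)
  expect_equal(est1$fa_cc, est2$fa_cc, tolerance = 1e-9)
})

test_that("pure-noise images are assigned without spurious confidence", {
  spec <- small_phantom_spec(hinge_sigma = 0)
  ph <- build_phantom(spec)
  lib <- build_library(ph$full, 15, symmetry = 13)
  set.seed(15)
  st <- array(rnorm(64 * 64 * 40), c(64, 64, 40))
  est <- assign_orientations(fx_stack(st), lib, shift_max = 0)
  # scores stay at the noise scale ~ 1/sqrt(npix) (max over K entries)
  expect_lt(max(est$fa_cc), 0.25)
  # assigned tilts cover the sphere rather than collapsing on one view
  expect_gt(length(unique(round(est$tilt / 10))), 5)
})

test_that("local search refines a perturbed prior and never worsens it", {
  spec <- small_phantom_spec(hinge_sigma = 0)
  ph <- build_phantom(spec)
  es <- random_eulers(8, seed = 16)
  rmax <- flexalign:::support_radius(ph$full$grid)
  st <- array(0, c(64, 64, 8))
  for (j in 1:8) st[, , j] <- project_volume(ph$full, es[j, ],
                                             rmax = rmax)
  set.seed(17)
  prior <- particle_table(8, rot = es[, 1] + runif(8, -3, 3),
                          tilt = pmin(179, pmax(1, es[, 2] +
                                                  runif(8, -3, 3))),
                          psi = es[, 3] + runif(8, -3, 3))
  prior0 <- prior
  sc0 <- flexalign:::score_against_reference(fx_stack(st), ph$full,
                                             prior0)
  est <- assign_orientations(fx_stack(st), ph$full,
                             local = list(prior_table = prior,
                                          delta = 4, fine_step = 1,
                                          shift_max = 1,
                                          shift_step = 1))
  d <- vapply(1:8, function(j)
    angular_distance(es[j, ], c(est$rot[j], est$tilt[j], est$psi[j]),
                     13), 0)
  expect_lt(median(d), 1)
  expect_true(all(est$fa_cc >= sc0 - 1e-9))
})

test_that("angular_distance matches brute force over symmetry copies", {
  set.seed(18)
  for (i in 1:50) {
    e1 <- random_eulers(1, seed = i)[1, ]
    e2 <- random_eulers(1, seed = i + 100)[1, ]
    sym <- sample(c(1, 2, 7, 13), 1)
    brute <- min(vapply(0:(sym - 1), function(k) {
      M1 <- euler_to_matrix(e1)
      M2 <- euler_to_matrix(e2) %*% flexalign:::rot_z(k * 360 / sym)
      acos(min(1, max(-1, (sum(diag(crossprod(M1, M2))) - 1) / 2))) *
        180 / pi
    }, 0))
    expect_equal(angular_distance(e1, e2, sym), brute,
                 tolerance = 1e-8)
  }
  expect_equal(angular_distance(c(10, 20, 30), c(10, 20, 30), 13), 0)
  expect_equal(angular_distance(c(10, 20, 30),
                                c(10 + 360 / 13, 20, 30), 13), 0,
               tolerance = 1e-8)
})
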