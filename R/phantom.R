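# Synthetic flexible-particle generator: an elongated secretin-like
# phantom made of stacked Cn rings (the periplasmic tail) and a
# membrane barrel with an azimuthally modulated shell (the cap), with
# a rocking hinge between the two modules. The simulator projects the
# bent phantom at random orientations, applies a per-particle CTF and
# white Gaussian noise, and keeps the ground truth for scoring.

#' Flexible-phantom geometry specification
#'
#' Defaults describe the standard acceptance phantom: a 96 px box at
#' 3.26 A/px (a 2x-binned acquisition at 1.63 A/px), six stacked
#' 13-fold rings, a barrel on top, and a hinge between the two topmost
#' ring levels so that the cap (top ring + barrel) rocks against the
#' tail with an 8 degree amplitude.
#'
#' @param box box side in pixels (even).
#' @param pixel_size voxel size in Angstrom.
#' @param symmetry_order cyclic order n: blobs per ring.
#' @param ring_radii ring radius in pixels (recycled over rings).
#' @param ring_z ring centre heights in pixels relative to the box
#'   centre.
#' @param barrel_z,barrel_radius,barrel_half_len membrane barrel centre
#'   height, radius and half-length in pixels.
#' @param hinge_z hinge height: everything above belongs to the cap.
#' @param hinge_sigma rocking amplitude (degrees, s.d. of the hinge
#'   angle).
#' @param twist_per_ring azimuthal phase advance between successive
#'   rings in degrees (helical protomer arrangement; breaks the
#'   top/bottom chirality degeneracy of side views).
#' @param blob_sigma Gaussian width of the ring protomer blobs.
#' @return An object of class `fx_phantom_spec`.
#' @export
phantom_spec <- function(box = 96, pixel_size = 3.26,
                         symmetry_order = 13,
                         ring_radii = c(13, 13, 15, 15, 13, 16),
                         ring_z = c(-36, -30, -18, -12, -2, 11),
                         barrel_z = 22, barrel_radius = 18,
                         barrel_half_len = 8, hinge_z = 6,
                         hinge_sigma = 8, twist_per_ring = 5,
                         blob_sigma = 1.6) {
  if (box %% 2 != 0) stop("box must be even")
  if (hinge_sigma < 0) stop("hinge_sigma must be >= 0")
  ring_radii <- rep_len(ring_radii, length(ring_z))
  zmax <- max(abs(c(ring_z, barrel_z + barrel_half_len))) +
    3 * blob_sigma
  rmax <- max(ring_radii, barrel_radius) + 3 * blob_sigma
  if (zmax >= box / 2 || rmax >= box / 2)
    stop("phantom features extend outside the box")
  structure(list(box = as.integer(box), pixel_size = pixel_size,
                 symmetry_order = as.integer(symmetry_order),
                 ring_radii = ring_radii, ring_z = ring_z,
                 barrel_z = barrel_z, barrel_radius = barrel_radius,
                 barrel_half_len = barrel_half_len, hinge_z = hinge_z,
                 hinge_sigma = hinge_sigma,
                 twist_per_ring = twist_per_ring,
                 blob_sigma = blob_sigma),
            class = "fx_phantom_spec")
}

# Add one Gaussian blob, evaluated only inside its 4-sigma sub-cube.
add_blob <- function(grid, centre, sigma, amp = 1) {
  n <- dim(grid)[1]
  c0 <- n / 2                               # 0-based box centre
  lo <- pmax(1, floor(centre + c0 - 4 * sigma) + 1)
  hi <- pmin(n, ceiling(centre + c0 + 4 * sigma) + 1)
  if (any(lo > hi)) return(grid)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (ix - 1 - c0 - centre[1])^2
  dy2 <- (iy - 1 - c0 - centre[2])^2
  dz2 <- (iz - 1 - c0 - centre[3])^2
  blob <- exp(-(outer(outer(dx2, dy2, `+`), dz2, `+`) / (2 * sigma^2)))
  grid[ix, iy, iz] <- grid[ix, iy, iz] + amp * blob
  grid
}

#' Build the flexible phantom and its two rigid modules
#'
#' Deterministic given the spec. Each ring is n Gaussian blobs at
#' equal azimuths; the barrel is a smooth cylindrical shell with a
#' `cos(n phi)` azimuthal modulation so that the cap carries the same
#' Cn signature as the rings. Features strictly above `hinge_z` form
#' the cap, the rest the tail; `full = cap + tail` voxel for voxel.
#'
#' @param spec an [phantom_spec()].
#' @return `list(full, cap, tail)` of [fx_volume()] objects.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "fx_phantom_spec"))
  n <- spec$box
  cap <- array(0, c(n, n, n))
  tail <- array(0, c(n, n, n))
  nsym <- spec$symmetry_order

  for (r in seq_along(spec$ring_z)) {
    z0 <- spec$ring_z[r]
    target_is_cap <- z0 > spec$hinge_z
    phase <- (r - 1) * spec$twist_per_ring * pi / 180
    for (b in seq_len(nsym)) {
      phi <- 2 * pi * (b - 1) / nsym + phase
      centre <- c(spec$ring_radii[r] * cos(phi),
                  spec$ring_radii[r] * sin(phi), z0)
      if (target_is_cap) {
        cap <- add_blob(cap, centre, spec$blob_sigma)
      } else {
        tail <- add_blob(tail, centre, spec$blob_sigma)
      }
    }
  }
  # membrane barrel: radial Gaussian shell * axial plateau * azimuthal
  # Cn modulation; always part of the cap
  coord <- seq_len(n) - 1 - n / 2
  rho <- sqrt(outer(coord^2, coord^2, `+`))
  phi <- atan2(matrix(coord, n, n, byrow = TRUE), matrix(coord, n, n))
  bphase <- (length(spec$ring_z) - 1) * spec$twist_per_ring * pi / 180
  radial <- exp(-(rho - spec$barrel_radius)^2 / (2 * 1.6^2)) *
    (1 + 0.55 * cos(nsym * (phi - bphase)))
  zprof <- exp(-pmax(0, abs(coord - spec$barrel_z) -
                       spec$barrel_half_len)^2 / (2 * 1.5^2))
  barrel <- outer(as.numeric(radial), zprof)
  dim(barrel) <- c(n, n, n)
  cap <- cap + 0.8 * barrel

  list(full = fx_volume(cap + tail, spec$pixel_size),
       cap = fx_volume(cap, spec$pixel_size),
       tail = fx_volume(tail, spec$pixel_size))
}

# Rotation by angle_deg about a unit axis (Rodrigues).
axis_angle_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Simulate a dataset of flexible particles with ground truth
#'
#' Per particle: a uniform orientation over the sphere, a hinge angle
#' drawn from `Normal(0, hinge_sigma)` applied as a rigid rotation of
#' the cap about a random in-plane axis through `(0, 0, hinge_z)`, an
#' origin shift uniform in +/- `shift_max` px, and a defocus uniform in
#' `defocus_range`. The image is `CTF{proj(bent phantom)}` plus white
#' Gaussian noise scaled so that the variance ratio between the signal
#' (within the particle support) and the noise equals `snr`. The
#' returned table is blind — it carries no orientations — unless
#' `with_truth_priors`.
#'
#' @param spec an [phantom_spec()].
#' @param n number of particles.
#' @param snr target signal-to-noise variance ratio (`Inf` for
#'   noise-free).
#' @param defocus_range `c(min, max)` defocus in Angstrom.
#' @param seed integer seed; fixed seed gives identical output.
#' @param shift_max largest origin shift in pixels.
#' @param with_truth_priors copy true orientations/origins into the
#'   table (for local-search experiments).
#' @param apply_ctf_flag simulate with (default) or without CTF.
#' @return `list(stack, table, truth, phantom)`: the image stack, the
#'   blind particle table, a `data.frame` of per-particle truth
#'   (whole-particle Euler angles; cap-module Euler angles `cap_rot`,
#'   `cap_tilt`, `cap_psi`; origins; cap projection offsets
#'   `cap_shift_x/y`; hinge angle/axis; defocus), and the phantom
#'   volumes.
#' @export
simulate_particles <- function(spec, n, snr, defocus_range = c(12000, 34000),
                               seed = 1, shift_max = 5,
                               with_truth_priors = FALSE,
                               apply_ctf_flag = TRUE) {
  stopifnot(inherits(spec, "fx_phantom_spec"))
  if (n < 1) stop("n must be >= 1")
  if (!(snr > 0)) stop("snr must be > 0")
  ph <- build_phantom(spec)
  box <- spec$box
  h <- c(0, 0, spec$hinge_z)
  rmax_cap <- support_radius(ph$cap$grid)
  rmax_tail <- support_radius(ph$tail$grid)

  draws <- with_seed(seed, {
    list(rot = runif(n, 0, 360),
         tilt = acos(runif(n, -1, 1)) * 180 / pi,
         psi = runif(n, 0, 360),
         alpha = rnorm(n, 0, spec$hinge_sigma),
         beta = runif(n, 0, 360),
         ox = runif(n, -shift_max, shift_max),
         oy = runif(n, -shift_max, shift_max),
         defocus = runif(n, defocus_range[1], defocus_range[2]),
         noise = rnorm(n * box * box))
  })

  stack <- array(0, c(box, box, n))
  truth <- data.frame(rot = wrap_angle(draws$rot), tilt = draws$tilt,
                      psi = wrap_angle(draws$psi),
                      hinge_angle = draws$alpha,
                      hinge_axis_azimuth = draws$beta,
                      origin_x = draws$ox, origin_y = draws$oy,
                      defocus = draws$defocus,
                      cap_rot = 0, cap_tilt = 0, cap_psi = 0,
                      cap_shift_x = 0, cap_shift_y = 0)
  support <- vector("list", n)
  for (i in seq_len(n)) {
    M <- euler_to_matrix(c(draws$rot[i], draws$tilt[i], draws$psi[i]))
    axis <- c(cos(draws$beta[i] * pi / 180),
              sin(draws$beta[i] * pi / 180), 0)
    H <- axis_angle_matrix(axis, draws$alpha[i])
    G <- M %*% H
    # rigid hinge rotation of the cap about h: the bent-cap projection
    # equals the static cap projected at G with an extra image shift
    # -(G t)_xy, t = h - H^{-1} h
    tvec <- h - crossprod(H, h)
    gs <- as.numeric(G %*% tvec)
    s <- c(draws$ox[i], draws$oy[i])
    img <- cpp_project(ph$tail$grid, M, s[1], s[2], box, rmax_tail) +
      cpp_project(ph$cap$grid, G, s[1] - gs[1], s[2] - gs[2], box,
                  rmax_cap)
    stack[, , i] <- img
    support[[i]] <- img > 0.02 * max(img)
    ecap <- matrix_to_euler(G)
    truth$cap_rot[i] <- ecap[1]
    truth$cap_tilt[i] <- ecap[2]
    truth$cap_psi[i] <- ecap[3]
    truth$cap_shift_x[i] <- -gs[1]
    truth$cap_shift_y[i] <- -gs[2]
  }

  table <- particle_table(n, pixel_size = spec$pixel_size,
                          defocus_u = draws$defocus,
                          defocus_v = draws$defocus)
  st <- fx_stack(stack, spec$pixel_size)
  if (apply_ctf_flag) st <- apply_ctf_stack(st, table)

  if (is.finite(snr)) {
    noise <- array(draws$noise, c(box, box, n))
    for (i in seq_len(n)) {
      sig_var <- stats::var(as.numeric(st$data[, , i][support[[i]]]))
      st$data[, , i] <- st$data[, , i] +
        noise[, , i] * sqrt(sig_var / snr)
    }
  }
  if (with_truth_priors) {
    table$rot <- truth$rot
    table$tilt <- truth$tilt
    table$psi <- truth$psi
    table$origin_x <- truth$origin_x
    table$origin_y <- truth$origin_y
  }
  list(stack = st, table = validate_particles(table), truth = truth,
       phantom = ph)
}

#' Score estimated orientations against simulator ground truth
#'
#' Per-particle symmetry-aware geodesic angular distance between truth
#' and estimate, plus the translational error where both tables carry
#' origins.
#'
#' @param truth data frame with `rot`, `tilt`, `psi` (e.g. the cap
#'   columns of the simulator truth, renamed) and optionally
#'   `origin_x/y`.
#' @param estimated_table a [particle_table()] of the same length and
#'   order.
#' @param symmetry cyclic order for the distance.
#' @return `list(median_deg, mean_deg, per_particle, trans_rmse)`.
#' @export
evaluate_alignment <- function(truth, estimated_table, symmetry = 1) {
  if (nrow(truth) != nrow(estimated_table))
    stop("truth and estimate lengths differ")
  d <- vapply(seq_len(nrow(truth)), function(i) {
    angular_distance(c(truth$rot[i], truth$tilt[i], truth$psi[i]),
                     c(estimated_table$rot[i], estimated_table$tilt[i],
                       estimated_table$psi[i]), symmetry)
  }, 0)
  trans <- NA_real_
  if (!is.null(truth$origin_x) && !is.null(estimated_table$origin_x)) {
    trans <- sqrt(mean((truth$origin_x - estimated_table$origin_x)^2 +
                         (truth$origin_y - estimated_table$origin_y)^2))
  }
  list(median_deg = median(d), mean_deg = mean(d), per_particle = d,
       trans_rmse = trans)
}

#' The versioned standard acceptance phantom configuration
#'
#' The fixed study conditions used throughout the package's own
#' validation: 96 px box at 3.26 A/px, two modules with an 8 degree
#' rocking hinge, SNR 0.08, 800 particles, defocus 1.2-3.4 um,
#' seed 1.
#'
#' @return A named list: `spec` (an [phantom_spec()]), `n`, `snr`,
#'   `defocus_range`, `seed`.
#' @export
pilq_like_preset <- function() {
  list(spec = phantom_spec(), n = 800L, snr = 0.08,
       defocus_range = c(12000, 34000), seed = 1L)
}
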