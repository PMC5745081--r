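# Reference-based orientation assignment. Scores are normalised
# cross-correlations under a circular mask; the translational search
# runs over an integer shift grid (applied to the particle as circular
# rolls) with an optional parabolic sub-pixel refinement. In-plane
# (psi) candidates are generated by rotating one projection per
# direction, which makes a 5-degree global library affordable: only
# the distinct (rot, tilt) directions are ray-traced.

#' Featureless initial reference
#'
#' Binary solid (sphere, or cylinder along z) with a 3 px raised-cosine
#' edge, the classical unbiased starting reference for projection
#' matching.
#'
#' @param kind `"sphere"` or `"cylinder"`.
#' @param box volume side in pixels.
#' @param radius solid radius in pixels (must be < box/2).
#' @param length cylinder length in pixels (ignored for spheres).
#' @param pixel_size voxel size in Angstrom.
#' @param edge_px cosine edge width.
#' @return An [fx_volume()].
#' @export
make_initial_reference <- function(kind = c("sphere", "cylinder"), box,
                                   radius, length = box / 2,
                                   pixel_size = 1, edge_px = 3) {
  kind <- match.arg(kind)
  if (radius >= box / 2) stop("radius must be smaller than box/2")
  coord <- seq_len(box) - 1 - box / 2
  edge_profile <- function(d) {  # d: signed distance beyond the surface
    if (edge_px <= 0) return(as.numeric(d <= 0))
    ifelse(d <= 0, 1, ifelse(d >= edge_px, 0,
                             0.5 * (1 + cos(pi * d / edge_px))))
  }
  if (kind == "sphere") {
    r2 <- outer(outer(coord^2, coord^2, `+`), coord^2, `+`)
    g <- edge_profile(sqrt(r2) - radius)
  } else {
    rho <- sqrt(outer(coord^2, coord^2, `+`))
    radial <- edge_profile(rho - radius)
    axial <- edge_profile(abs(coord) - length / 2)
    g <- outer(radial, axial)
  }
  dim(g) <- c(box, box, box)
  fx_volume(g, pixel_size)
}

# Deterministic quasi-uniform directions: Fibonacci spiral on the
# sphere, returned as (rot, tilt) in degrees with rot in [0, 360).
spiral_directions <- function(n_points) {
  i <- seq_len(n_points) - 0.5
  z <- 1 - 2 * i / n_points
  tilt <- acos(z) * 180 / pi
  golden <- pi * (3 - sqrt(5))
  rot <- (i * golden * 180 / pi) %% 360
  cbind(rot = rot, tilt = tilt)
}

#' Build a projection library over one asymmetric unit
#'
#' Directions are quasi-uniform (deterministic spiral) at
#' `angular_step` spacing, restricted to `rot` within one asymmetric
#' unit `[0, 360/symmetry)` of Cn; each direction is ray-traced once
#' and the in-plane angles `psi = 0, step, ...` are generated by
#' bilinear image rotation.
#'
#' @param reference an [fx_volume()].
#' @param angular_step angular spacing in degrees (> 0).
#' @param symmetry cyclic order n of Cn (1 for no symmetry).
#' @param psi_step in-plane step in degrees (defaults to
#'   `angular_step`).
#' @param out_box projection side (defaults to the reference box).
#' @return A list of class `fx_library`: `eulers` (K x 3), `images`
#'   (box x box x K), `angular_step`, `symmetry`, `pixel_size`.
#' @export
build_library <- function(reference, angular_step, symmetry = 1,
                          psi_step = angular_step, out_box = NULL) {
  stopifnot(inherits(reference, "fx_volume"))
  if (angular_step <= 0) stop("angular_step must be > 0")
  n <- if (is.null(out_box)) dim(reference$grid)[1] else out_box
  n_total <- max(4L, ceiling(41253 / angular_step^2))
  dirs <- spiral_directions(n_total)
  dirs <- dirs[dirs[, "rot"] < 360 / symmetry, , drop = FALSE]
  psis <- seq(0, 360 - psi_step, by = psi_step)
  rmax <- support_radius(reference$grid)

  k_total <- nrow(dirs) * length(psis)
  eulers <- matrix(0, k_total, 3,
                   dimnames = list(NULL, c("rot", "tilt", "psi")))
  images <- array(0, c(n, n, k_total))
  k <- 0
  for (d in seq_len(nrow(dirs))) {
    base <- cpp_project(reference$grid,
                        euler_to_matrix(c(dirs[d, 1], dirs[d, 2], 0)),
                        0, 0, as.integer(n), rmax)
    for (p in psis) {
      k <- k + 1
      eulers[k, ] <- c(dirs[d, 1], dirs[d, 2], p)
      images[, , k] <- if (p == 0) base else cpp_rotate_image(base, p)
    }
  }
  structure(list(eulers = eulers, images = images,
                 angular_step = angular_step, symmetry = symmetry,
                 pixel_size = reference$pixel_size),
            class = "fx_library")
}

circular_mask <- function(n, radius_frac = 0.45) {
  xy <- seq_len(n) - 1 - n / 2
  sqrt(outer(xy^2, xy^2, `+`)) <= radius_frac * n
}

# Flatten images to zero-mean unit-norm vectors under the mask, so that
# plain dot products are normalised cross-correlations. Constant
# images get norm 0 and score 0 against everything.
normalize_masked <- function(arr, mask) {
  n <- sum(mask)
  m <- matrix(arr[rep(mask, length.out = length(arr))],
              nrow = n)
  m <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  nrm[nrm < 1e-12] <- Inf
  sweep(m, 2, nrm, `/`)
}

shift_grid <- function(shift_max, shift_step) {
  s <- seq(-shift_max, shift_max, by = shift_step)
  expand.grid(dx = s, dy = s)
}

# Parabolic 1D sub-step refinement from three scores around a maximum.
parabolic_offset <- function(sm, s0, sp) {
  den <- sm - 2 * s0 + sp
  if (abs(den) < 1e-12) return(0)
  off <- 0.5 * (sm - sp) / den
  max(-0.5, min(0.5, off))
}

#' Assign particle orientations by projection matching
#'
#' Global mode scores every particle against every library entry over
#' an integer shift grid and keeps the argmax of the normalised
#' cross-correlation (ties broken by the smallest library index).
#' Local mode searches a per-particle grid of Euler offsets around the
#' prior orientation (step `fine_step`, extent `delta` on each of rot,
#' tilt, psi) and a shift grid around the prior origin, with parabolic
#' sub-pixel refinement of the shifts.
#'
#' @param stack an [fx_stack()].
#' @param library an `fx_library` from [build_library()] (global mode),
#'   or the reference [fx_volume()] itself when `local` is given.
#' @param local `NULL` for global matching, else a list with
#'   `prior_table` (a [particle_table()]), `delta`, `fine_step`
#'   (degrees), and optionally `shift_max`, `shift_step` (pixels).
#' @param shift_max,shift_step global-mode translational search: grid
#'   `seq(-shift_max, shift_max, shift_step)` in pixels.
#' @param mask_radius circular scoring mask radius as a fraction of the
#'   box.
#' @param filter2d optional real filter on the centred frequency grid
#'   (e.g. an average |CTF|) applied to reference projections before
#'   scoring.
#' @param n_hypotheses global mode only: with 2, a second orientation
#'   hypothesis from a different viewing-direction basin (at least 20
#'   degrees away) is returned in `alt_*` columns, so that a later
#'   local refinement can rescue near-degenerate global matches.
#' @return A [particle_table()] with updated `rot`, `tilt`, `psi`,
#'   `origin_x`, `origin_y` and a score column `fa_cc`.
#' @export
assign_orientations <- function(stack, library, local = NULL,
                                shift_max = 8, shift_step = 2,
                                mask_radius = 0.45, filter2d = NULL,
                                n_hypotheses = 1) {
  stopifnot(inherits(stack, "fx_stack"))
  if (is.null(local)) {
    assign_global(stack, library, shift_max, shift_step, mask_radius,
                  filter2d, n_hypotheses)
  } else {
    assign_local(stack, library, local, mask_radius, filter2d)
  }
}

filter_images <- function(arr, filter2d) {
  if (is.null(filter2d)) return(arr)
  Re(batch_fft2(batch_fft2(arr) *
                  as.vector(filter2d), inverse = TRUE))
}

assign_global <- function(stack, library, shift_max, shift_step,
                          mask_radius, filter2d, n_hypotheses = 1) {
  stopifnot(inherits(library, "fx_library"))
  n <- dim(stack$data)[1]
  if (dim(library$images)[1] != n)
    stop("library and stack box sizes differ")
  k_lib <- dim(library$images)[3]
  if (k_lib == 0) stop("empty library")
  k <- n_images(stack)
  mask <- circular_mask(n, mask_radius)
  L <- t(normalize_masked(filter_images(library$images, filter2d),
                          mask))                       # K x npix
  shifts <- shift_grid(shift_max, shift_step)
  # per-(entry, particle) best score over shifts, plus the shift index
  S <- matrix(-Inf, k_lib, k)
  Sidx <- matrix(1L, k_lib, k)
  chunk <- max(1L, floor(2e7 / k_lib))
  for (s in seq_len(nrow(shifts))) {
    dx <- shifts$dx[s]; dy <- shifts$dy[s]
    rolled <- stack$data
    if (dx != 0 || dy != 0)
      for (i in seq_len(k)) rolled[, , i] <-
          roll_image(stack$data[, , i], -dx, -dy)
    P <- normalize_masked(rolled, mask)                # npix x K
    for (i0 in seq(1, k, by = chunk)) {
      ii <- i0:min(k, i0 + chunk - 1)
      sc <- L %*% P[, ii, drop = FALSE]                # K_lib x chunk
      upd <- sc > S[, ii, drop = FALSE]
      S[, ii][upd] <- sc[upd]
      Sidx[, ii][upd] <- s
    }
  }
  best_entry <- max.col(t(S), ties.method = "first")
  fill <- function(entries) {
    sidx <- Sidx[cbind(entries, seq_len(k))]
    data.frame(rot = library$eulers[entries, 1],
               tilt = library$eulers[entries, 2],
               psi = library$eulers[entries, 3],
               origin_x = shifts$dx[sidx],
               origin_y = shifts$dy[sidx],
               fa_cc = S[cbind(entries, seq_len(k))])
  }
  tab <- particle_table(k, pixel_size = stack$pixel_size)
  b <- fill(best_entry)
  for (nm in names(b)) tab[[nm]] <- b[[nm]]
  if (n_hypotheses > 1) {
    # best alternative in a genuinely different orientation basin:
    # viewing direction at least 20 degrees from the winner
    dirs <- t(vapply(seq_len(k_lib), function(j)
      euler_to_matrix(library$eulers[j, ])[3, ], numeric(3)))
    coslim <- cos(20 * pi / 180)
    alt_entry <- vapply(seq_len(k), function(i) {
      far <- which((dirs %*% dirs[best_entry[i], ]) < coslim)
      if (!length(far)) return(best_entry[i])
      far[which.max(S[far, i])]
    }, 0L)
    a <- fill(alt_entry)
    for (nm in names(a)) tab[[paste0("alt_", nm)]] <- a[[nm]]
  }
  validate_particles(tab)
}

assign_local <- function(stack, reference, local, mask_radius,
                         filter2d) {
  stopifnot(inherits(reference, "fx_volume"))
  prior <- local$prior_table
  delta <- rep_len(local$delta, 3)       # (rot, tilt, psi) extents
  step <- rep_len(local$fine_step, 3)
  sh_max <- if (!is.null(local$shift_max)) local$shift_max else 2
  sh_step <- if (!is.null(local$shift_step)) local$shift_step else 1
  n <- dim(stack$data)[1]
  k <- n_images(stack)
  if (nrow(prior) != k) stop("prior table and stack sizes differ")
  mask <- circular_mask(n, mask_radius)
  rmax <- support_radius(reference$grid)
  offsets <- lapply(1:3, function(a)
    if (delta[a] <= 0) 0 else seq(-delta[a], delta[a], by = step[a]))
  shifts <- shift_grid(sh_max, sh_step)
  n_sh <- nrow(shifts)
  sgrid <- sort(unique(shifts$dx))

  ctf_tab <- local$ctf_table
  out <- prior
  out$fa_cc <- -Inf
  filt <- filter2d
  for (i in seq_len(k)) {
    e0 <- c(prior$rot[i], prior$tilt[i], prior$psi[i])
    o0 <- c(prior$origin_x[i], prior$origin_y[i])
    if (all(abs(shifts$dx - round(shifts$dx)) < 1e-9))
      o0 <- round(o0)                  # integer grid: roll-based search
    # per-particle |CTF| applied to the reference candidates so that
    # they carry the same modulation as the phase-flipped particle;
    # with zero astigmatism the filter is radial and commutes with the
    # in-plane psi rotation, so coarse rounds filter before rotating
    fi <- if (is.null(ctf_tab)) filt else {
      f <- abs(ctf_2d(ctf_from_record(ctf_tab, i), n,
                      stack$pixel_size))
      if (is.null(filt)) f else f * filt
    }
    cand <- expand.grid(dr = offsets[[1]], dt = offsets[[2]],
                        dp = offsets[[3]])
    n_cand <- nrow(cand)
    imgs <- array(0, c(n, n, n_cand))
    if (identical(local$psi_mode, "project")) {
      # exact: one ray-traced projection per candidate (fine rounds)
      for (j in seq_len(n_cand)) {
        e <- e0 + c(cand$dr[j], cand$dt[j], cand$dp[j])
        imgs[, , j] <- cpp_project(reference$grid, euler_to_matrix(e),
                                   0, 0, as.integer(n), rmax)
      }
      imgs <- filter_images(imgs, fi)
    } else {
      # fast: one ray-traced projection per (rot, tilt); psi via
      # in-plane rotation (interpolation-limited, for coarse rounds)
      rt <- expand.grid(dr = offsets[[1]], dt = offsets[[2]])
      proj_rt <- array(0, c(n, n, nrow(rt)))
      for (j in seq_len(nrow(rt))) {
        e <- c(e0[1] + rt$dr[j], e0[2] + rt$dt[j], 0)
        proj_rt[, , j] <- cpp_project(reference$grid,
                                      euler_to_matrix(e), 0, 0,
                                      as.integer(n), rmax)
      }
      proj_rt <- filter_images(proj_rt, fi)
      n_rt <- nrow(rt)
      for (j in seq_len(n_cand)) {
        jrt <- ((j - 1) %% n_rt) + 1   # expand.grid: (dr, dt) cycle first
        psi <- e0[3] + cand$dp[j]
        imgs[, , j] <- if (psi == 0) proj_rt[, , jrt] else
          cpp_rotate_image(proj_rt[, , jrt], psi)
      }
    }
    Lc <- t(normalize_masked(imgs, mask))
    pv <- array(0, c(n, n, n_sh))
    whole <- all(abs(shifts$dx - round(shifts$dx)) < 1e-9)
    for (s in seq_len(n_sh)) {
      dx <- o0[1] + shifts$dx[s]
      dy <- o0[2] + shifts$dy[s]
      pv[, , s] <- if (whole) roll_image(stack$data[, , i], -dx, -dy)
        else shift_image(stack$data[, , i], -dx, -dy)
    }
    Pm <- normalize_masked(pv, mask)
    rm(pv)
    sc <- Lc %*% Pm                                   # cand x shift
    top <- arrayInd(which.max(sc), dim(sc))
    jc <- top[1]; js <- top[2]
    # parabolic sub-pixel shifts from the score grid
    sub <- c(0, 0)
    if (sh_step <= 1.5) {
      ix <- match(shifts$dx[js], sgrid)
      iy <- match(shifts$dy[js], sgrid)
      scm <- matrix(sc[jc, ], length(sgrid), length(sgrid))
      if (ix > 1 && ix < length(sgrid))
        sub[1] <- sh_step * parabolic_offset(scm[ix - 1, iy],
                                             scm[ix, iy],
                                             scm[ix + 1, iy])
      if (iy > 1 && iy < length(sgrid))
        sub[2] <- sh_step * parabolic_offset(scm[ix, iy - 1],
                                             scm[ix, iy],
                                             scm[ix, iy + 1])
    }
    out$rot[i] <- e0[1] + cand$dr[jc]
    out$tilt[i] <- min(180, max(0, e0[2] + cand$dt[jc]))
    out$psi[i] <- e0[3] + cand$dp[jc]
    out$origin_x[i] <- o0[1] + shifts$dx[js] + sub[1]
    out$origin_y[i] <- o0[2] + shifts$dy[js] + sub[2]
    out$fa_cc[i] <- sc[jc, js]
  }
  validate_particles(out)
}

# Score each record's current orientation/origin against a reference:
# normalised cross-correlation of the (optionally CTF-modulated)
# projection with the particle image, under the circular mask.
score_against_reference <- function(stack, reference, table,
                                    ctf_table = NULL,
                                    mask_radius = 0.45) {
  n <- dim(stack$data)[1]
  k <- n_images(stack)
  mask <- circular_mask(n, mask_radius)
  rmax <- support_radius(reference$grid)
  vapply(seq_len(k), function(i) {
    p <- cpp_project(reference$grid,
                     euler_to_matrix(c(table$rot[i], table$tilt[i],
                                       table$psi[i])),
                     table$origin_x[i], table$origin_y[i],
                     as.integer(n), rmax)
    if (!is.null(ctf_table)) {
      fi <- abs(ctf_2d(ctf_from_record(ctf_table, i), n,
                       stack$pixel_size))
      p <- Re(fft2c(fft2c(p) * fi, inverse = TRUE))
    }
    pv <- p[mask]; pv <- pv - mean(pv)
    iv <- stack$data[, , i][mask]; iv <- iv - mean(iv)
    den <- sqrt(sum(pv^2) * sum(iv^2))
    if (den < 1e-12) 0 else sum(pv * iv) / den
  }, 0)
}

#' Symmetry-aware geodesic distance between two orientations
#'
#' Minimum rotation angle between `M(e1)` and `M(e2) S_k` over all
#' in-plane symmetry copies `S_k = Rz(k 360/n)` of Cn (the symmetry
#' axis lives in the reference frame, so equivalent orientations differ
#' by right-multiplication).
#'
#' @param e1,e2 Euler triplets `(rot, tilt, psi)` in degrees.
#' @param symmetry cyclic order n.
#' @return Angle in degrees in `[0, 180]`.
#' @export
angular_distance <- function(e1, e2, symmetry = 1) {
  M1 <- euler_to_matrix(e1)
  M2 <- euler_to_matrix(e2)
  A <- crossprod(M1, M2)                 # M1^T M2
  best <- Inf
  for (kk in 0:(symmetry - 1)) {
    tr <- sum(diag(A %*% rot_z(kk * 360 / symmetry)))
    ang <- acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
    if (ang < best) best <- ang
  }
  best
}
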