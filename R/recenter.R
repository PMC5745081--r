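# Sub-particle recentering: map a chosen 3D point of the consensus
# reference into each particle image, re-window the particle about that
# point in a smaller box, and update the metadata (sub-pixel residual
# origins, depth-corrected defocus). Extraction is integer-pixel; the
# sub-pixel remainder is carried in the origin fields rather than
# interpolated into the image, so no interpolation loss occurs before
# alignment.

#' Recentering specification
#'
#' @param center3d point `(x, y, z)` in voxels relative to the
#'   reference box centre that the new boxes are centred on.
#' @param new_box output box side in pixels (even, at most the
#'   original box).
#' @return An object of class `fx_recenter_spec`.
#' @export
recenter_spec <- function(center3d, new_box) {
  stopifnot(length(center3d) == 3)
  if (new_box %% 2 != 0) stop("new_box must be even")
  structure(list(center3d = as.numeric(center3d),
                 new_box = as.integer(new_box)),
            class = "fx_recenter_spec")
}

#' Project a 3D reference point into a particle image
#'
#' With `u = M(e) center3d`, returns the image-frame position
#' `(u_x + ox, u_y + oy)` and the depth offset `u_z` along the beam.
#'
#' @param center3d point in voxels relative to the reference centre.
#' @param euler particle orientation `(rot, tilt, psi)` in degrees.
#' @param origin in-plane origin shift `(ox, oy)` in pixels.
#' @return `list(px, py, z_offset)`.
#' @export
project_point <- function(center3d, euler, origin = c(0, 0)) {
  u <- euler_to_matrix(euler) %*% as.numeric(center3d)
  list(px = u[1] + origin[1], py = u[2] + origin[2], z_offset = u[3])
}

#' Intensity-weighted centre of a module mask
#'
#' @param mask an [fx_volume()] with non-negative weights.
#' @return `(x, y, z)` centroid in voxels relative to the box centre.
#' @export
module_centers_from_mask <- function(mask) {
  stopifnot(inherits(mask, "fx_volume"))
  g <- mask$grid
  tot <- sum(g)
  if (tot <= 0) stop("empty mask")
  n <- dim(g)[1]
  coord <- seq_len(n) - 1 - n / 2
  c(sum(apply(g, 1, sum) * coord),
    sum(apply(g, 2, sum) * coord),
    sum(apply(g, 3, sum) * coord)) / tot
}

#' Re-box a reference volume about a module centre
#'
#' Convenience wrapper around [resample_volume()]: returns the
#' `new_box`-sized volume whose centre sits at `center3d` of the input
#' map, i.e. the reference that recentered particles align against.
#'
#' @param vol an [fx_volume()].
#' @param center3d module centre in voxels relative to the box centre.
#' @param new_box output side in pixels.
#' @return An [fx_volume()].
#' @export
recenter_volume <- function(vol, center3d, new_box) {
  resample_volume(vol, R = diag(3), t = center3d, out_box = new_box)
}

#' Re-window particles about a projected 3D point
#'
#' For each record the chosen reference point is projected with
#' [project_point()], a `new_box` window centred on the rounded
#' position is extracted, the sub-pixel remainder is stored in the
#' origin fields, Euler angles are copied unchanged (they remain valid
#' priors for local search), and the defocus is depth-corrected with
#' [adjust_defocus_for_z()]. Windows reaching outside the original box
#' are padded according to `edge` and flagged in `fa_edge_padded`;
#' records whose window lies fully outside are dropped with a message.
#'
#' @param stack an [fx_stack()].
#' @param table matching [particle_table()] with consensus alignment.
#' @param spec an [recenter_spec()].
#' @param z_sign sign convention for the defocus depth correction.
#' @param edge `"mean"` (annulus mean of the source image), `"zero"`,
#'   or `"noise"` (Gaussian with the annulus mean/sd).
#' @return `list(stack, table)` with the re-windowed images and updated
#'   metadata.
#' @export
recenter_stack <- function(stack, table, spec, z_sign = 1,
                           edge = c("mean", "zero", "noise")) {
  edge <- match.arg(edge)
  stopifnot(inherits(stack, "fx_stack"),
            inherits(spec, "fx_recenter_spec"))
  n <- dim(stack$data)[1]
  nb <- spec$new_box
  if (nb > n) stop("new_box exceeds the original box")
  k <- n_images(stack)
  if (nrow(table) != k) stop("stack and table sizes differ")
  if (sqrt(sum(spec$center3d^2)) >= n / 2)
    stop("center3d lies outside the reference sphere")

  cc <- n / 2          # 0-based centre of source
  co <- nb / 2         # 0-based centre of window
  out <- array(0, c(nb, nb, k))
  keep <- rep(TRUE, k)
  padded <- numeric(k)
  xy <- seq_len(n) - 1 - cc
  rr <- sqrt(outer(xy^2, xy^2, `+`))
  annulus <- rr >= 0.45 * n & rr <= 0.5 * n

  for (i in seq_len(k)) {
    pp <- project_point(spec$center3d,
                        c(table$rot[i], table$tilt[i], table$psi[i]),
                        c(table$origin_x[i], table$origin_y[i]))
    tx <- round(pp$px); ty <- round(pp$py)
    # source pixel range (0-based): centre cc + t, half-width co
    x0 <- cc + tx - co; y0 <- cc + ty - co
    sx <- x0 + seq_len(nb) - 1
    sy <- y0 + seq_len(nb) - 1
    okx <- sx >= 0 & sx < n
    oky <- sy >= 0 & sy < n
    if (!any(okx) || !any(oky)) {
      keep[i] <- FALSE
      message("record ", i, ": window fully outside the image; dropped")
      next
    }
    img <- stack$data[, , i]
    fill <- switch(edge, zero = 0, mean = mean(img[annulus]),
                   noise = mean(img[annulus]))
    win <- matrix(fill, nb, nb)
    if (edge == "noise")
      win <- matrix(rnorm(nb * nb, mean(img[annulus]),
                          sd(img[annulus])), nb, nb)
    win[okx, oky] <- img[sx[okx] + 1, sy[oky] + 1]
    out[, , i] <- win
    padded[i] <- as.numeric(!all(okx) || !all(oky))
    table$origin_x[i] <- pp$px - tx
    table$origin_y[i] <- pp$py - ty
    p <- adjust_defocus_for_z(ctf_from_record(table, i), pp$z_offset,
                              stack$pixel_size, z_sign)
    table$defocus_u[i] <- p$defocus_u
    table$defocus_v[i] <- p$defocus_v
  }
  table$fa_edge_padded <- padded
  list(stack = fx_stack(out[, , keep, drop = FALSE], stack$pixel_size),
       table = validate_particles(table[keep, , drop = FALSE]))
}
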