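# Residual signal subtraction: remove the CTF-modulated projection of
# everything outside a chosen module from each experimental image, so
# that only the module of interest remains for local alignment.

#' Build a soft-edged 3D mask from a reference map
#'
#' Binarises the map at `threshold`, dilates the binary region by
#' `extend_px` (Euclidean distance), and adds a raised-cosine edge of
#' width `soft_edge_px`, i.e. the mask value at distance d beyond the
#' dilated surface is `0.5 (1 + cos(pi d / soft_edge_px))`.
#'
#' @param reference an [fx_volume()].
#' @param threshold binarisation level (must be below the map maximum).
#' @param extend_px dilation distance in voxels.
#' @param soft_edge_px cosine edge width in voxels; 0 gives a binary
#'   mask.
#' @return An [fx_volume()] with values in \[0, 1\].
#' @export
make_soft_mask <- function(reference, threshold, extend_px = 0,
                           soft_edge_px = 3) {
  stopifnot(inherits(reference, "fx_volume"))
  if (soft_edge_px < 0) stop("soft_edge_px must be >= 0")
  bin <- reference$grid >= threshold
  if (!any(bin)) stop("empty mask: threshold is above the map maximum")
  storage.mode(bin) <- "double"
  d <- sqrt(cpp_edt_sq(bin)) - extend_px
  if (soft_edge_px > 0) {
    m <- ifelse(d <= 0, 1,
                ifelse(d < soft_edge_px,
                       0.5 * (1 + cos(pi * d / soft_edge_px)), 0))
  } else {
    m <- as.numeric(d <= 0)
  }
  dim(m) <- dim(reference$grid)
  fx_volume(m, reference$pixel_size)
}

#' Subtract the signal outside a kept region from particle images
#'
#' For every record i, the projection of `(1 - keep_mask) * reference`
#' at the record's orientation and origin is CTF-modulated with the
#' record's parameters and subtracted:
#' `out_i = img_i - s_i * CTF_i{ proj((1 - keep) ref, e_i, o_i) }`.
#' The scale is `s_i = 1` (`scale_mode = "fixed"`) or a least-squares
#' amplitude fit within the footprint of the subtracted projection
#' (`scale_mode = "lsq"`; falls back to 1 with a warning when the
#' footprint has no variance). Origins are applied to the projection,
#' so the output stays in the original particle frame.
#'
#' @param stack an [fx_stack()] of aligned particles.
#' @param table matching [particle_table()] with valid orientations,
#'   origins and CTF parameters.
#' @param reference consensus map ([fx_volume()], same box as images).
#' @param keep_mask [fx_volume()] in \[0, 1\] selecting the density to
#'   keep.
#' @param scale_mode `"fixed"` or `"lsq"`.
#' @param normalize_background divide each output image by the standard
#'   deviation of its edge annulus (off by default; subtracted images
#'   are left unnormalised).
#' @return `list(stack, table)`: the subtracted stack and the table
#'   with a `fa_subtracted` provenance column; all other fields are
#'   unchanged.
#' @export
subtract_signal <- function(stack, table, reference, keep_mask,
                            scale_mode = c("fixed", "lsq"),
                            normalize_background = FALSE) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(inherits(stack, "fx_stack"), inherits(reference, "fx_volume"),
            inherits(keep_mask, "fx_volume"))
  n <- dim(stack$data)[1]
  if (!identical(dim(reference$grid), dim(keep_mask$grid)))
    stop("grid mismatch: reference and keep_mask differ")
  if (dim(reference$grid)[1] != n)
    stop("grid mismatch: reference box differs from image box")
  if (any(keep_mask$grid < -1e-9 | keep_mask$grid > 1 + 1e-9))
    stop("keep_mask values must lie in [0, 1]")
  k <- n_images(stack)
  if (nrow(table) != k) stop("stack and table sizes differ")

  sub_grid <- (1 - keep_mask$grid) * reference$grid
  rmax <- support_radius(sub_grid)
  proj <- array(0, c(n, n, k))
  for (i in seq_len(k)) {
    M <- euler_to_matrix(c(table$rot[i], table$tilt[i], table$psi[i]))
    proj[, , i] <- cpp_project(sub_grid, M, table$origin_x[i],
                               table$origin_y[i], n, rmax)
  }
  f <- batch_fft2(proj)
  for (i in seq_len(k)) {
    ctf <- ctf_2d(ctf_from_record(table, i), n, stack$pixel_size)
    f[, , i] <- f[, , i] * ctf
  }
  proj <- Re(batch_fft2(f, inverse = TRUE))

  out <- stack$data
  for (i in seq_len(k)) {
    p <- proj[, , i]
    s <- 1
    if (scale_mode == "lsq") {
      fp <- abs(p) > 0.025 * max(abs(p))
      denom <- sum(p[fp]^2)
      if (denom < 1e-12) {
        warning("zero-variance subtraction footprint for record ", i,
                "; falling back to s = 1")
      } else {
        s <- sum(out[, , i][fp] * p[fp]) / denom
      }
    }
    out[, , i] <- out[, , i] - s * p
    if (normalize_background) {
      cc <- n / 2
      xy <- (seq_len(n) - 1 - cc)
      rr <- sqrt(outer(xy^2, xy^2, `+`))
      bg <- sd(out[, , i][rr > 0.45 * n])
      if (bg > 0) out[, , i] <- out[, , i] / bg
    }
  }
  table$fa_subtracted <- 1
  list(stack = fx_stack(out, stack$pixel_size), table = table)
}
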