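# Orientation convention: a ZYZ Euler triplet (rot, tilt, psi), all in
# degrees, defines M = Rz(psi) %*% Ry(tilt) %*% Rz(rot). A vector v in
# the reference frame maps to u = M v in the projection frame, and a
# projection integrates the rotated density along u_z. This single
# convention binds the simulator, the projector, recentering and the
# aligners to each other; the tests enforce the self-consistency.

rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix from a ZYZ Euler triplet
#'
#' `M = Rz(psi) Ry(tilt) Rz(rot)`; reference-frame vectors map to the
#' projection frame as `u = M v`.
#'
#' @param euler numeric length-3 vector `(rot, tilt, psi)` in degrees.
#' @return 3x3 rotation matrix (orthonormal, det +1).
#' @export
euler_to_matrix <- function(euler) {
  rot_z(euler[3]) %*% rot_y(euler[2]) %*% rot_z(euler[1])
}

#' Euler triplet from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At the gimbal-locked poles
#' (tilt near 0 or 180 degrees) only the sum/difference of rot and psi
#' is defined; the convention here puts all of it into psi and sets
#' rot = 0.
#'
#' @param M 3x3 rotation matrix.
#' @return Numeric `(rot, tilt, psi)` in degrees, with
#'   `tilt` in `[0, 180]` and rot, psi in `[-180, 180)`.
#' @export
matrix_to_euler <- function(M) {
  if (max(abs(crossprod(M) - diag(3))) > 1e-6)
    stop("not a rotation: input matrix is not orthonormal")
  r2d <- 180 / pi
  st <- sqrt(M[1, 3]^2 + M[2, 3]^2)  # sin(tilt)
  if (st < 1e-10) {
    if (M[3, 3] > 0) {               # tilt = 0: M = Rz(psi + rot)
      e <- c(0, 0, atan2(M[2, 1], M[1, 1]) * r2d)
    } else {                         # tilt = 180: M = Rz(psi) diag(-1,1,-1)
      e <- c(0, 180, atan2(-M[2, 1], -M[1, 1]) * r2d)
    }
  } else {
    tilt <- atan2(st, M[3, 3]) * r2d
    psi <- atan2(M[2, 3], M[1, 3]) * r2d
    rot <- atan2(M[3, 2], -M[3, 1]) * r2d
    e <- c(rot, tilt, psi)
  }
  c(wrap_angle(e[1]), e[2], wrap_angle(e[3]))
}

# Radius (voxels from centre) beyond which the volume is numerically
# empty; rays outside it can be skipped by the projector.
support_radius <- function(grid, rel_tol = 1e-8) {
  n <- dim(grid)[1]
  mx <- max(abs(grid))
  if (mx == 0) return(1)
  idx <- which(abs(grid) > rel_tol * mx, arr.ind = TRUE)
  cc <- n / 2 + 1
  min(n / 2, sqrt(max(rowSums((idx - cc)^2))) + 2)
}

#' Project a volume along the beam axis
#'
#' Real-space line integral of the rotated volume: the image value at
#' projection coordinate `(x, y)` is the sum over z of
#' `vol(M^T (x, y, z))`, sampled at unit steps with trilinear
#' interpolation, then translated so the content moves by `+shift`
#' pixels. Density is assumed to live inside the inscribed sphere of
#' the box (`rmax`); rays outside it are exactly zero.
#'
#' @param vol an [fx_volume()].
#' @param euler `(rot, tilt, psi)` in degrees.
#' @param shift length-2 shift `(dx, dy)` in pixels applied to the
#'   projected content.
#' @param out_box output image side in pixels (defaults to the volume
#'   side).
#' @param rmax support radius in voxels; defaults to the measured
#'   support of `vol` (capped at N/2).
#' @return `out_box x out_box` numeric matrix.
#' @export
project_volume <- function(vol, euler = c(0, 0, 0), shift = c(0, 0),
                           out_box = NULL, rmax = NULL) {
  stopifnot(inherits(vol, "fx_volume"))
  n <- dim(vol$grid)[1]
  if (is.null(out_box)) out_box <- n
  if (is.null(rmax)) rmax <- support_radius(vol$grid)
  cpp_project(vol$grid, euler_to_matrix(euler), shift[1], shift[2],
              as.integer(out_box), rmax)
}

#' Translate an image by a (possibly fractional) shift
#'
#' Fourier phase-ramp translation: content moves by `+(dx, dy)` pixels
#' with circular wrap-around. Integer shifts reproduce an exact
#' circular roll.
#'
#' @param img square numeric matrix.
#' @param dx,dy shift in pixels.
#' @return Shifted image (real matrix).
#' @export
shift_image <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img)
  Re(fft2c(fft2c(img) * phase_ramp2(n, dx, dy), inverse = TRUE))
}

# Integer circular roll with the same +shift semantics as shift_image.
roll_image <- function(img, dx, dy) {
  n <- nrow(img)
  ix <- ((seq_len(n) - 1 - dx) %% n) + 1
  iy <- ((seq_len(n) - 1 - dy) %% n) + 1
  img[ix, iy, drop = FALSE]
}

#' Resample a volume under a rigid transform
#'
#' `out(v) = vol(R v + t)` with v in centred output-box coordinates and
#' trilinear interpolation; out-of-range samples are zero. With
#' `R = t(euler_to_matrix(e))` and `t = 0` this rotates the density by
#' `e`; with `R = I` and `t = centre` it re-boxes a sub-volume about
#' `centre` (used to build module references).
#'
#' @param vol an [fx_volume()].
#' @param R 3x3 matrix applied to output coordinates.
#' @param t length-3 offset in voxels.
#' @param out_box output side (defaults to input side).
#' @return An [fx_volume()] with the same pixel size.
#' @export
resample_volume <- function(vol, R = diag(3), t = c(0, 0, 0),
                            out_box = NULL) {
  stopifnot(inherits(vol, "fx_volume"))
  n <- dim(vol$grid)[1]
  if (is.null(out_box)) out_box <- n
  fx_volume(cpp_resample_volume(vol$grid, R, as.numeric(t),
                                as.integer(out_box)),
            vol$pixel_size)
}

#' Rotate a volume's density by an Euler triplet
#'
#' The density is rotated so that a feature at reference coordinate v
#' moves to `M v` (same sense as the projector).
#'
#' @param vol an [fx_volume()].
#' @param euler `(rot, tilt, psi)` in degrees.
#' @return Rotated [fx_volume()].
#' @export
rotate_volume <- function(vol, euler) {
  resample_volume(vol, R = t(euler_to_matrix(euler)))
}

#' Reconstruct a volume from aligned particle images
#'
#' Direct Fourier inversion: the centred 2D transform of every image is
#' phase-shifted back by its origin, inserted as a central slice at its
#' Euler orientation with trilinear spreading (plus the Hermitian
#' mate), the accumulated grid is normalised by the accumulated
#' interpolation weights, and inverse-transformed.
#'
#' @param stack an [fx_stack()] of aligned particles.
#' @param table matching [particle_table()] carrying `rot`, `tilt`,
#'   `psi`, `origin_x`, `origin_y`.
#' @param min_weight voxels with accumulated weight below this are set
#'   to zero rather than amplified.
#' @return An [fx_volume()] of the same box and pixel size.
#' @export
reconstruct <- function(stack, table, min_weight = 0.2) {
  stopifnot(inherits(stack, "fx_stack"))
  k <- n_images(stack)
  if (k == 0) stop("empty stack")
  if (nrow(table) != k) stop("stack and table sizes differ")
  n <- dim(stack$data)[1]

  dirs <- vapply(seq_len(k), function(i) {
    euler_to_matrix(c(table$rot[i], table$tilt[i], table$psi[i]))[3, ]
  }, numeric(3))
  if (k > 1) {
    cosang <- crossprod(dirs[, 1], dirs)
    if (all(abs(abs(cosang) - 1) < 1e-6))
      warning("anisotropic coverage: all projection directions coincide")
  }

  f <- batch_fft2(stack$data)
  for (i in seq_len(k)) {
    if (table$origin_x[i] != 0 || table$origin_y[i] != 0)
      f[, , i] <- f[, , i] *
        phase_ramp2(n, -table$origin_x[i], -table$origin_y[i])
  }
  Rarr <- vapply(seq_len(k), function(i) {
    as.numeric(euler_to_matrix(c(table$rot[i], table$tilt[i],
                                 table$psi[i])))
  }, numeric(9))
  acc <- cpp_insert_slices(Re(f), Im(f), matrix(Rarr, 9, k), n / 2 - 1)
  fv <- complex(real = acc$re, imaginary = acc$im)
  w <- pmax(acc$wt, min_weight)
  fv <- fv / w
  fv[acc$wt < min_weight] <- 0
  dim(fv) <- c(n, n, n)
  vol <- Re(fft3c(fv, inverse = TRUE))
  fx_volume(vol, stack$pixel_size)
}
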