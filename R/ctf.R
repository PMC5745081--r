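# Contrast transfer function. Sign convention: underfocus is positive
# and the CTF is negative at low frequency,
#   CTF(f) = -sqrt(1 - w^2) sin(chi) - w cos(chi),
#   chi(f, theta) = pi lambda df(theta) f^2 - (pi/2) Cs lambda^3 f^4
#                   + phase_shift,
# with the astigmatic defocus
#   df(theta) = (du + dv)/2 + (du - dv)/2 cos(2 (theta - astig)).
# At f = 0 this evaluates to -w (the amplitude-contrast fraction).

#' CTF parameter set
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism
#'   axes in Angstrom (underfocus positive).
#' @param astig_angle astigmatism azimuth in degrees.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in \[0, 1\].
#' @param phase_shift additional phase shift in degrees (phase plate).
#' @return An object of class `fx_ctf`.
#' @export
ctf_params <- function(defocus_u = 20000, defocus_v = defocus_u,
                       astig_angle = 0, voltage = 300, cs = 2.0,
                       amplitude_contrast = 0.07, phase_shift = 0) {
  if (voltage <= 0) stop("voltage must be > 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift), class = "fx_ctf")
}

ctf_from_record <- function(table, i) {
  ctf_params(table$defocus_u[i], table$defocus_v[i],
             table$astig_angle[i], table$voltage[i], table$cs[i],
             table$amplitude_contrast[i], table$phase_shift[i])
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV.
#' @return Wavelength in Angstrom (0.0197 A at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  u <- voltage_kv * 1000
  12.2639 / sqrt(u + 0.97845e-6 * u^2)
}

#' Evaluate the CTF on a centred 2D frequency grid
#'
#' @param p an [ctf_params()] set.
#' @param box image side in pixels (even).
#' @param pixel_size pixel size in Angstrom.
#' @return `box x box` matrix of CTF values, DC at 0-based pixel
#'   `box/2`; real, equal to `-amplitude_contrast` at f = 0.
#' @export
ctf_2d <- function(p, box, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  g <- freq_grid2(box)
  fx <- g$kx / (box * pixel_size)
  fy <- g$ky / (box * pixel_size)
  f2 <- fx^2 + fy^2
  theta <- atan2(fy, fx)
  lambda <- electron_wavelength(p$voltage)
  df <- 0.5 * (p$defocus_u + p$defocus_v) +
    0.5 * (p$defocus_u - p$defocus_v) *
      cos(2 * (theta - p$astig_angle * pi / 180))
  chi <- pi * lambda * df * f2 -
    (pi / 2) * (p$cs * 1e7) * lambda^3 * f2^2 +
    p$phase_shift * pi / 180
  w <- p$amplitude_contrast
  -sqrt(1 - w^2) * sin(chi) - w * cos(chi)
}

#' Apply (or phase-flip against) a CTF in Fourier space
#'
#' Multiplies the centred image transform by `ctf_2d(p, ...)`, by its
#' absolute value (`sign_flipped = TRUE`, i.e. the modulation left
#' after phase flipping), or by its sign only (`mode = "flip"`, the
#' phase-flip correction itself).
#'
#' @param img square numeric matrix.
#' @param p an [ctf_params()] set.
#' @param pixel_size pixel size in Angstrom.
#' @param sign_flipped multiply by `|CTF|` instead of `CTF`.
#' @param mode `"apply"` (default, honours `sign_flipped`) or `"flip"`
#'   (multiply by `sign(CTF)` to correct phases of an already
#'   CTF-affected image).
#' @return Filtered real image.
#' @export
apply_ctf <- function(img, p, pixel_size, sign_flipped = FALSE,
                      mode = c("apply", "flip")) {
  mode <- match.arg(mode)
  if (nrow(img) != ncol(img)) stop("shape error: image must be square")
  ctf <- ctf_2d(p, nrow(img), pixel_size)
  filt <- switch(mode,
                 apply = if (sign_flipped) abs(ctf) else ctf,
                 flip = sign(ctf))
  Re(fft2c(fft2c(img) * filt, inverse = TRUE))
}

# Batched version over an fx_stack with per-record parameters.
# mode "wiener" divides out the CTF with the regularised inverse
# C/(C^2 + k), the standard single-image CTF correction used before
# matching against unmodulated reference projections.
apply_ctf_stack <- function(stack, table, mode = c("apply", "flip",
                                                   "wiener"),
                            sign_flipped = FALSE, wiener_k = 0.2) {
  mode <- match.arg(mode)
  n <- dim(stack$data)[1]
  f <- batch_fft2(stack$data)
  for (i in seq_len(n_images(stack))) {
    ctf <- ctf_2d(ctf_from_record(table, i), n, stack$pixel_size)
    f[, , i] <- f[, , i] * switch(mode,
                                  apply = if (sign_flipped) abs(ctf)
                                          else ctf,
                                  flip = sign(ctf),
                                  wiener = ctf / (ctf^2 + wiener_k))
  }
  fx_stack(Re(batch_fft2(f, inverse = TRUE)), stack$pixel_size)
}

#' Adjust defocus for a depth offset along the beam axis
#'
#' Recentering a sub-particle moves its effective centre along z; the
#' defocus of the sub-particle differs from the whole-particle value by
#' that depth. By default +z (towards the source in the projection
#' frame) increases defocus; `z_sign = -1` inverts the convention.
#'
#' @param p an [ctf_params()] set.
#' @param z_offset_px depth offset in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param z_sign +1 (default) or -1.
#' @return Updated [ctf_params()] with both defoci shifted by
#'   `z_sign * z_offset_px * pixel_size` Angstrom.
#' @export
adjust_defocus_for_z <- function(p, z_offset_px, pixel_size,
                                 z_sign = 1) {
  dz <- z_sign * z_offset_px * pixel_size
  p$defocus_u <- p$defocus_u + dz
  p$defocus_v <- p$defocus_v + dz
  p
}
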