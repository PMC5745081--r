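# Lightweight S3 containers. Volumes and stacks carry their pixel size;
# single images are plain matrices and take a pixel size argument where
# physics needs one.

#' Cubic volume container
#'
#' Wraps an `N x N x N` numeric array together with its pixel size.
#' `N` must be even; the coordinate origin sits at 0-based voxel
#' `N/2` along every axis (the FFT-centre convention). Axis order is
#' `[x, y, z]` with z the slowest (section) axis, as in MRC2014.
#'
#' @param grid numeric 3D array, cubic with even side.
#' @param pixel_size voxel edge in Angstrom (> 0).
#' @return An object of class `fx_volume` with elements `grid` and
#'   `pixel_size`.
#' @export
fx_volume <- function(grid, pixel_size = 1) {
  d <- dim(grid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("shape error: volume grid must be cubic")
  if (d[1] %% 2 != 0) stop("shape error: volume side must be even")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "fx_volume")
}

#' Image stack container
#'
#' Wraps an `N x N x K` numeric array of K square images plus the pixel
#' size. Slice `k` corresponds to `image_index == k` of the matching
#' particle table. A single `N x N` matrix is promoted to a stack of
#' one.
#'
#' @param data numeric array `N x N x K` (or an `N x N` matrix).
#' @param pixel_size pixel edge in Angstrom (> 0).
#' @return An object of class `fx_stack` with elements `data` and
#'   `pixel_size`.
#' @export
fx_stack <- function(data, pixel_size = 1) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (length(d) != 3 || d[1] != d[2])
    stop("shape error: stack images must be square")
  if (d[1] %% 2 != 0) stop("shape error: image side must be even")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(data = data, pixel_size = pixel_size),
            class = "fx_stack")
}

#' @export
print.fx_volume <- function(x, ...) {
  cat(sprintf("<fx_volume %d^3, %.4g A/px>\n", dim(x$grid)[1],
              x$pixel_size))
  invisible(x)
}

#' @export
print.fx_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fx_stack %d images of %d^2, %.4g A/px>\n", d[3], d[1],
              x$pixel_size))
  invisible(x)
}

n_images <- function(stack) dim(stack$data)[3]

particle_columns <- c(
  "image_index", "micrograph_id", "rot", "tilt", "psi",
  "origin_x", "origin_y", "defocus_u", "defocus_v", "astig_angle",
  "voltage", "cs", "amplitude_contrast", "phase_shift", "pixel_size")

#' Construct a particle metadata table
#'
#' Builds the canonical per-particle table used throughout the package:
#' ZYZ Euler angles in degrees, in-plane origin shifts in pixels
#' (content of the image is displaced by +origin relative to the
#' reference projection), and CTF parameters. Unrecognised columns are
#' carried through all operations untouched.
#'
#' @param n number of particles, or a data frame to validate/complete.
#' @param pixel_size pixel size in Angstrom shared by all records.
#' @param ... per-particle values recycled to length `n` (any of
#'   `rot`, `tilt`, `psi`, `origin_x`, `origin_y`, `defocus_u`,
#'   `defocus_v`, `astig_angle`, `voltage`, `cs`,
#'   `amplitude_contrast`, `phase_shift`, `micrograph_id`).
#' @return A `data.frame` with class `fx_particles`.
#' @export
particle_table <- function(n, pixel_size = 1, ...) {
  if (is.data.frame(n)) {
    tab <- n
  } else {
    tab <- data.frame(image_index = seq_len(n))
  }
  dots <- list(...)
  defaults <- list(
    micrograph_id = "mic_1", rot = 0, tilt = 0, psi = 0,
    origin_x = 0, origin_y = 0, defocus_u = 20000, defocus_v = 20000,
    astig_angle = 0, voltage = 300, cs = 2.0, amplitude_contrast = 0.07,
    phase_shift = 0, pixel_size = pixel_size)
  if (is.null(tab$image_index)) tab$image_index <- seq_len(nrow(tab))
  for (nm in names(defaults)) {
    val <- if (!is.null(dots[[nm]])) dots[[nm]] else
      if (!is.null(tab[[nm]])) tab[[nm]] else defaults[[nm]]
    tab[[nm]] <- rep_len(val, nrow(tab))
  }
  validate_particles(tab)
}

validate_particles <- function(tab) {
  for (nm in particle_columns)
    if (is.null(tab[[nm]])) stop("format error: missing column ", nm)
  num <- setdiff(particle_columns, "micrograph_id")
  for (nm in num)
    if (!is.numeric(tab[[nm]]))
      stop("parse error: non-numeric values in ", nm)
  if (any(tab$tilt < 0 | tab$tilt > 180))
    stop("tilt must lie in [0, 180]")
  if (any(tab$pixel_size <= 0)) stop("pixel_size must be > 0")
  if (length(unique(tab$pixel_size)) > 1)
    stop("all records must share one pixel_size")
  if (any(tab$defocus_u < 0 | tab$defocus_v < 0))
    stop("defocus must be >= 0")
  tab$rot <- wrap_angle(tab$rot)
  tab$psi <- wrap_angle(tab$psi)
  if (anyDuplicated(tab[c("micrograph_id", "image_index")]))
    stop("image_index must be unique per micrograph")
  class(tab) <- unique(c("fx_particles", class(tab)))
  tab
}

#' Reduce angles to the canonical [-180, 180) interval
#'
#' @param a angles in degrees.
#' @return Angles wrapped into `[-180, 180)`.
#' @export
wrap_angle <- function(a) ((a + 180) %% 360) - 180
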