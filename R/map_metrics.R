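# Map-quality and model/map-correspondence metrics: Fourier shell
# correlation with threshold-crossing resolution, global and per-voxel
# local Pearson correlation, B-factor sharpening, low-pass filtering
# and MTF division. Shells are one Fourier voxel wide.

shell_index <- function(n) {
  k <- seq_len(n) - 1 - n / 2
  k2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  round(sqrt(k2))
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalised complex correlation
#' `Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` with shells one
#' Fourier voxel wide.
#'
#' @param map1,map2 [fx_volume()] objects on the same grid.
#' @param mask optional real-space mask ([fx_volume()] or array)
#'   applied to both maps first.
#' @return A `data.frame` of class `fx_fsc` with columns `shell`,
#'   `freq` (1/Angstrom), `fsc`, `n_voxels`.
#' @export
fsc <- function(map1, map2, mask = NULL) {
  stopifnot(inherits(map1, "fx_volume"), inherits(map2, "fx_volume"))
  if (!identical(dim(map1$grid), dim(map2$grid)) ||
      map1$pixel_size != map2$pixel_size)
    stop("grid mismatch: maps differ in box or pixel size")
  g1 <- map1$grid
  g2 <- map2$grid
  if (!is.null(mask)) {
    m <- if (inherits(mask, "fx_volume")) mask$grid else mask
    g1 <- g1 * m
    g2 <- g2 * m
  }
  n <- dim(g1)[1]
  f1 <- fft3c(g1)
  f2 <- fft3c(g2)
  sh <- shell_index(n)
  shells <- 1:(n / 2 - 1)
  num <- rep(0, length(shells))
  d1 <- num
  d2 <- num
  cnt <- num
  idx <- factor(sh, levels = shells)
  keep <- !is.na(idx)
  num <- tapply(Re(f1 * Conj(f2))[keep], idx[keep], sum)
  d1 <- tapply(abs(f1[keep])^2, idx[keep], sum)
  d2 <- tapply(abs(f2[keep])^2, idx[keep], sum)
  cnt <- tapply(rep(1, sum(keep)), idx[keep], sum)
  val <- as.numeric(num) / sqrt(as.numeric(d1) * as.numeric(d2))
  val[!is.finite(val)] <- 0
  out <- data.frame(shell = shells,
                    freq = shells / (n * map1$pixel_size),
                    fsc = val, n_voxels = as.numeric(cnt))
  attr(out, "pixel_size") <- map1$pixel_size
  class(out) <- c("fx_fsc", class(out))
  out
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first crossing below `threshold`, linearly
#' interpolated between shells; a curve that never crosses reports the
#' Nyquist resolution `2 * pixel`.
#'
#' @param curve an `fx_fsc` from [fsc()].
#' @param threshold FSC criterion (0.143 by default; 0.5 is the other
#'   common choice).
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$fsc
  below <- which(f < threshold)
  nyq <- if (!is.null(attr(curve, "pixel_size")))
    2 * attr(curve, "pixel_size") else 1 / max(curve$freq)
  if (!length(below)) return(nyq)
  i <- below[1]
  if (i == 1) return(1 / curve$freq[1])
  f0 <- f[i - 1]
  f1 <- f[i]
  frac <- (f0 - threshold) / (f0 - f1)
  1 / (curve$freq[i - 1] + frac * (curve$freq[i] - curve$freq[i - 1]))
}

#' Global Pearson correlation between two maps
#'
#' @param mapA,mapB [fx_volume()] objects on the same grid.
#' @param mask optional mask; only voxels with mask > 0.5 enter.
#' @return Pearson correlation coefficient.
#' @export
global_cc <- function(mapA, mapB, mask = NULL) {
  stopifnot(inherits(mapA, "fx_volume"), inherits(mapB, "fx_volume"))
  if (!identical(dim(mapA$grid), dim(mapB$grid)))
    stop("grid mismatch")
  a <- as.numeric(mapA$grid)
  b <- as.numeric(mapB$grid)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "fx_volume")) mask$grid else mask
    sel <- as.numeric(m) > 0.5
    a <- a[sel]
    b <- b[sel]
  }
  if (sd(a) < 1e-15 || sd(b) < 1e-15)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' Per-voxel local cross-correlation between two maps
#'
#' Pearson correlation inside a cubic window centred at every voxel.
#' Voxels whose window lacks variance in either map get value 0 and
#' flag 0.
#'
#' @param mapA,mapB [fx_volume()] objects on the same grid.
#' @param window_px odd window side >= 3.
#' @return `list(cc, flag)`: an [fx_volume()] of correlations and a
#'   0/1 array marking informative voxels.
#' @export
local_cc <- function(mapA, mapB, window_px = 5) {
  stopifnot(inherits(mapA, "fx_volume"), inherits(mapB, "fx_volume"))
  if (!identical(dim(mapA$grid), dim(mapB$grid)))
    stop("grid mismatch")
  if (window_px %% 2 != 1 || window_px < 3)
    stop("window_px must be odd and >= 3")
  if (window_px > dim(mapA$grid)[1])
    stop("window larger than the grid")
  r <- cpp_local_cc(mapA$grid, mapB$grid, as.integer(window_px))
  list(cc = fx_volume(r$cc, mapA$pixel_size), flag = r$flag)
}

radial_freq3 <- function(n, pixel_size) {
  sh <- shell_index(n)
  sh / (n * pixel_size)
}

#' B-factor sharpening / damping
#'
#' Multiplies the Fourier amplitudes by `exp(-b s^2 / 4)` with s the
#' spatial frequency in 1/Angstrom; negative b sharpens.
#'
#' @param map an [fx_volume()].
#' @param b B factor in Angstrom^2 (e.g. -250 to sharpen).
#' @return Filtered [fx_volume()].
#' @export
sharpen_bfactor <- function(map, b) {
  stopifnot(inherits(map, "fx_volume"))
  if (b == 0) return(map)
  n <- dim(map$grid)[1]
  s <- radial_freq3(n, map$pixel_size)
  f <- fft3c(map$grid) * exp(-b * s^2 / 4)
  fx_volume(Re(fft3c(f, inverse = TRUE)), map$pixel_size)
}

#' Low-pass filter with a raised-cosine edge
#'
#' Unit gain below the cutoff, raised-cosine roll-off over two Fourier
#' shells, zero beyond.
#'
#' @param map an [fx_volume()].
#' @param cutoff_A cutoff resolution in Angstrom.
#' @return Filtered [fx_volume()].
#' @export
lowpass <- function(map, cutoff_A) {
  stopifnot(inherits(map, "fx_volume"))
  n <- dim(map$grid)[1]
  s <- radial_freq3(n, map$pixel_size)
  sc <- 1 / cutoff_A
  dw <- 2 / (n * map$pixel_size)        # two shells
  w <- ifelse(s <= sc, 1,
              ifelse(s >= sc + dw, 0,
                     0.5 * (1 + cos(pi * (s - sc) / dw))))
  f <- fft3c(map$grid) * w
  fx_volume(Re(fft3c(f, inverse = TRUE)), map$pixel_size)
}

#' Read a tabulated detector MTF curve
#'
#' Two whitespace-separated columns: spatial frequency as a fraction of
#' Nyquist in \[0, 1\], and MTF value.
#'
#' @param path text file.
#' @return `data.frame(freq_frac, mtf)`.
#' @export
read_mtf <- function(path) {
  tab <- utils::read.table(path, col.names = c("freq_frac", "mtf"))
  if (any(tab$freq_frac < 0 | tab$freq_frac > 1))
    stop("MTF frequencies must be fractions of Nyquist in [0, 1]")
  tab
}

#' Divide a map by the detector MTF
#'
#' Fourier amplitudes are divided by the MTF interpolated at each
#' voxel's frequency (as a fraction of Nyquist); the divisor is floored
#' to avoid noise amplification at vanishing MTF.
#'
#' @param map an [fx_volume()].
#' @param mtf a table from [read_mtf()].
#' @param floor smallest divisor allowed.
#' @return Corrected [fx_volume()].
#' @export
apply_mtf_correction <- function(map, mtf, floor = 0.05) {
  stopifnot(inherits(map, "fx_volume"))
  n <- dim(map$grid)[1]
  frac <- shell_index(n) / (n / 2)
  vals <- stats::approx(mtf$freq_frac, mtf$mtf, xout = pmin(frac, 1),
                        rule = 2)$y
  f <- fft3c(map$grid) / pmax(vals, floor)
  fx_volume(Re(fft3c(f, inverse = TRUE)), map$pixel_size)
}
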