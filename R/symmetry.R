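# Rotational-symmetry assessment of a top-view class average by
# eigenimage analysis: many randomly rotated copies are realigned
# translationally and decomposed into principal components; the
# angular harmonic content of the leading eigenimages reveals the
# cyclic order. A ring of n protomers puts its variance into cos/sin
# (n theta) modes, which survive the rotational scrambling while all
# non-harmonic structure averages out.

#' Produce randomly rotated copies of an image
#'
#' Rotation angles are drawn uniformly on \[0, 360) from a private
#' seeded generator; rotation is bilinear about the box centre.
#'
#' @param img square numeric matrix.
#' @param n_copies number of copies (>= 2).
#' @param seed integer seed; a fixed seed reproduces the stack
#'   bit-for-bit.
#' @return `list(stack, angles)`: `n x n x n_copies` array and the
#'   angles used.
#' @export
rotate_random_copies <- function(img, n_copies, seed = 1) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  angles <- with_seed(seed, runif(n_copies, 0, 360))
  n <- nrow(img)
  out <- array(0, c(n, n, n_copies))
  for (i in seq_len(n_copies)) out[, , i] <- cpp_rotate_image(img,
                                                              angles[i])
  list(stack = out, angles = angles)
}

#' Translationally align a stack to its running mean
#'
#' Each image is aligned to the current stack mean by the FFT
#' cross-correlation peak with parabolic sub-pixel interpolation, then
#' shifted by the negated peak; the procedure is repeated `n_iter`
#' times.
#'
#' @param stack `n x n x K` array (or an [fx_stack()]).
#' @param n_iter alignment iterations.
#' @param max_shift largest allowed shift in pixels.
#' @return `list(stack, shifts)` with the aligned array and the total
#'   applied shifts (K x 2).
#' @export
translational_align <- function(stack, n_iter = 2, max_shift = NULL) {
  if (inherits(stack, "fx_stack")) stack <- stack$data
  n <- dim(stack)[1]
  k <- dim(stack)[3]
  if (is.null(max_shift)) max_shift <- n / 4
  total <- matrix(0, k, 2)
  s <- shift_half(n)
  for (iter in seq_len(n_iter)) {
    ref <- apply(stack, c(1, 2), mean)
    fr <- Conj(fft(ref))
    for (i in seq_len(k)) {
      cc <- Re(fft(fft(stack[, , i]) * fr, inverse = TRUE))
      cc <- cc[s, s]                     # centre the zero-shift bin
      pk <- arrayInd(which.max(cc), dim(cc))
      dx <- pk[1] - 1 - n / 2
      dy <- pk[2] - 1 - n / 2
      # parabolic refinement around the integer peak
      if (pk[1] > 1 && pk[1] < n)
        dx <- dx + parabolic_offset(cc[pk[1] - 1, pk[2]],
                                    cc[pk[1], pk[2]],
                                    cc[pk[1] + 1, pk[2]])
      if (pk[2] > 1 && pk[2] < n)
        dy <- dy + parabolic_offset(cc[pk[1], pk[2] - 1],
                                    cc[pk[1], pk[2]],
                                    cc[pk[1], pk[2] + 1])
      dx <- max(-max_shift, min(max_shift, dx))
      dy <- max(-max_shift, min(max_shift, dy))
      if (abs(dx) > 1e-3 || abs(dy) > 1e-3)
        stack[, , i] <- shift_image(stack[, , i], -dx, -dy)
      total[i, ] <- total[i, ] + c(dx, dy)
    }
  }
  list(stack = stack, shifts = total)
}

#' Principal-component (eigenimage) decomposition of a stack
#'
#' Eigendecomposition of the image-image covariance of the
#' mean-subtracted stack; eigenimages are returned orthonormal with
#' eigenvalues in descending order.
#'
#' @param stack `n x n x K` array (or an [fx_stack()]).
#' @param n_components number of components (< K).
#' @return `list(eigenimages, eigenvalues)`: an
#'   `n x n x n_components` array and the corresponding variances.
#' @export
msa_eigenimages <- function(stack, n_components) {
  if (inherits(stack, "fx_stack")) stack <- stack$data
  n <- dim(stack)[1]
  k <- dim(stack)[3]
  if (n_components >= k)
    stop("n_components must be smaller than the number of images")
  X <- matrix(stack, n * n, k)
  X <- sweep(X, 1, rowMeans(X))
  C <- crossprod(X) / (k - 1)            # K x K
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values[seq_len(n_components)], 0)
  imgs <- array(0, c(n, n, n_components))
  for (e in seq_len(n_components)) {
    v <- X %*% eg$vectors[, e]
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-12) v <- v / nrm
    imgs[, , e] <- v
  }
  list(eigenimages = imgs, eigenvalues = vals)
}

#' Infer the cyclic symmetry order from eigenimages
#'
#' Each eigenimage is resampled on a polar grid about the box centre
#' (the inner 3 px are excluded), Fourier-transformed along the angle
#' at every radius, and its harmonic power averaged over radii with
#' weights proportional to the local angular variance. Per-eigenimage
#' spectra are combined with eigenvalue weights into an aggregate
#' `S(m)`, and the fundamental is the argmax over `m` of
#' `S(m) + comb_weight * S(2m)` (the comb-folding term credits the
#' first overtone to its fundamental). When the top score does not
#' exceed `confidence_threshold` times the median score — as for a
#' rotationally featureless input — the order is reported as 1.
#'
#' @param eigenimages `n x n x E` array (E >= 2).
#' @param eigenvalues length-E variances used as weights.
#' @param m_max largest candidate order.
#' @param n_eigen number of leading eigenimages to use.
#' @param comb_weight weight of the `S(2m)` folding term.
#' @param confidence_threshold minimum top/median score ratio for a
#'   finite order.
#' @param power_floor absolute variance below which an eigenimage is
#'   considered uninformative (e.g. the residual interpolation noise of
#'   a rotationally featureless input); fewer than 2 informative
#'   eigenimages yield order 1 with confidence 0.
#' @param n_ang angular samples of the polar grid.
#' @return A list of class `fx_symmetry_report`: `order`,
#'   `harmonic_power` (named vector over m = 2..m_max), `confidence`,
#'   `n_eigen_used`.
#' @export
detect_symmetry_order <- function(eigenimages, eigenvalues, m_max = 20,
                                  n_eigen = 10, comb_weight = 0.5,
                                  confidence_threshold = 3,
                                  power_floor = 0, n_ang = 256) {
  d <- dim(eigenimages)
  if (length(d) != 3 || d[3] < 2) stop("need at least 2 eigenimages")
  n <- d[1]
  e_use <- which(eigenvalues > pmax(1e-8 * max(sum(eigenvalues), 1e-300),
                                    power_floor))
  e_use <- head(e_use, n_eigen)
  empty_report <- function() {
    structure(list(order = 1L,
                   harmonic_power = setNames(rep(0, m_max - 1),
                                             2:m_max),
                   confidence = 0, n_eigen_used = length(e_use)),
              class = "fx_symmetry_report")
  }
  if (length(e_use) < 2) return(empty_report())

  m_hi <- min(2 * m_max, floor(n_ang / 2) - 1)
  S <- rep(0, m_hi)
  for (e in e_use) {
    pol <- cpp_polar_transform(eigenimages[, , e], n_ang, 3,
                               n / 2 - 2)
    F <- mvfft(pol)                      # FFT along the angle axis
    pw <- abs(F[seq_len(m_hi) + 1, , drop = FALSE])^2  # m = 1..m_hi
    w <- colSums(pw)                     # angular variance per radius
    w <- w * seq_len(ncol(pw))           # annulus area
    if (sum(w) <= 0) next
    P_e <- as.numeric(pw %*% w) / sum(w)
    tot <- sum(P_e)
    if (tot <= 0) next
    S <- S + eigenvalues[e] * P_e / tot
  }
  ms <- 2:m_max
  score <- S[ms] + comb_weight * ifelse(2 * ms <= m_hi, S[2 * ms], 0)
  names(score) <- ms
  best <- ms[which.max(score)]
  med <- median(score)
  confidence <- if (med > 0) max(score) / med else 0
  order <- if (confidence >= confidence_threshold) best else 1L
  structure(list(order = as.integer(order), harmonic_power = score,
                 confidence = confidence,
                 n_eigen_used = length(e_use)),
            class = "fx_symmetry_report")
}

#' Full randomized symmetry assessment of one top view
#'
#' Convenience pipeline mirroring the classical eigenimage recipe:
#' `n_copies` randomly rotated copies, translational realignment, one
#' round of principal-component analysis, and harmonic scoring of the
#' eigenimages.
#'
#' @param img square matrix (top-view class average).
#' @param n_copies rotated copies to draw (default 50).
#' @param seed RNG seed for the rotations.
#' @param n_components principal components to compute.
#' @param ... passed to [detect_symmetry_order()].
#' @return An `fx_symmetry_report` with `n_copies` and `seed` attached.
#' @export
assess_symmetry <- function(img, n_copies = 50, seed = 1,
                            n_components = 12, ...) {
  rc <- rotate_random_copies(img, n_copies, seed)
  al <- translational_align(rc$stack, n_iter = 2)
  msa <- msa_eigenimages(al$stack, min(n_components, n_copies - 1))
  tot_pow <- mean(apply(al$stack, 3, function(m) sum(m^2)))
  rep <- detect_symmetry_order(msa$eigenimages, msa$eigenvalues,
                               power_floor = 1e-4 * tot_pow, ...)
  rep$n_copies <- n_copies
  rep$seed <- seed
  rep
}

#' @export
print.fx_symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry report: order C%d, confidence %.2f, %d eigenimages>\n",
              x$order, x$confidence, x$n_eigen_used))
  invisible(x)
}
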