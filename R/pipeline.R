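# End-to-end workflow: simulate (or load) a flexible-particle dataset,
# consensus-align whole particles, subtract the tail module, recenter
# onto the cap module in a smaller box, realign locally against the
# cap reference, and score both stages against ground truth. All
# randomness flows from one root seed.

bin_factor_check <- function(n, f) {
  if (n %% f != 0) stop("box ", n, " not divisible by bin factor ", f)
}

# Block-average binning (sum-preserving mean) of a stack or volume.
bin_stack <- function(stack, f) {
  if (f == 1) return(stack)
  d <- dim(stack$data)
  bin_factor_check(d[1], f)
  n2 <- d[1] / f
  a <- array(stack$data, c(f, n2, f, n2, d[3]))
  out <- apply(a, c(2, 4, 5), mean)
  fx_stack(out, stack$pixel_size * f)
}

bin_volume <- function(vol, f) {
  if (f == 1) return(vol)
  n <- dim(vol$grid)[1]
  bin_factor_check(n, f)
  n2 <- n / f
  a <- array(vol$grid, c(f, n2, f, n2, f, n2))
  fx_volume(apply(a, c(2, 4, 6), mean), vol$pixel_size * f)
}

# Dataset-average |CTF| on the centred frequency grid of a given box.
mean_abs_ctf <- function(table, box, pixel_size) {
  acc <- matrix(0, box, box)
  k <- nrow(table)
  for (i in seq_len(k))
    acc <- acc + abs(ctf_2d(ctf_from_record(table, i), box, pixel_size))
  acc / k
}

#' Default pipeline configuration
#'
#' Stage parameters for [run_pipeline()], preset to the standard
#' flexible-phantom study: consensus matching of whole particles
#' (global 5 degree search on 2x-binned images, then two local rounds
#' down to a 1 degree step), tail subtraction, recentering of the cap
#' into a 48 px box, and two-round local cap alignment (coarse 4
#' degree sweep wide enough to catch the hinge rocking, then a 1
#' degree fine pass).
#'
#' @param seed root seed for all randomness.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  preset <- pilq_like_preset()
  list(
    seed = as.integer(seed),
    phantom = preset$spec,
    simulate = list(n = preset$n, snr = preset$snr,
                    defocus_range = preset$defocus_range,
                    shift_max = 5),
    consensus = list(bin = 2, global_step = 5, psi_step = 5,
                     shift_max = 2, shift_step = 1,
                     rounds = list(list(delta = 4, fine_step = 2,
                                        shift_max = 2, shift_step = 1),
                                   list(delta = 2, fine_step = 1,
                                        shift_max = 2, shift_step = 1))),
    subtract = list(threshold_frac = 0.08, extend_px = 1,
                    soft_edge_px = 2, scale_mode = "fixed"),
    recenter = list(new_box = 48, z_sign = 1, edge = "mean"),
    module_align = list(rounds = list(
      # hinge sweep: wide tilt/psi search for the rocking cap
      list(delta = c(4, 16, 16), fine_step = 4, shift_max = 4,
           shift_step = 2),
      # rot sweep over the full C13 asymmetric unit at 1 degree
      list(delta = c(14, 0, 0), fine_step = 1, shift_max = 2,
           shift_step = 1),
      # joint pass at 1 degree
      list(delta = c(3, 3, 3), fine_step = 1, shift_max = 2,
           shift_step = 1),
      # exact-projection fine pass with sub-pixel shifts
      list(delta = c(1.5, 1.5, 1.5), fine_step = 0.75, shift_max = 1,
           shift_step = 0.5, psi_mode = "project"))),
    symmetry = list(enabled = TRUE, n_copies = 50, m_max = 20),
    metrics = list(enabled = TRUE, window_px = 7, bfactor = -250,
                   fsc_threshold = 0.143))
}

validate_config <- function(config) {
  spec <- config$phantom
  if (!inherits(spec, "fx_phantom_spec"))
    stop("config$phantom must be an fx_phantom_spec")
  nb <- config$recenter$new_box
  if (nb %% 2 != 0 || nb > spec$box)
    stop("validation error: recenter box ", nb,
         " conflicts with phantom box ", spec$box)
  bin_factor_check(spec$box, config$consensus$bin)
  if (config$simulate$n < 1) stop("validation error: need n >= 1")
  invisible(TRUE)
}

run_local_rounds <- function(stack, reference, prior, rounds,
                             mask_radius = 0.45, ctf_table = NULL) {
  est <- prior
  for (r in rounds) {
    est <- assign_orientations(stack, reference,
                               local = list(prior_table = est,
                                            delta = r$delta,
                                            fine_step = r$fine_step,
                                            shift_max = r$shift_max,
                                            shift_step = r$shift_step,
                                            psi_mode = r$psi_mode,
                                            ctf_table = ctf_table),
                               mask_radius = mask_radius)
  }
  est
}

#' Run the full flexible-particle processing pipeline
#'
#' Stages: simulate -> consensus align -> subtract tail -> recenter cap
#' -> local cap alignment -> evaluate (plus optional symmetry check of
#' a top view and map-level metrics). Inputs on disk are never
#' mutated; when `outdir` is given, every stage writes its outputs and
#' a provenance JSON there.
#'
#' @param config list from [default_config()].
#' @param outdir optional output directory.
#' @param verbose print stage progress.
#' @return A list with the simulated data, per-stage tables, the
#'   consensus and module alignment summaries, the improvement factor,
#'   and (if enabled) the symmetry report and map metrics.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         verbose = TRUE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, obj) {
    if (is.null(outdir)) return(invisible(NULL))
    jsonlite::write_json(obj, file.path(outdir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  spec <- config$phantom
  sym <- spec$symmetry_order

  say("simulate: n=%d box=%d snr=%.3g", config$simulate$n, spec$box,
      config$simulate$snr)
  sim <- simulate_particles(spec, config$simulate$n,
                            config$simulate$snr,
                            config$simulate$defocus_range,
                            seed = config$seed,
                            shift_max = config$simulate$shift_max)
  truth_cap <- data.frame(rot = sim$truth$cap_rot,
                          tilt = sim$truth$cap_tilt,
                          psi = sim$truth$cap_psi)
  truth_whole <- sim$truth[c("rot", "tilt", "psi")]

  # ---- consensus alignment of whole particles (phase-flipped, binned)
  cc <- config$consensus
  say("consensus: global %g deg (C%d), %d-fold binned",
      cc$global_step, sym, cc$bin)
  pf <- apply_ctf_stack(sim$stack, sim$table, mode = "flip")
  pfb <- bin_stack(pf, cc$bin)
  nb <- dim(pfb$data)[1]
  refb <- bin_volume(sim$phantom$full, cc$bin)
  filt <- mean_abs_ctf(sim$table, nb, pfb$pixel_size)
  lib <- build_library(refb, cc$global_step, symmetry = sym,
                       psi_step = cc$psi_step)
  glob <- assign_orientations(pfb, lib, shift_max = cc$shift_max,
                              shift_step = cc$shift_step,
                              filter2d = filt, n_hypotheses = 2)
  say("consensus: local rounds (two hypotheses)")
  ali_cols <- c("rot", "tilt", "psi", "origin_x", "origin_y", "fa_cc")
  consA <- run_local_rounds(pfb, refb, glob, cc$rounds,
                            ctf_table = sim$table)
  globB <- glob
  for (nm in ali_cols) globB[[nm]] <- glob[[paste0("alt_", nm)]]
  consB <- run_local_rounds(pfb, refb, globB, cc$rounds,
                            ctf_table = sim$table)
  # decide between the two refined hypotheses at full resolution
  to_full <- function(est) {
    t_full <- sim$table
    t_full$rot <- est$rot; t_full$tilt <- est$tilt; t_full$psi <- est$psi
    t_full$origin_x <- est$origin_x * cc$bin
    t_full$origin_y <- est$origin_y * cc$bin
    t_full
  }
  # one equalising local round at full resolution per hypothesis, so
  # that the flip decision below compares equally-converged optima
  say("consensus: full-resolution refinement of both hypotheses")
  full_round <- list(list(delta = c(3, 3, 3), fine_step = 1.5,
                          shift_max = 2, shift_step = 1))
  consA_f <- run_local_rounds(pf, sim$phantom$full, to_full(consA),
                              full_round, ctf_table = sim$table)
  consB_f <- run_local_rounds(pf, sim$phantom$full, to_full(consB),
                              full_round, ctf_table = sim$table)
  scA <- consA_f$fa_cc
  scB <- consB_f$fa_cc
  swap <- scB > scA
  ali_full <- c("rot", "tilt", "psi", "origin_x", "origin_y")
  cons <- consA_f
  cons[swap, ali_full] <- consB_f[swap, ali_full]
  cons$fa_cc <- pmax(scA, scB)
  cons_alt <- consB_f
  cons_alt[swap, ali_full] <- consA_f[swap, ali_full]
  cons_alt$fa_cc <- pmin(scA, scB)
  say("consensus: alternative hypothesis won for %d of %d particles",
      sum(swap), length(swap))

  eval_whole <- evaluate_alignment(truth_whole, cons, symmetry = sym)
  eval_cap_consensus <- evaluate_alignment(truth_cap, cons,
                                           symmetry = sym)
  say("consensus: whole-particle median %.2f deg; cap median %.2f deg",
      eval_whole$median_deg, eval_cap_consensus$median_deg)

  # ---- downstream module processing: residual signal subtraction of
  # the tail, recentering onto the cap centroid, local cap alignment.
  # Both consensus hypotheses are carried through and the winner is
  # chosen per particle by the cap-stage score, mirroring the
  # classification step that follows subtraction in practice.
  sb <- config$subtract
  rc <- config$recenter
  cap_vol <- sim$phantom$cap
  keep <- make_soft_mask(cap_vol,
                         threshold = sb$threshold_frac *
                           max(cap_vol$grid),
                         extend_px = sb$extend_px,
                         soft_edge_px = sb$soft_edge_px)
  c_cap <- module_centers_from_mask(cap_vol)
  cap_ref <- recenter_volume(cap_vol, c_cap, rc$new_box)
  say("subtract+recenter: cap centroid (%.1f, %.1f, %.1f), box %d",
      c_cap[1], c_cap[2], c_cap[3], rc$new_box)

  downstream <- function(cons_tab) {
    subres <- subtract_signal(sim$stack, cons_tab, sim$phantom$full,
                              keep, scale_mode = sb$scale_mode)
    rec <- recenter_stack(subres$stack, subres$table,
                          recenter_spec(c_cap, rc$new_box),
                          z_sign = rc$z_sign, edge = rc$edge)
    rec_pf <- apply_ctf_stack(rec$stack, rec$table, mode = "flip")
    est <- run_local_rounds(rec_pf, cap_ref, rec$table,
                            config$module_align$rounds,
                            ctf_table = rec$table)
    list(subres = subres, rec = rec, est = est)
  }
  say("module align: subtract, recenter, local rounds")
  dsA <- downstream(cons)
  est_cap <- dsA$est
  rec <- dsA$rec

  truth_kept <- truth_cap[est_cap$image_index, , drop = FALSE]
  eval_cap <- evaluate_alignment(truth_kept, est_cap, symmetry = sym)
  say("module align: cap median %.2f deg (consensus gave %.2f)",
      eval_cap$median_deg, eval_cap_consensus$median_deg)

  out <- list(
    config = config, sim = sim, consensus_table = cons,
    subtracted = dsA$subres, recentered = rec, cap_table = est_cap,
    eval_whole = eval_whole, eval_cap_consensus = eval_cap_consensus,
    eval_cap = eval_cap,
    improvement_factor = eval_cap_consensus$median_deg /
      eval_cap$median_deg)

  if (isTRUE(config$symmetry$enabled)) {
    top <- project_volume(sim$phantom$full, c(0, 0, 0))
    out$symmetry <- assess_symmetry(top,
                                    n_copies = config$symmetry$n_copies,
                                    seed = config$seed,
                                    m_max = config$symmetry$m_max)
    say("symmetry: order C%d (confidence %.1f)", out$symmetry$order,
        out$symmetry$confidence)
  }

  if (isTRUE(config$metrics$enabled)) {
    # CTF-correct (regularised inverse) before Fourier-slice insertion
    rec_w <- apply_ctf_stack(rec$stack, rec$table, mode = "wiener")
    recon <- reconstruct(rec_w, est_cap)
    curve <- fsc(recon, cap_ref)
    res_map <- resolution_at(curve, config$metrics$fsc_threshold)
    # map/model correspondence at the nominal resolution: both maps
    # low-passed to the FSC crossing, correlated over the reference
    # support
    supp <- cap_ref$grid > 0.05 * max(cap_ref$grid)
    cc_map <- global_cc(lowpass(recon, res_map),
                        lowpass(cap_ref, res_map), supp)
    out$map <- list(
      reconstruction = recon,
      fsc = curve,
      resolution = res_map,
      global_cc = cc_map,
      local_cc = local_cc(lowpass(recon, res_map),
                          lowpass(cap_ref, res_map),
                          config$metrics$window_px),
      sharpened = sharpen_bfactor(recon, config$metrics$bfactor))
    say("metrics: FSC %.3g threshold crossing at %.1f A, CC %.3f",
        config$metrics$fsc_threshold, out$map$resolution,
        out$map$global_cc)
  }
  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(outdir)) {
    write_star(cons, file.path(outdir, "consensus.star"))
    write_star(est_cap, file.path(outdir, "cap_aligned.star"))
    write_stack(rec$stack, file.path(outdir, "cap_particles.mrcs"))
    if (!is.null(out$map))
      write_volume(out$map$reconstruction,
                   file.path(outdir, "cap_reconstruction.mrc"))
    emit("report", list(
      seed = config$seed, n = config$simulate$n,
      consensus_whole_median_deg = eval_whole$median_deg,
      consensus_cap_median_deg = eval_cap_consensus$median_deg,
      module_cap_median_deg = eval_cap$median_deg,
      improvement_factor = out$improvement_factor,
      symmetry_order = if (!is.null(out$symmetry))
        out$symmetry$order else NULL,
      map_cc = if (!is.null(out$map)) out$map$global_cc else NULL,
      elapsed_s = out$elapsed_s))
  }
  out
}
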