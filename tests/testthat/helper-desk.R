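# Desk-scale study conditions shared by the acceptance tests: 64x64
# matrix, 30 heartbeats, 4 coils, 21 golden-angle spokes per frame
# (~4.8-fold undersampling), 5 px peak respiratory displacement at
# 0.3 Hz, 2% k-space noise.  Heavy products are cached across blocks.

desk_phantom <- function() fixture("desk_phantom", {
  make_phantom(phantom_spec(matrix_size = 64, n_frames = 30, n_coils = 4,
                            spokes_per_frame = 21, samples_per_spoke = 128,
                            motion_amplitude_px = 5, resp_freq_hz = 0.3,
                            noise_fraction = 0.02, seed = 3))
})

desk_kspace <- function() fixture("desk_kspace", sample_kspace(desk_phantom()))

desk_zerofill <- function() fixture("desk_zerofill",
  zerofill_recon(desk_kspace(), desk_phantom()$coil_maps))

desk_itsense <- function() fixture("desk_itsense",
  itsense(desk_kspace(), desk_phantom()$coil_maps))

# Subspace for the simulation-parity studies: ground-truth-aligned
# series, fixed rank 8 (the full-scale protocol's reconstruction rank).
desk_subspace8 <- function() fixture("desk_subspace8", {
  ph <- desk_phantom()
  estimate_subspace(align_series(ph$truth_series, ph$motion),
                    roi = ph$roi, rank = 8)
})

# Fully estimated chain for the method-ordering comparison: ICA
# references from the itSENSE series, registered motion, estimated
# subspace, regularized LRMC.
desk_estimated <- function() fixture("desk_estimated", {
  ph <- desk_phantom()
  ks <- desk_kspace()
  X <- abs(desk_itsense())
  ica <- ica_references(X, n_components = 5, frame_rate_hz = 1, seed = 1)
  motion <- estimate_motion(X, ica$Xref)
  sub <- estimate_subspace(align_series(X, motion), roi = ph$roi)
  rec <- lrmc(ks, ph$coil_maps, motion, sub,
              admm = admm_config(), patch = patch_config())
  list(ica = ica, motion = motion, sub = sub, lrmc = rec)
})

desk_lps <- function() fixture("desk_lps",
  lps(desk_kspace(), desk_phantom()$coil_maps))

# Regularized LRMC with the ground-truth operators (solver-behavior
# reference, free of estimation error).
desk_lrmc_gt <- function() fixture("desk_lrmc_gt", {
  ph <- desk_phantom()
  sub <- estimate_subspace(align_series(ph$truth_series, ph$motion),
                           roi = ph$roi)
  lrmc(desk_kspace(), ph$coil_maps, ph$motion, sub,
       admm = admm_config(), patch = patch_config())
})
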