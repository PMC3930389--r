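# small homogeneous-tumor phantom used across tests
tiny_spec <- function(f_rim = 90, noise_sd = 0, n_repeats = 1L, seed = 1L,
                      ...) {
  phantom_spec(grid_shape = c(16, 12), rim_radius = 4, core_radius = 0,
               f_rim = f_rim, f_core = 0, noise_sd = noise_sd,
               n_repeats = n_repeats, seed = seed, ...)
}

# image_series holding one enhancement curve per voxel of a small grid;
# rows of `dsi_mat` are voxels, columns dynamics. Baseline level 100.
series_from_dsi <- function(dsi_mat, dt = 3.1) {
  nvox <- nrow(dsi_mat); nt <- ncol(dsi_mat)
  sh <- c(nvox, 1L)
  vol <- array(100 * (1 + t(dsi_mat)), dim = c(nt, nvox))
  vol <- aperm(array(vol, dim = c(nt, nvox, 1)), c(2, 3, 1))
  image_series(vol, "time_s", (seq_len(nt) - 1) * dt, 1L)
}

# full measurement chain on one phantom: returns the perfusion map
recover_flow <- function(spec, ir_noise_free = FALSE) {
  asl <- generate_asl_series(spec)
  ir_spec <- spec
  if (ir_noise_free) ir_spec$noise_sd <- 0
  ir <- generate_ir_series(ir_spec)
  t1f <- fit_ir_t1(ir, mask = asl$truth$tumor_mask)
  dm <- compute_delta_m(asl$control, asl$label)
  fit_perfusion(dm, t1f, roi_mask = asl$truth$tumor_mask)
}
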