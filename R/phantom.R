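#' Specification of the digital tumor phantom
#'
#' The phantom is a 2D slice holding a two-compartment tumor — a
#' well-perfused rim and a poorly perfused (necrotic) core — embedded in
#' background tissue, with an optional kidney-cortex disc as a high-flow
#' reference region. Each compartment carries its own ground-truth blood
#' flow, T1, and contrast-enhancement parameters, so that every analysis
#' stage can be validated against known truth.
#'
#' @param grid_shape integer vector `c(nx, ny)` (default matches a 64 x 48
#'   EPI matrix).
#' @param pixel_size_mm in-plane pixel size, mm.
#' @param center tumor center in voxel coordinates (1-based; default grid
#'   center).
#' @param rim_radius,core_radius tumor and necrotic-core radii, voxels.
#' @param f_rim,f_core blood flow in rim and core, mL/100 g/min.
#' @param t1_rim,t1_core,t1_background tissue T1 per compartment, ms.
#' @param m0_scale equilibrium signal level (arbitrary units).
#' @param noise_sd per-frame Gaussian noise SD as a fraction of `m0_scale`.
#' @param n_repeats ASL repeat count (40 measurements by default).
#' @param kidney optional `list(center =, radius =, f =, t1 =)` adding a
#'   kidney-cortex disc; `NULL` for none.
#' @param dce enhancement-curve parameters per compartment:
#'   `amp_rim`, `amp_core` (peak fractional enhancement), `onset_delay_s`
#'   (voxel arrival delay after the bolus; the default of half a 3.1 s
#'   dynamic places the onset between samples, so the first dynamic after
#'   onset is the first to carry enhancement), `ttp_rim_s`, `ttp_core_s`
#'   (time from onset to peak), `shape` (gamma-variate exponent).
#' @param seed integer seed controlling all stochastic draws; sub-streams for
#'   the individual series are derived from it deterministically.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 48), pixel_size_mm = 0.44,
                         center = NULL, rim_radius = 12, core_radius = 5,
                         f_rim = 90, f_core = 10,
                         t1_rim = 1600, t1_core = 1400, t1_background = 1500,
                         m0_scale = 1000, noise_sd = 0.02, n_repeats = 40L,
                         kidney = NULL,
                         dce = list(amp_rim = 1.5, amp_core = 0.4,
                                    onset_delay_s = 1.55,
                                    ttp_rim_s = 25, ttp_core_s = 60,
                                    shape = 3),
                         seed = 1L) {
  if (is.null(center)) center <- round(grid_shape / 2)
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), pixel_size_mm = pixel_size_mm,
         center = center, rim_radius = rim_radius, core_radius = core_radius,
         f_rim = f_rim, f_core = f_core,
         t1_rim = t1_rim, t1_core = t1_core, t1_background = t1_background,
         m0_scale = m0_scale, noise_sd = noise_sd,
         n_repeats = as.integer(n_repeats),
         kidney = kidney, dce = dce, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  for (fld in c("f_rim", "f_core"))
    if (spec[[fld]] < 0)
      stop(sprintf("phantom field `%s` must be >= 0 (got %g)",
                   fld, spec[[fld]]), call. = FALSE)
  for (fld in c("t1_rim", "t1_core", "t1_background"))
    if (spec[[fld]] <= 0)
      stop(sprintf("phantom field `%s` must be > 0 (got %g)",
                   fld, spec[[fld]]), call. = FALSE)
  if (spec$noise_sd < 0)
    stop("phantom field `noise_sd` must be >= 0", call. = FALSE)
  if (spec$n_repeats < 1L)
    stop("phantom field `n_repeats` must be >= 1", call. = FALSE)
  if (!is.null(spec$kidney) && spec$kidney$f < 0)
    stop("phantom field `kidney$f` must be >= 0", call. = FALSE)
  invisible(spec)
}

# deterministic sub-stream seeds (kept well below 2^31)
phantom_substream <- function(seed, stream) {
  (abs(seed) * 1009L + stream * 97L) %% 2147480000L
}

# radius <= 0 means an empty region, not a single point
disc_mask <- function(grid_shape, center, radius) {
  if (radius <= 0) return(matrix(FALSE, grid_shape[1], grid_shape[2]))
  x <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  y <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2],
              byrow = TRUE)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Ground-truth maps of a phantom
#'
#' Builds the per-voxel truth implied by a [phantom_spec()]: blood flow,
#' tissue T1, equilibrium signal, enhancement-curve parameters (amplitude,
#' onset seconds after acquisition start, time to peak, shape), and the
#' compartment masks. The enhancement onset is the bolus time plus the
#' spec's onset delay, so onset never precedes the injection.
#'
#' @param spec a [phantom_spec()].
#' @param bolus_time_s bolus injection time used for the DCE onset map, s.
#' @return a list of class `phantom_truth` with `f_map`, `t1_map`, `m0_map`,
#'   `dce_params` (list of maps `amplitude`, `onset_s`, `ttp_s`, `shape`),
#'   `tumor_mask`, `core_mask`, `kidney_mask`, `vessel_mask` (empty until
#'   [generate_vessel_mask()] fills it).
#' @export
phantom_truth <- function(spec, bolus_time_s = 15.5) {
  sh <- spec$grid_shape
  tumor <- disc_mask(sh, spec$center, spec$rim_radius)
  core <- disc_mask(sh, spec$center, spec$core_radius) & tumor
  kid <- if (!is.null(spec$kidney))
    disc_mask(sh, spec$kidney$center, spec$kidney$radius) & !tumor
  else matrix(FALSE, sh[1], sh[2])

  f <- matrix(0, sh[1], sh[2])
  f[tumor] <- spec$f_rim
  f[core] <- spec$f_core
  t1 <- matrix(spec$t1_background, sh[1], sh[2])
  t1[tumor] <- spec$t1_rim
  t1[core] <- spec$t1_core
  if (!is.null(spec$kidney)) {
    f[kid] <- spec$kidney$f
    t1[kid] <- spec$kidney$t1
  }
  m0 <- matrix(spec$m0_scale, sh[1], sh[2])

  amp <- matrix(0, sh[1], sh[2])
  amp[tumor] <- spec$dce$amp_rim
  amp[core] <- spec$dce$amp_core
  onset <- matrix(NA_real_, sh[1], sh[2])
  onset[amp > 0] <- bolus_time_s + spec$dce$onset_delay_s
  ttp <- matrix(NA_real_, sh[1], sh[2])
  ttp[tumor] <- spec$dce$ttp_rim_s
  ttp[core] <- spec$dce$ttp_core_s

  structure(
    list(f_map = f, t1_map = t1, m0_map = m0,
         dce_params = list(amplitude = amp, onset_s = onset, ttp_s = ttp,
                           shape = spec$dce$shape),
         tumor_mask = tumor, core_mask = core, kidney_mask = kid,
         vessel_mask = matrix(FALSE, sh[1], sh[2])),
    class = "phantom_truth")
}

#' Simulate a multi-TI FAIR control/label acquisition
#'
#' The nonselective (control) series follows signed inversion recovery with
#' the tissue T1; the slice-selective (label) series adds the noise-free FAIR
#' kinetic difference signal computed from the truth flow and apparent T1.
#' Independent Gaussian noise of SD `noise_sd * m0_scale / sqrt(2)` is added
#' to every frame of each series, so the per-repeat label-minus-control
#' difference carries noise of SD exactly `noise_sd * m0_scale`.
#'
#' @param spec a [phantom_spec()].
#' @param ti_ms inversion times, ms.
#' @param consts an [asl_constants()] used for the forward model.
#' @return `list(control =, label =, truth =)`, the series being
#'   [image_series()] with one frame per (TI, repeat).
#' @export
generate_asl_series <- function(spec,
                                ti_ms = c(100, 350, 750, 1500, 2500, 4000),
                                consts = asl_constants()) {
  validate_phantom_spec(spec)
  truth <- phantom_truth(spec)
  sh <- spec$grid_shape
  nti <- length(ti_ms)
  nrep <- spec$n_repeats
  t1app <- t1app_from_t1(truth$t1_map, truth$f_map, consts$lambda_part)

  ctrl_clean <- lab_clean <- array(0, dim = c(sh, nti))
  for (j in seq_len(nti)) {
    base <- ir_signal(truth$m0_map, truth$t1_map, 1, ti_ms[j])
    dm <- fair_delta_m_model(truth$f_map, truth$m0_map, t1app, consts,
                             ti_ms[j])
    ctrl_clean[, , j] <- base
    lab_clean[, , j] <- base + dm
  }

  old <- set_local_seed(phantom_substream(spec$seed, 1L))
  on.exit(restore_seed(old), add = TRUE)
  sd_frame <- spec$noise_sd * spec$m0_scale / sqrt(2)
  nfr <- nti * nrep
  ctrl <- array(rep(ctrl_clean, nrep), dim = c(sh, nfr))
  lab <- array(rep(lab_clean, nrep), dim = c(sh, nfr))
  if (sd_frame > 0) {
    ctrl <- ctrl + array(stats::rnorm(length(ctrl), 0, sd_frame), dim(ctrl))
    lab <- lab + array(stats::rnorm(length(lab), 0, sd_frame), dim(lab))
  }
  list(
    control = image_series(ctrl, "ti_ms", ti_ms, nrep, spec$pixel_size_mm),
    label = image_series(lab, "ti_ms", ti_ms, nrep, spec$pixel_size_mm),
    truth = truth)
}

#' Simulate an inversion-recovery T1-mapping acquisition
#'
#' Per voxel the signal is the magnitude of
#' `M0 * (1 - 2 exp(-TI / T1app)) + noise`, where the apparent T1 derives
#' from the truth flow and T1 (the series emulates the slice-selective
#' acquisition at the ASL slice, whose recovery constant is T1app). The noise
#' SD is `noise_sd * m0_scale / sqrt(2)`, reflecting the two averages of the
#' T1-mapping protocol.
#'
#' @param spec a [phantom_spec()].
#' @param ti_ms strictly increasing positive inversion times, ms.
#' @param consts an [asl_constants()].
#' @return an [image_series()] with a `ti_ms` axis.
#' @export
generate_ir_series <- function(spec,
                               ti_ms = c(10, 100, 500, 1000, 2000, 5000, 8000),
                               consts = asl_constants()) {
  validate_phantom_spec(spec)
  if (length(ti_ms) == 0L) stop("`ti_ms` must be non-empty", call. = FALSE)
  if (any(ti_ms <= 0) || is.unsorted(ti_ms, strictly = TRUE))
    stop("`ti_ms` must be strictly increasing and positive", call. = FALSE)
  truth <- phantom_truth(spec)
  t1app <- t1app_from_t1(truth$t1_map, truth$f_map, consts$lambda_part)
  sh <- spec$grid_shape
  old <- set_local_seed(phantom_substream(spec$seed, 2L))
  on.exit(restore_seed(old), add = TRUE)
  sd_frame <- spec$noise_sd * spec$m0_scale / sqrt(2)
  vol <- array(0, dim = c(sh, length(ti_ms)))
  for (j in seq_along(ti_ms)) {
    s <- ir_signal(truth$m0_map, t1app, 1, ti_ms[j])
    if (sd_frame > 0) s <- s + stats::rnorm(length(s), 0, sd_frame)
    vol[, , j] <- abs(s)
  }
  image_series(vol, "ti_ms", ti_ms, 1L, spec$pixel_size_mm)
}

#' Gamma-variate enhancement curve
#'
#' `dsi(t) = amp * u^shape * exp(shape * (1 - u))` with
#' `u = (t - onset) / ttp`, zero before onset; the peak value `amp` occurs at
#' `t = onset + ttp`.
#'
#' @param t time, s (vectorised).
#' @param amp peak fractional enhancement.
#' @param onset_s enhancement onset, s.
#' @param ttp_s time from onset to peak, s.
#' @param shape gamma-variate exponent (> 0).
#' @return fractional enhancement at `t`.
#' @export
gamma_variate <- function(t, amp, onset_s, ttp_s, shape = 3) {
  u <- (t - onset_s) / ttp_s
  out <- ifelse(u > 0, amp * u^shape * exp(shape * (1 - u)), 0)
  out
}

#' Closed-form partial integral of the gamma-variate curve
#'
#' Integral of [gamma_variate()] over `[onset_s, onset_s + window_s]`,
#' obtained from the regularized lower incomplete gamma function:
#' `amp * ttp * e^shape * shape^-(shape+1) * Gamma(shape+1) *
#' P(shape+1, shape * window/ttp)`. Used as the analytic oracle for the
#' trapezoidal AUC.
#'
#' @param amp,ttp_s,shape curve parameters as in [gamma_variate()].
#' @param window_s integration window from onset, s.
#' @return area in (fractional enhancement) x s.
#' @export
gamma_variate_auc <- function(amp, ttp_s, shape = 3, window_s) {
  a <- shape + 1
  amp * ttp_s * exp(shape) * shape^(-a) * gamma(a) *
    stats::pgamma(shape * window_s / ttp_s, a)
}

#' Simulate a DCE-MRI dynamic acquisition
#'
#' Per voxel `SI(t) = baseline * (1 + dsi_true(t)) + noise` with the
#' baseline equal to the truth `m0_map`, `dsi_true` a gamma-variate
#' enhancement curve with known onset, time to peak and analytically
#' integrable area, and Gaussian noise of SD `noise_sd * m0_scale`. Dynamic
#' `i` is acquired at `t = (i - 1) * dt` from the start of the acquisition;
#' the bolus is injected at dynamic `bolus_dynamic`.
#'
#' @param spec a [phantom_spec()].
#' @param n_dynamics number of dynamics (>= `bolus_dynamic + 2`).
#' @param dt temporal resolution, s per dynamic.
#' @param bolus_dynamic 1-based dynamic index of the bolus injection.
#' @return `list(dynamics = image_series, truth = phantom_truth)`.
#' @export
generate_dce_series <- function(spec, n_dynamics = 100L, dt = 3.1,
                                bolus_dynamic = 6L) {
  validate_phantom_spec(spec)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (n_dynamics < bolus_dynamic + 2L)
    stop("`n_dynamics` must be >= bolus_dynamic + 2", call. = FALSE)
  bolus_time <- (bolus_dynamic - 1) * dt
  truth <- phantom_truth(spec, bolus_time_s = bolus_time)
  sh <- spec$grid_shape
  times <- (seq_len(n_dynamics) - 1) * dt
  p <- truth$dce_params
  vol <- array(0, dim = c(sh, n_dynamics))
  enh <- p$amplitude > 0
  for (j in seq_len(n_dynamics)) {
    dsi <- matrix(0, sh[1], sh[2])
    dsi[enh] <- gamma_variate(times[j], p$amplitude[enh], p$onset_s[enh],
                              p$ttp_s[enh], p$shape)
    vol[, , j] <- truth$m0_map * (1 + dsi)
  }
  if (spec$noise_sd > 0) {
    old <- set_local_seed(phantom_substream(spec$seed, 3L))
    on.exit(restore_seed(old), add = TRUE)
    vol <- vol + array(
      stats::rnorm(length(vol), 0, spec$noise_sd * spec$m0_scale), dim(vol))
  }
  list(dynamics = image_series(vol, "time_s", times, 1L, spec$pixel_size_mm),
       truth = truth)
}

#' Place non-overlapping circular vessels inside the tumor
#'
#' Draws `n_vessels` discs of the given radius fully inside the tumor mask
#' with no overlap (so the mask has exactly `n_vessels` 8-connected
#' components). Placement is rejection sampling with a bounded retry budget.
#'
#' @param spec a [phantom_spec()].
#' @param n_vessels number of vessels to place.
#' @param vessel_radius vessel radius, voxels.
#' @param max_tries retry budget per vessel.
#' @return a logical matrix (the vessel mask).
#' @export
generate_vessel_mask <- function(spec, n_vessels, vessel_radius = 2,
                                 max_tries = 1000L) {
  validate_phantom_spec(spec)
  truth <- phantom_truth(spec)
  sh <- spec$grid_shape
  mask <- matrix(FALSE, sh[1], sh[2])
  if (n_vessels == 0L) return(mask)
  old <- set_local_seed(phantom_substream(spec$seed, 4L))
  on.exit(restore_seed(old), add = TRUE)
  # a vessel disc plus a 1-voxel moat must fit inside the tumor
  centers <- list()
  for (v in seq_len(n_vessels)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- spec$center[1] + stats::runif(1, -1, 1) * spec$rim_radius
      cy <- spec$center[2] + stats::runif(1, -1, 1) * spec$rim_radius
      d_tumor <- sqrt(sum((c(cx, cy) - spec$center)^2))
      if (d_tumor + vessel_radius + 1 > spec$rim_radius) next
      clear <- all(vapply(centers, function(cc)
        sqrt(sum((cc - c(cx, cy))^2)) > 2 * vessel_radius + 2, logical(1)))
      if (!clear) next
      centers[[length(centers) + 1L]] <- c(cx, cy)
      mask <- mask | disc_mask(sh, c(cx, cy), vessel_radius)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "could not place vessel %d of %d without overlap after %d tries",
        v, n_vessels, max_tries), call. = FALSE)
  }
  mask
}

# save/restore the global RNG state around seeded generation so phantom
# calls do not perturb a caller's random stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
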