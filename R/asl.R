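#' Constants for FAIR-ASL quantification
#'
#' Physiological and sequence constants entering the kinetic model:
#' the blood/tissue water partition coefficient lambda (mL/g), the
#' longitudinal relaxation time of arterial blood at 7 T (ms), the inversion
#' efficiency alpha, and the arterial transit time (fixed at 0; spin delivery
#' is treated as instantaneous for a thin imaging slice inside a much wider
#' inversion slab).
#'
#' @param lambda_part blood/tissue partition coefficient, mL/g.
#' @param t1a arterial blood T1, ms.
#' @param alpha inversion efficiency in (0, 1].
#' @param transit_time arterial transit time, ms (only 0 is supported).
#' @return a list of class `asl_constants`.
#' @export
asl_constants <- function(lambda_part = 0.9, t1a = 2210, alpha = 1,
                          transit_time = 0) {
  if (lambda_part <= 0) stop("`lambda_part` must be > 0", call. = FALSE)
  if (t1a <= 0) stop("`t1a` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (transit_time != 0)
    stop("nonzero `transit_time` is not supported", call. = FALSE)
  structure(list(lambda_part = lambda_part, t1a = t1a, alpha = alpha,
                 transit_time = transit_time),
            class = "asl_constants")
}

# f in mL/100 g/min -> f/lambda in 1/ms
flow_rate_per_ms <- function(f, lambda_part) f / (6000 * lambda_part) / 1000

#' Apparent longitudinal relaxation time under perfusion
#'
#' Inflowing blood water shortens the observed tissue relaxation:
#' 1/T1app = 1/T1 + f/lambda, with f converted from mL/100 g/min to 1/s
#' before dividing by lambda (mL/g).
#'
#' @param t1 tissue T1, ms. Vectorised.
#' @param f blood flow, mL/100 g/min.
#' @param lambda_part partition coefficient, mL/g.
#' @return T1app in ms.
#' @export
t1app_from_t1 <- function(t1, f, lambda_part = 0.9) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("`t1` must be > 0", call. = FALSE)
  1 / (1 / t1 + flow_rate_per_ms(f, lambda_part))
}

#' FAIR difference-signal kinetic model
#'
#' Noise-free control-minus-label magnetization difference at inversion time
#' `ti` for flow `f`, under the zero-transit-time solution of the general
#' kinetic model:
#' \deqn{\Delta M(TI) = 2 M_0 \alpha \frac{f}{\lambda}
#'   \frac{e^{-TI/T_{1app}} - e^{-TI/T_{1a}}}{1/T_{1a} - 1/T_{1app}}}
#' with the removable singularity at `t1app == t1a` evaluated by its limit
#' \eqn{2 M_0 \alpha (f/\lambda)\, TI\, e^{-TI/T_{1a}}}.
#'
#' All arguments are vectorised and recycled against each other.
#'
#' @param f blood flow, mL/100 g/min (>= 0).
#' @param m0 equilibrium magnetization per unit mass, signal units.
#' @param t1app apparent tissue T1, ms.
#' @param consts an [asl_constants()] object.
#' @param ti inversion time, ms (>= 0).
#' @return difference signal in the units of `m0`.
#' @export
fair_delta_m_model <- function(f, m0, t1app, consts = asl_constants(), ti) {
  if (any(ti < 0)) stop("`ti` must be >= 0", call. = FALSE)
  if (any(f < 0, na.rm = TRUE)) stop("`f` must be >= 0", call. = FALSE)
  r1a <- 1 / consts$t1a
  r1app <- 1 / t1app
  dr <- r1a - r1app
  pref <- 2 * m0 * consts$alpha * flow_rate_per_ms(f, consts$lambda_part)
  # relative rate difference below ~1e-9 treated as the degenerate limit
  n <- max(length(f), length(m0), length(t1app), length(ti), length(dr))
  dr <- rep_len(dr, n); r1app <- rep_len(r1app, n)
  pref <- rep_len(pref, n); ti <- rep_len(ti, n)
  out <- numeric(n)
  deg <- abs(dr) < r1a * 1e-9
  if (any(!deg))
    out[!deg] <- pref[!deg] *
      (exp(-ti[!deg] * r1app[!deg]) - exp(-ti[!deg] * r1a)) / dr[!deg]
  if (any(deg))
    out[deg] <- pref[deg] * ti[deg] * exp(-ti[deg] * r1a)
  out
}

#' Control/label difference signal per inversion time
#'
#' Averages repeats and subtracts: per TI, `delta_m = mean over repeats of
#' (label - control)`, where `label` is the slice-selective and `control` the
#' nonselective (global) inversion series, so that inflow of non-inverted
#' blood yields a positive difference.
#'
#' @param control nonselective-inversion [image_series()] with a `ti_ms` axis.
#' @param label slice-selective [image_series()] matching `control` in grid,
#'   TI list, and repeat count.
#' @return a list of class `delta_m_series`: `delta_m` (array
#'   `nx x ny x nTI`), `ti_ms`, `pixel_size_mm`.
#' @export
compute_delta_m <- function(control, label) {
  if (!inherits(control, "image_series") || !inherits(label, "image_series"))
    stop("`control` and `label` must be image_series objects", call. = FALSE)
  if (control$axis != "ti_ms" || label$axis != "ti_ms")
    stop("ASL series must carry a `ti_ms` axis", call. = FALSE)
  stopifnot_same_grid(control$data, label$data, "control/label series")
  if (!isTRUE(all.equal(control$values, label$values)))
    stop("control and label TI lists differ", call. = FALSE)
  if (control$repeats != label$repeats)
    stop(sprintf("repeat counts differ: %d vs %d",
                 control$repeats, label$repeats), call. = FALSE)
  ctrl <- average_repeats(control)
  lab <- average_repeats(label)
  structure(
    list(delta_m = lab$data - ctrl$data,
         ti_ms = control$values,
         pixel_size_mm = control$pixel_size_mm),
    class = "delta_m_series")
}

#' Voxel-wise perfusion fit from multi-TI difference signals
#'
#' With `m0` and `t1app` fixed per voxel from the T1-mapping fit, the FAIR
#' kinetic model is linear in the single free parameter f, so the
#' least-squares flow estimate is the exact projection
#' `f = sum(g * dm) / sum(g^2)` with `g(TI)` the model evaluated at unit
#' flow. Negative estimates are clamped at zero by default (bound-constrained
#' fit; tissue flow cannot be negative); `clamp_negative = FALSE` preserves
#' the sign for diagnostics.
#'
#' Voxels excluded by the T1-fit quality filter (`r2 <= r2_threshold`, strict
#' inequality for inclusion) or without a converged T1 fit are dropped from
#' the inclusion mask and from all ROI statistics.
#'
#' @param dm a `delta_m_series` from [compute_delta_m()].
#' @param t1fit a [t1_map_result()] on the same grid (its `t1_map` is the
#'   apparent T1 when fitted from the ASL-slice inversion-recovery series).
#' @param consts an [asl_constants()] object.
#' @param roi_mask optional logical matrix; ROI mean/SD/histogram restricted
#'   to it (default: whole grid).
#' @param r2_threshold T1-fit R-squared inclusion threshold (strict `>`).
#' @param clamp_negative clamp negative flow estimates at 0.
#' @param hist_breaks breaks passed to [hist()] for the ROI flow histogram.
#' @return a list of class `perfusion_map`: `f_map`, `residual_map` (SSE),
#'   `inclusion_mask`, `roi_mean`, `roi_sd`, `histogram`.
#' @export
fit_perfusion <- function(dm, t1fit, consts = asl_constants(),
                          roi_mask = NULL, r2_threshold = 0.9,
                          clamp_negative = TRUE, hist_breaks = 20) {
  if (!inherits(dm, "delta_m_series")) stop("`dm` must be a delta_m_series")
  if (!inherits(t1fit, "t1_map_result")) stop("`t1fit` must be a t1_map_result")
  stopifnot_same_grid(dm$delta_m, t1fit$t1_map, "delta-m and T1 maps")
  sh <- dim(dm$delta_m)[1:2]
  nti <- length(dm$ti_ms)
  nvox <- prod(sh)
  y <- matrix(dm$delta_m, nrow = nvox, ncol = nti)
  t1app <- as.vector(t1fit$t1_map)
  m0 <- as.vector(t1fit$m0_map)

  # design vector g_v(TI): model at f = 1 for each voxel
  g <- matrix(NA_real_, nrow = nvox, ncol = nti)
  ok <- is.finite(t1app) & is.finite(m0) & t1app > 0
  for (j in seq_len(nti))
    g[ok, j] <- fair_delta_m_model(1, m0[ok], t1app[ok], consts, dm$ti_ms[j])

  gg <- rowSums(g * g)
  gy <- rowSums(g * y)
  f_hat <- ifelse(ok & gg > 0 & is.finite(gy), gy / gg, NA_real_)
  if (clamp_negative) f_hat <- pmax(f_hat, 0)
  fitted <- g * f_hat
  sse <- rowSums((y - fitted)^2)

  all_nan <- rowSums(is.finite(y)) == 0L
  if (any(all_nan))
    message(sprintf("fit_perfusion: %d all-NaN voxel(s) excluded",
                    sum(all_nan)))
  incl <- ok & !all_nan & is.finite(f_hat) &
    as.vector(t1fit$converged_mask) &
    !is.na(as.vector(t1fit$r2_map)) &
    as.vector(t1fit$r2_map) > r2_threshold

  f_map <- matrix(f_hat, sh[1], sh[2])
  residual_map <- matrix(sse, sh[1], sh[2])
  inclusion_mask <- matrix(incl, sh[1], sh[2])

  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, sh[1], sh[2])
  sel <- roi_mask & inclusion_mask
  vals <- f_map[sel]
  h <- if (length(vals)) graphics::hist(vals, breaks = hist_breaks,
                                        plot = FALSE) else NULL
  structure(
    list(f_map = f_map, residual_map = residual_map,
         inclusion_mask = inclusion_mask,
         roi_mean = if (length(vals)) mean(vals) else NA_real_,
         roi_sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
         histogram = h),
    class = "perfusion_map")
}

#' Apply the R-squared quality filter to a voxel map
#'
#' Voxels whose fit quality does not strictly exceed the threshold are set to
#' `NA`, removing them from any downstream statistic. The strict inequality
#' means a voxel at exactly the threshold is excluded.
#'
#' @param map numeric matrix.
#' @param r2_map matrix of per-voxel coefficients of determination.
#' @param threshold inclusion threshold in `[0, 1]`.
#' @return `map` with failing voxels set to `NA`.
#' @export
apply_quality_mask <- function(map, r2_map, threshold = 0.9) {
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  stopifnot_same_grid(map, r2_map, "map and r2_map")
  map[!(is.finite(r2_map) & r2_map > threshold)] <- NA_real_
  map
}
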