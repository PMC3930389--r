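#' Three-parameter inversion-recovery signal
#'
#' `S(TI) = M0 * (1 - 2 * inv_eff * exp(-TI / T1))`, signed, or its absolute
#' value when `magnitude = TRUE` (EPI magnitude reconstruction). Vectorised.
#'
#' @param m0 equilibrium signal.
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param inv_eff inversion efficiency in `[0, 1]`.
#' @param ti inversion time, ms.
#' @param magnitude return `abs()` of the signed signal.
#' @return signal in the units of `m0`.
#' @export
ir_signal <- function(m0, t1, inv_eff = 1, ti, magnitude = FALSE) {
  if (any(t1 <= 0)) stop("`t1` must be > 0", call. = FALSE)
  if (any(inv_eff < 0 | inv_eff > 1))
    stop("`inv_eff` must be in [0, 1]", call. = FALSE)
  s <- m0 * (1 - 2 * inv_eff * exp(-ti / t1))
  if (magnitude) abs(s) else s
}

#' T1-map fit result
#'
#' Container for voxel-wise relaxometry fits: equilibrium magnetization,
#' T1 (the apparent T1 when the series was acquired at the ASL slice),
#' coefficient of determination, and a convergence mask. Non-converged voxels
#' carry `NA` in all maps rather than silently filled values.
#'
#' @param m0_map,t1_map,r2_map numeric matrices.
#' @param converged_mask logical matrix.
#' @return a list of class `t1_map_result`.
#' @export
t1_map_result <- function(m0_map, t1_map, r2_map, converged_mask) {
  stopifnot_same_grid(m0_map, t1_map, "m0 and t1 maps")
  stopifnot_same_grid(m0_map, r2_map, "m0 and r2 maps")
  bad_t1 <- converged_mask & !(is.finite(t1_map) & t1_map > 0)
  if (any(bad_t1, na.rm = TRUE))
    stop("converged voxels must have positive finite T1", call. = FALSE)
  if (any(r2_map < 0 | r2_map > 1, na.rm = TRUE))
    stop("r2_map values must lie in [0, 1]", call. = FALSE)
  structure(list(m0_map = m0_map, t1_map = t1_map, r2_map = r2_map,
                 converged_mask = converged_mask),
            class = "t1_map_result")
}

# Fit one voxel's IR curve. For magnitude data the polarity of the early-TI
# points is restored before the signed three-parameter fit: candidate sign
# splits around the minimum-magnitude TI are tried and the lowest-SSE fit
# kept. Returns c(m0, t1, inv_eff, r2) or NAs.
fit_ir_voxel <- function(ti, y, magnitude = TRUE) {
  if (all(!is.finite(y))) return(rep(NA_real_, 4))
  if (stats::sd(y) == 0) return(rep(NA_real_, 4))  # degenerate: R2 undefined
  ord <- order(ti)
  ti <- ti[ord]; y <- y[ord]
  splits <- if (magnitude) {
    j <- which.min(abs(y))
    unique(pmax(0, pmin(length(ti), c(j - 1, j))))
  } else 0L
  best <- NULL; best_sse <- Inf
  for (k in splits) {
    ys <- y
    if (k > 0) ys[seq_len(k)] <- -abs(ys[seq_len(k)])
    t1_0 <- ti[which.min(abs(ys))] / log(2)
    t1_0 <- min(max(t1_0, 100), 8000)
    st <- list(m0 = abs(ys[length(ys)]), t1 = t1_0, b = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(ys ~ m0 * (1 - 2 * b * exp(-ti / t1)),
                        start = st,
                        lower = c(1e-9, 50, 0), upper = c(Inf, 10000, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- list(fit = fit, ys = ys) }
  }
  if (is.null(best)) return(rep(NA_real_, 4))
  p <- stats::coef(best$fit)
  sst <- sum((best$ys - mean(best$ys))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best_sse / sst)) else NA_real_
  c(p[["m0"]], p[["t1"]], p[["b"]], r2)
}

#' Voxel-wise inversion-recovery T1 mapping
#'
#' Nonlinear least squares of the three-parameter model
#' `M0 * (1 - 2 * inv_eff * exp(-TI/T1))` in every voxel. Magnitude data
#' (the default, matching EPI magnitude images) are handled by polarity
#' restoration: the sign of points before the null crossing is flipped when
#' that lowers the residual. T1 is bounded to `[50, 10000]` ms; starting T1
#' comes from the null-point heuristic (TI of minimum magnitude / ln 2) and
#' starting M0 from the longest-TI frame.
#'
#' @param series an [image_series()] with a `ti_ms` axis and at least 4
#'   distinct TIs; repeats are averaged first.
#' @param magnitude treat the data as magnitude images.
#' @param mask optional logical matrix restricting the fit (other voxels are
#'   `NA`, not converged).
#' @return a [t1_map_result()]; `r2_map` is `1 - SS_res/SS_tot` of the
#'   (polarity-restored) fit.
#' @export
fit_ir_t1 <- function(series, magnitude = TRUE, mask = NULL) {
  if (!inherits(series, "image_series")) stop("not an image_series")
  if (series$axis != "ti_ms") stop("series must carry a `ti_ms` axis")
  if (length(unique(series$values)) < 4L)
    stop("inversion-recovery fit needs >= 4 distinct TIs (3 parameters + 1 df)",
         call. = FALSE)
  s <- average_repeats(series)
  sh <- grid_shape(s)
  if (is.null(mask)) mask <- matrix(TRUE, sh[1], sh[2])
  m0 <- t1 <- r2 <- matrix(NA_real_, sh[1], sh[2])
  conv <- matrix(FALSE, sh[1], sh[2])
  idx <- which(mask)
  y_all <- matrix(s$data, nrow = prod(sh))
  for (v in idx) {
    out <- fit_ir_voxel(s$values, y_all[v, ], magnitude = magnitude)
    if (all(is.finite(out))) {
      m0[v] <- out[1]; t1[v] <- out[2]; r2[v] <- out[4]; conv[v] <- TRUE
    }
  }
  t1_map_result(m0, t1, r2, conv)
}

#' Spoiled gradient-echo (SPGR/FLASH) steady-state signal
#'
#' `S(theta) = M0 sin(theta) (1 - E1) / (1 - E1 cos(theta))` with
#' `E1 = exp(-TR/T1)`. Angles in degrees.
#'
#' @param m0 equilibrium signal.
#' @param t1 longitudinal relaxation time, ms.
#' @param tr repetition time, ms.
#' @param flip_deg flip angle, degrees.
#' @return signal in the units of `m0`.
#' @export
spgr_signal <- function(m0, t1, tr, flip_deg) {
  if (any(t1 <= 0)) stop("`t1` must be > 0", call. = FALSE)
  th <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(th) * (1 - e1) / (1 - e1 * cos(th))
}

#' Voxel-wise variable-flip-angle T1 mapping
#'
#' Linearises the SPGR signal (`S/sin(theta)` against `S/tan(theta)`; the
#' slope is `E1 = exp(-TR/T1)`), then refines by nonlinear least squares.
#' Voxels whose linearised slope falls outside (0, 1) — e.g. in the
#' `TR >> T1` regime where the signal is proportional to `sin(theta)` and T1
#' is unidentifiable — are flagged non-converged.
#'
#' @param series an [image_series()] with a `flip_deg` axis (angles strictly
#'   inside (0, 90) degrees, at least 2 of them); repeats are averaged first.
#' @param tr repetition time, ms.
#' @param mask optional logical matrix restricting the fit.
#' @return a [t1_map_result()].
#' @export
fit_vfa_t1 <- function(series, tr, mask = NULL) {
  if (!inherits(series, "image_series")) stop("not an image_series")
  if (series$axis != "flip_deg") stop("series must carry a `flip_deg` axis")
  if (tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  ang <- series$values
  if (length(ang) < 2L) stop("variable-flip-angle fit needs >= 2 angles",
                             call. = FALSE)
  if (any(ang <= 0 | ang >= 90))
    stop("flip angles must lie strictly inside (0, 90) degrees", call. = FALSE)
  s <- average_repeats(series)
  sh <- grid_shape(s)
  if (is.null(mask)) mask <- matrix(TRUE, sh[1], sh[2])
  th <- ang * pi / 180
  m0 <- t1 <- r2 <- matrix(NA_real_, sh[1], sh[2])
  conv <- matrix(FALSE, sh[1], sh[2])
  y_all <- matrix(s$data, nrow = prod(sh))
  for (v in which(mask)) {
    y <- y_all[v, ]
    if (!all(is.finite(y)) || stats::sd(y) == 0) next
    xl <- y / tan(th); yl <- y / sin(th)
    lf <- stats::lm.fit(cbind(1, xl), yl)
    slope <- lf$coefficients[2]
    if (!is.finite(slope) || slope <= 0 || slope >= 1) next  # unidentifiable
    t1_0 <- -tr / log(slope)
    m0_0 <- lf$coefficients[1] / (1 - slope)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ m0v * sin(th) * (1 - exp(-tr / t1v)) /
          (1 - exp(-tr / t1v) * cos(th)),
        start = list(m0v = m0_0, t1v = min(max(t1_0, 50), 10000)),
        lower = c(1e-9, 50), upper = c(Inf, 10000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- stats::coef(fit)
    sse <- sum(stats::resid(fit)^2)
    sst <- sum((y - mean(y))^2)
    m0[v] <- p[["m0v"]]; t1[v] <- p[["t1v"]]
    r2[v] <- max(0, min(1, 1 - sse / sst)); conv[v] <- TRUE
  }
  t1_map_result(m0, t1, r2, conv)
}
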