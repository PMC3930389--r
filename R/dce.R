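#' Baseline-normalized signal enhancement
#'
#' Per voxel, `dsi(t) = (SI(t) - mean_baseline) / mean_baseline`, where the
#' baseline mean is taken over the precontrast dynamics. Voxels whose
#' baseline mean is zero or negative cannot be normalized; they are set to
#' `NA` across all dynamics and counted in the `flagged` attribute.
#'
#' @param dynamics an [image_series()] with a `time_s` axis.
#' @param baseline_range integer indices (1-based dynamics) of the
#'   precontrast baseline.
#' @return a list of class `dsi_series`: `dsi` (array `nx x ny x nt`),
#'   `time_s`, `baseline_range`, `n_flagged`.
#' @export
normalize_si <- function(dynamics, baseline_range = 1:5) {
  if (!inherits(dynamics, "image_series")) stop("not an image_series")
  if (dynamics$axis != "time_s") stop("series must carry a `time_s` axis")
  nt <- length(dynamics$values)
  if (any(baseline_range < 1L) || any(baseline_range > nt))
    stop("`baseline_range` outside the acquired dynamics", call. = FALSE)
  sh <- grid_shape(dynamics)
  base <- apply(dynamics$data[, , baseline_range, drop = FALSE], c(1, 2),
                mean)
  bad <- !(is.finite(base) & base > 0)
  dsi <- sweep(sweep(dynamics$data, c(1, 2), base, "-"), c(1, 2), base, "/")
  if (any(bad)) {
    idx <- which(bad)
    for (j in seq_len(dim(dsi)[3])) dsi[, , j][idx] <- NA_real_
    warning(sprintf("normalize_si: %d voxel(s) with non-positive baseline excluded",
                    sum(bad)), call. = FALSE)
  }
  structure(list(dsi = dsi, time_s = dynamics$values,
                 baseline_range = baseline_range, n_flagged = sum(bad)),
            class = "dsi_series")
}

#' Per-voxel bolus-arrival detection
#'
#' In each voxel the contrast-arrival time T0 is the first time at which the
#' enhancement exceeds `k` times the baseline noise level (`delta`, the SD of
#' the enhancement over the baseline period), sustained for at least two
#' consecutive dynamics to reject single-frame spikes. Voxels that never
#' cross carry the sentinel `NA`. The earliest non-sentinel T0 across voxels
#' is reported as the actual (global) bolus arrival time. In noise-free
#' voxels (`delta == 0`) the test degenerates to `dsi > 0`.
#'
#' The search starts at the first dynamic after the baseline window.
#'
#' @param dsi a `dsi_series` from [normalize_si()].
#' @param k threshold multiplier (> 0).
#' @return a list of class `bolus_arrival`: `t0_map` (seconds; `NA`
#'   sentinel), `global_arrival` (s), `t0_index_map` (1-based dynamic).
#' @export
detect_bolus_arrival <- function(dsi, k = 3) {
  if (!inherits(dsi, "dsi_series")) stop("`dsi` must be a dsi_series")
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (length(dsi$baseline_range) < 3L)
    stop("need >= 3 baseline frames to estimate the baseline SD", call. = FALSE)
  sh <- dim(dsi$dsi)[1:2]
  nt <- length(dsi$time_s)
  y <- matrix(dsi$dsi, nrow = prod(sh), ncol = nt)
  delta <- apply(y[, dsi$baseline_range, drop = FALSE], 1, stats::sd)
  thr <- k * delta
  zero_noise <- is.finite(delta) & delta == 0
  if (any(zero_noise))
    message(sprintf(
      "detect_bolus_arrival: %d noise-free voxel(s); falling back to dsi > 0",
      sum(zero_noise)))
  start_j <- max(dsi$baseline_range) + 1L
  above <- y > ifelse(zero_noise, 0, thr)  # recycles thr down columns
  above[is.na(above)] <- FALSE
  idx <- rep(NA_integer_, prod(sh))
  if (start_j < nt) {
    sustained <- above[, start_j:(nt - 1L), drop = FALSE] &
      above[, (start_j + 1L):nt, drop = FALSE]
    first <- apply(sustained, 1, function(r)
      if (any(r)) which(r)[1] else NA_integer_)
    idx <- first + start_j - 1L
  }
  t0 <- dsi$time_s[idx]
  t0_map <- matrix(t0, sh[1], sh[2])
  structure(list(
    t0_map = t0_map,
    t0_index_map = matrix(idx, sh[1], sh[2]),
    global_arrival = if (all(is.na(t0))) NA_real_ else min(t0, na.rm = TRUE)),
    class = "bolus_arrival")
}

#' Time of maximum enhancement per voxel
#'
#' Returns the acquisition time of the maximum enhancement in each voxel;
#' ties are broken by the earliest occurrence. All-`NA` voxels carry the
#' sentinel `NA`.
#'
#' @param dsi a `dsi_series` from [normalize_si()].
#' @return matrix of times, s.
#' @export
compute_tmax <- function(dsi) {
  if (!inherits(dsi, "dsi_series")) stop("`dsi` must be a dsi_series")
  sh <- dim(dsi$dsi)[1:2]
  y <- matrix(dsi$dsi, nrow = prod(sh))
  idx <- apply(y, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  matrix(dsi$time_s[idx], sh[1], sh[2])
}

# trapezoidal integral of (t, y) over [a, b] with linear interpolation at
# the window edges; assumes t sorted increasing
trapz_window <- function(t, y, a, b) {
  if (b <= a) return(0)
  keep <- is.finite(y)
  if (sum(keep) < 2L) return(NA_real_)
  t <- t[keep]; y <- y[keep]
  a <- max(a, t[1]); b <- min(b, t[length(t)])
  if (b <= a) return(0)
  inner <- t > a & t < b
  tt <- c(a, t[inner], b)
  yy <- c(stats::approx(t, y, xout = a)$y, y[inner],
          stats::approx(t, y, xout = b)$y)
  pracma::trapz(tt, yy)
}

#' Area under the enhancement curve over a post-arrival window
#'
#' Trapezoidal integral of the enhancement over `[start, start + window]`
#' on the dynamic time grid, with linear interpolation at the window edges.
#' `window = "tmax"` integrates from `start` to each voxel's time of maximum
#' enhancement. A window extending past the acquisition is integrated to the
#' end and flagged via the `"truncated"` attribute.
#'
#' @param dsi a `dsi_series` from [normalize_si()].
#' @param start integration start (normally the global bolus arrival), s.
#' @param window window length in s, or `"tmax"`.
#' @param tmax_map required when `window = "tmax"`: matrix from
#'   [compute_tmax()].
#' @return matrix of areas (fractional enhancement x s), with attribute
#'   `truncated` (logical).
#' @export
compute_auc <- function(dsi, start, window, tmax_map = NULL) {
  if (!inherits(dsi, "dsi_series")) stop("`dsi` must be a dsi_series")
  sh <- dim(dsi$dsi)[1:2]
  nt <- length(dsi$time_s)
  y <- matrix(dsi$dsi, nrow = prod(sh))
  t <- dsi$time_s
  out <- rep(NA_real_, prod(sh))
  truncated <- FALSE
  if (identical(window, "tmax")) {
    if (is.null(tmax_map))
      stop("`tmax_map` is required for window = \"tmax\"", call. = FALSE)
    ends <- as.vector(tmax_map)
  } else {
    window <- as.numeric(window)
    if (!is.finite(window) || window <= 0)
      stop("`window` must be > 0 or \"tmax\"", call. = FALSE)
    if (start + window > t[nt] + 1e-9) {
      truncated <- TRUE
      warning(sprintf(
        "AUC window [%g, %g] s extends past the acquisition (ends %g s); integrating to the end",
        start, start + window, t[nt]), call. = FALSE)
    }
    ends <- rep(start + window, prod(sh))
  }
  for (v in seq_len(prod(sh))) {
    if (is.na(ends[v])) next
    out[v] <- trapz_window(t, y[v, ], start, ends[v])
  }
  structure(matrix(out, sh[1], sh[2]), truncated = truncated)
}

#' Full semi-quantitative DCE parameter maps
#'
#' Convenience wrapper running [normalize_si()], [detect_bolus_arrival()],
#' [compute_tmax()] and [compute_auc()] for the requested windows, returning
#' the standard map bundle.
#'
#' @param dynamics an [image_series()] with a `time_s` axis.
#' @param baseline_range precontrast dynamic indices.
#' @param k arrival-threshold multiplier.
#' @param windows numeric window lengths in s; `"tmax"` may be included.
#' @return a list of class `dce_maps`: `t0_map`, `global_arrival`,
#'   `tmax_map`, `auc_maps` (named list, e.g. `auc60`), `dsi`.
#' @export
dce_maps <- function(dynamics, baseline_range = 1:5, k = 3,
                     windows = c(60, 90, 150, "tmax")) {
  dsi <- normalize_si(dynamics, baseline_range)
  arr <- detect_bolus_arrival(dsi, k = k)
  tmax <- compute_tmax(dsi)
  aucs <- list()
  for (w in windows) {
    nm <- if (identical(w, "tmax")) "auc_tmax" else paste0("auc", w)
    aucs[[nm]] <- if (identical(w, "tmax"))
      compute_auc(dsi, arr$global_arrival, "tmax", tmax_map = tmax)
    else compute_auc(dsi, arr$global_arrival, as.numeric(w))
  }
  structure(list(t0_map = arr$t0_map, global_arrival = arr$global_arrival,
                 tmax_map = tmax, auc_maps = aucs, dsi = dsi),
            class = "dce_maps")
}
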