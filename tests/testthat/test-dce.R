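test_that("enhancement normalization follows the baseline-relative formula", {
  dsi_true <- rbind(c(0, 0, 0, 0, 0, 0.5, 0.2),
                    c(0, 0, 0, 0, 0, 1.0, 1.0))
  s <- series_from_dsi(dsi_true)
  out <- normalize_si(s, baseline_range = 1:5)
  expect_equal(out$dsi[1, 1, ], dsi_true[1, ])
  expect_equal(out$dsi[2, 1, 6], 1.0)   # SI doubled -> dsi = 1
  # flat series normalizes to zero
  flat <- series_from_dsi(matrix(0, 1, 7))
  expect_equal(max(abs(normalize_si(flat, 1:5)$dsi)), 0)
  expect_error(normalize_si(s, baseline_range = 1:20), "outside")
})

test_that("zero-baseline voxels are flagged and excluded", {
  vol <- array(100, dim = c(2, 1, 7))
  vol[2, 1, ] <- 0
  s <- image_series(vol, "time_s", (0:6) * 3.1, 1L)
  expect_warning(out <- normalize_si(s, 1:5), "non-positive baseline")
  expect_equal(out$n_flagged, 1)
  expect_true(all(is.na(out$dsi[2, 1, ])))
})

test_that("bolus arrival is the first sustained threshold crossing", {
  nt <- 30
  # noise-free step from 0 to 0.5 at dynamic 10; flat voxel never crosses
  step10 <- c(rep(0, 9), rep(0.5, nt - 9))
  step8 <- c(rep(0, 7), rep(0.5, nt - 7))
  step12 <- c(rep(0, 11), rep(0.5, nt - 11))
  flat <- rep(0, nt)
  spike <- c(rep(0, 14), 0.5, rep(0, nt - 15))  # single-frame spike
  s <- series_from_dsi(rbind(step10, flat, step8, step12, spike))
  dsi <- normalize_si(s, 1:5)
  arr <- suppressMessages(detect_bolus_arrival(dsi, k = 3))
  expect_equal(arr$t0_index_map[1, 1], 10L)
  expect_true(is.na(arr$t0_index_map[2, 1]))   # sentinel, never crosses
  expect_true(is.na(arr$t0_index_map[5, 1]))   # spike rejected (not sustained)
  # global arrival is the earliest voxel arrival: dynamic 8
  expect_equal(arr$global_arrival, dsi$time_s[8])
  expect_error(detect_bolus_arrival(dsi, k = 0), "k")
})

test_that("noisy arrival detection uses k times the baseline SD", {
  set.seed(3)
  nt <- 40
  noise <- rnorm(nt, 0, 0.01)
  curve <- noise + c(rep(0, 19), rep(0.6, nt - 19))
  dsi <- normalize_si(series_from_dsi(rbind(curve)), 1:8)
  arr <- detect_bolus_arrival(dsi, k = 3)
  expect_equal(arr$t0_index_map[1, 1], 20L)
})

test_that("time of maximum enhancement uses the earliest-tie convention", {
  nt <- 20
  rising <- seq(0, 1, length.out = nt)
  peak12 <- exp(-abs(seq_len(nt) - 12))
  constant <- rep(0.3, nt)
  s <- series_from_dsi(rbind(rising, peak12, constant))
  dsi <- normalize_si(series_from_dsi(rbind(
    c(rep(0, 5), rising[-(1:5)]), peak12, constant)), 1:5)
  tm <- compute_tmax(dsi)
  expect_equal(tm[1, 1], dsi$time_s[nt])   # monotone -> last time point
  expect_equal(tm[2, 1], dsi$time_s[12])
  expect_equal(tm[3, 1], dsi$time_s[1])    # tie-break: first dynamic
})

test_that("AUC matches closed-form areas and flags truncation", {
  dt <- 3.1
  nt <- 60
  t <- (seq_len(nt) - 1) * dt
  # unit enhancement: area over any 60 s window is exactly 60
  dsi <- normalize_si(series_from_dsi(rbind(rep(1, nt)), dt), 1:5)
  dsi$dsi[1, 1, ] <- 1  # constant unit curve (baseline frames included)
  auc <- compute_auc(dsi, start = 15.5, window = 60)
  expect_equal(auc[1, 1], 60)
  # zero curve integrates to zero
  z <- normalize_si(series_from_dsi(rbind(rep(0, nt)), dt), 1:5)
  expect_equal(compute_auc(z, 15.5, 60)[1, 1], 0)
  # triangle rising 0 -> 1 over 62 s from t = 0, truncated at 60 s:
  # area = 60^2 / (2 * 62); trapezoid with edge interpolation is exact here
  tri <- pmax(0, pmin((t - 0) / 62, 1))
  dsi_tri <- normalize_si(series_from_dsi(rbind(tri), dt), 1:5)
  dsi_tri$dsi[1, 1, ] <- tri
  expect_equal(compute_auc(dsi_tri, 0, 60)[1, 1], 60^2 / (2 * 62),
               tolerance = 1e-12)
  # window past acquisition end: integrate to the end, flag it
  expect_warning(auc_tr <- compute_auc(dsi, 15.5, 1000), "past the acquisition")
  expect_true(attr(auc_tr, "truncated"))
  expect_equal(auc_tr[1, 1], t[nt] - 15.5)
  expect_error(compute_auc(dsi, 15.5, -1), "window")
})

test_that("AUC windows are monotone on nonnegative curves", {
  set.seed(11)
  nt <- 100
  ok <- TRUE
  for (i in seq_len(1000)) {
    dsi_row <- c(rep(0, 5), runif(nt - 5, 0, 2))
    dsi <- normalize_si(series_from_dsi(rbind(dsi_row)), 1:5)
    a60 <- compute_auc(dsi, 15.5, 60)[1, 1]
    a90 <- compute_auc(dsi, 15.5, 90)[1, 1]
    a150 <- compute_auc(dsi, 15.5, 150)[1, 1]
    ok <- ok && (a60 <= a90 + 1e-12) && (a90 <= a150 + 1e-12) && a60 >= 0
  }
  expect_true(ok)
})

test_that("AUC depends only on the enhancement, not the baseline level", {
  nt <- 40
  dsi_row <- c(rep(0, 5), gamma_variate((5:(nt - 1)) * 3.1, 1.2, 17, 25))
  lo <- series_from_dsi(rbind(dsi_row))
  hi <- lo; hi$data <- lo$data * 40      # 40x baseline, same relative curve
  a_lo <- compute_auc(normalize_si(lo, 1:5), 15.5, 60)[1, 1]
  a_hi <- compute_auc(normalize_si(hi, 1:5), 15.5, 60)[1, 1]
  expect_equal(a_lo, a_hi, tolerance = 1e-12)
})

test_that("no-enhancement phantom yields only arrival sentinels", {
  spec <- tiny_spec()
  spec$noise_sd <- 0
  spec$dce$amp_rim <- 0
  spec$dce$amp_core <- 0
  d <- generate_dce_series(spec, n_dynamics = 30)
  dsi <- normalize_si(d$dynamics, 1:5)
  arr <- suppressMessages(detect_bolus_arrival(dsi))
  expect_true(all(is.na(arr$t0_map)))
  expect_true(is.na(arr$global_arrival))
})

test_that("phantom rank order of enhancement amplitude is preserved in AUC60", {
  spec <- tiny_spec()
  spec$noise_sd <- 0
  spec$core_radius <- 2
  spec$f_core <- 10
  d <- generate_dce_series(spec, n_dynamics = 60)
  maps <- suppressMessages(dce_maps(d$dynamics, 1:5, windows = 60))
  amp <- d$truth$dce_params$amplitude
  sel <- amp > 0
  expect_equal(
    suppressWarnings(cor(amp[sel], maps$auc_maps$auc60[sel],
                         method = "spearman")), 1)
})
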