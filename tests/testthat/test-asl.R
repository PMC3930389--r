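test_that("T1app shortens with flow and matches the hand-computed value", {
  expect_equal(t1app_from_t1(1500, 0), 1500)
  # 1/(1/1.5 + 0.016667) s: f/lambda = 90/(6000*0.9) = 0.016667 1/s
  expect_equal(t1app_from_t1(1500, 90, 0.9), 1463.4146, tolerance = 1e-6)
  f_grid <- seq(0, 200, by = 10)
  expect_true(all(diff(t1app_from_t1(1500, f_grid)) < 0))
  expect_error(t1app_from_t1(-5, 90), "t1")
})

test_that("kinetic model vanishes at zero flow and zero TI", {
  tis <- c(100, 350, 750, 1500, 2500, 4000)
  expect_equal(fair_delta_m_model(0, 1000, 1463, ti = tis), rep(0, 6))
  expect_equal(fair_delta_m_model(90, 1000, 1463, ti = 0), 0)
  expect_error(fair_delta_m_model(90, 1000, 1463, ti = -10), "ti")
  expect_error(fair_delta_m_model(-1, 1000, 1463, ti = 100), "f")
})

test_that("removable singularity at T1app = T1a is handled by its limit", {
  consts <- asl_constants()
  tis <- c(100, 750, 2500)
  lim <- 2 * 1000 * (90 / (6000 * 0.9) / 1000) * tis * exp(-tis / consts$t1a)
  # exactly at the singular point
  expect_equal(fair_delta_m_model(90, 1000, consts$t1a, consts, tis), lim)
  # approaching it from both sides through the general branch
  for (eps in c(-1e-5, 1e-5)) {
    t1app <- consts$t1a * (1 + eps)
    expect_equal(fair_delta_m_model(90, 1000, t1app, consts, tis), lim,
                 tolerance = 1e-4)
  }
})

test_that("model is linear in flow and its peak TI does not depend on flow", {
  tis <- seq(10, 6000, by = 10)
  consts <- asl_constants()
  m1 <- fair_delta_m_model(45, 1000, 1400, consts, tis)
  m2 <- fair_delta_m_model(90, 1000, 1400, consts, tis)
  expect_equal(m2, 2 * m1)
  # analytic stationarity: TI* = log(r_app/r_a) / (r_app - r_a)
  r_app <- 1 / 1400; r_a <- 1 / consts$t1a
  ti_star <- log(r_app / r_a) / (r_app - r_a)
  expect_equal(tis[which.max(m1)], ti_star, tolerance = 10)
  expect_equal(which.max(m1), which.max(m2))
})

test_that("delta-M computation averages repeats and checks its inputs", {
  tis <- c(100, 500)
  base <- array(10, dim = c(3, 2, 8))  # 2 TIs x 4 repeats
  ctrl <- image_series(base, "ti_ms", tis, 4L)
  lab_arr <- base
  # +5 units in voxel (2,1) at TI index 2 of every repeat
  lab_arr[2, 1, seq(2, 8, by = 2)] <- 15
  lab <- image_series(lab_arr, "ti_ms", tis, 4L)
  dm <- compute_delta_m(ctrl, lab)
  expect_equal(dm$delta_m[2, 1, ], c(0, 5))
  expect_equal(sum(dm$delta_m != 0), 1)
  # identical series give identically zero
  dm0 <- compute_delta_m(ctrl, ctrl)
  expect_equal(max(abs(dm0$delta_m)), 0)
  expect_error(compute_delta_m(ctrl, image_series(base, "ti_ms", c(100, 600), 4L)),
               "TI lists")
  expect_error(
    compute_delta_m(ctrl, image_series(base[, , 1:4], "ti_ms", tis, 2L)),
    "repeat counts")
})

test_that("noise-free perfusion fit recovers truth within 0.1%", {
  for (f in c(10, 90, 200)) {
    pm <- recover_flow(tiny_spec(f_rim = f))
    tum_vals <- pm$f_map[pm$inclusion_mask]
    expect_lt(max(abs(pm$roi_mean - f)) / f, 1e-3)
    expect_equal(pm$roi_sd, 0, tolerance = f * 1e-6)
  }
})

test_that("zero difference signal fits to zero flow", {
  spec <- tiny_spec(f_rim = 0)
  pm <- recover_flow(spec)
  expect_equal(pm$roi_mean, 0, tolerance = 1e-9)
})

test_that("doubling the true flow doubles the recovered flow", {
  pm1 <- recover_flow(tiny_spec(f_rim = 45))
  pm2 <- recover_flow(tiny_spec(f_rim = 90))
  expect_equal(pm2$roi_mean, 2 * pm1$roi_mean, tolerance = 1e-6)
})

test_that("ROI statistics conserve the included-voxel values", {
  spec <- tiny_spec(f_rim = 60, noise_sd = 0.02, n_repeats = 10)
  asl <- generate_asl_series(spec)
  ir <- generate_ir_series(spec)
  t1f <- fit_ir_t1(ir, mask = asl$truth$tumor_mask)
  pm <- fit_perfusion(compute_delta_m(asl$control, asl$label), t1f,
                      roi_mask = asl$truth$tumor_mask)
  sel <- pm$inclusion_mask & asl$truth$tumor_mask
  expect_equal(pm$roi_mean, mean(pm$f_map[sel]))
  expect_equal(sum(pm$histogram$counts), sum(sel))
})

test_that("negative-going noise fits are clamped at zero unless asked not to", {
  spec <- tiny_spec(f_rim = 0, noise_sd = 0.05, n_repeats = 2, seed = 7)
  asl <- generate_asl_series(spec)
  ir_spec <- spec; ir_spec$noise_sd <- 0
  t1f <- fit_ir_t1(generate_ir_series(ir_spec), mask = asl$truth$tumor_mask)
  dm <- compute_delta_m(asl$control, asl$label)
  pm <- fit_perfusion(dm, t1f, roi_mask = asl$truth$tumor_mask)
  expect_true(all(pm$f_map[pm$inclusion_mask] >= 0))
  pm_signed <- fit_perfusion(dm, t1f, roi_mask = asl$truth$tumor_mask,
                             clamp_negative = FALSE)
  expect_true(any(pm_signed$f_map[pm_signed$inclusion_mask] < 0))
})
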