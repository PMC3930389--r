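test_that("invalid phantom specs are rejected naming the field", {
  expect_error(phantom_spec(f_rim = -1), "f_rim")
  expect_error(phantom_spec(t1_core = 0), "t1_core")
  expect_error(phantom_spec(noise_sd = -0.1), "noise_sd")
})

test_that("zero flow gives zero difference signal at every TI", {
  spec <- tiny_spec(f_rim = 0)
  asl <- generate_asl_series(spec)
  dm <- compute_delta_m(asl$control, asl$label)
  expect_equal(max(abs(dm$delta_m)), 0)
})

test_that("seeding contract: same seed reproduces, different seed differs", {
  a1 <- generate_asl_series(tiny_spec(noise_sd = 0.02, seed = 1))
  a2 <- generate_asl_series(tiny_spec(noise_sd = 0.02, seed = 1))
  a3 <- generate_asl_series(tiny_spec(noise_sd = 0.02, seed = 2))
  expect_identical(a1$control$data, a2$control$data)
  expect_identical(a1$label$data, a2$label$data)
  expect_false(identical(a1$control$data, a3$control$data))
  v1 <- generate_vessel_mask(phantom_spec(seed = 5), 4, 2)
  v2 <- generate_vessel_mask(phantom_spec(seed = 5), 4, 2)
  expect_identical(v1, v2)
})

test_that("phantom generation does not disturb the caller's random stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_asl_series(tiny_spec(noise_sd = 0.02)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free label-minus-control equals the kinetic model", {
  spec <- tiny_spec(f_rim = 90)
  asl <- generate_asl_series(spec)
  dm <- compute_delta_m(asl$control, asl$label)
  t1app <- t1app_from_t1(spec$t1_rim, 90)
  v <- which(asl$truth$tumor_mask)[1]
  ij <- arrayInd(v, dim(asl$truth$tumor_mask))
  expect_equal(dm$delta_m[ij[1], ij[2], ],
               fair_delta_m_model(90, spec$m0_scale, t1app, asl_constants(),
                                  dm$ti_ms))
})

test_that("IR series obeys the recovery limits of the signed model", {
  # full recovery at the longest TI and a null point at T1app * ln 2
  spec <- tiny_spec(f_rim = 0)  # background T1 = 1500 everywhere, f = 0
  s <- generate_ir_series(spec, ti_ms = c(10, 100, 500, 1000, 2000, 5000, 8000))
  expect_lt(abs(s$data[1, 1, 7] - spec$m0_scale) / spec$m0_scale, 0.01)
  null_ti <- 1500 * log(2)
  s2 <- generate_ir_series(spec, ti_ms = sort(c(100, null_ti, 3000)))
  expect_lt(abs(s2$data[1, 1, 2]), 1e-9)
  expect_error(generate_ir_series(spec, ti_ms = numeric(0)), "non-empty")
  expect_error(generate_ir_series(spec, ti_ms = c(500, 100)), "increasing")
})

test_that("IR arithmetic: magnitude at TI = T1 matches the closed form", {
  # 1000 * (1 - 2 e^-1): positive signed (TI past the null point), 264.24 mag
  expect_equal(ir_signal(1000, 1500, 1, 1500), 1000 * (1 - 2 * exp(-1)))
  expect_equal(ir_signal(1000, 1500, 1, 1500, magnitude = TRUE),
               264.2411, tolerance = 1e-6)
})

test_that("DCE series carries a gamma-variate with known closed-form area", {
  spec <- tiny_spec()
  spec$noise_sd <- 0
  d <- generate_dce_series(spec, n_dynamics = 100, dt = 3.1,
                           bolus_dynamic = 6)
  expect_equal(length(d$dynamics$values), 100L)
  # truth onset never precedes the bolus
  expect_true(all(d$truth$dce_params$onset_s >= (6 - 1) * 3.1, na.rm = TRUE))
  # numeric integral of the curve matches the analytic value
  p <- d$truth$dce_params
  v <- which(d$truth$tumor_mask)[1]
  fine_t <- seq(p$onset_s[v], p$onset_s[v] + 60, by = 0.001)
  num <- pracma::trapz(fine_t, gamma_variate(fine_t, p$amplitude[v],
                                             p$onset_s[v], p$ttp_s[v],
                                             p$shape))
  expect_equal(gamma_variate_auc(p$amplitude[v], p$ttp_s[v], p$shape, 60),
               num, tolerance = 1e-6)
  expect_error(generate_dce_series(spec, dt = 0), "dt")
  expect_error(generate_dce_series(spec, n_dynamics = 6, bolus_dynamic = 6),
               "n_dynamics")
})

test_that("vessel placement yields the requested component count", {
  spec <- phantom_spec(seed = 3)
  expect_equal(sum(generate_vessel_mask(spec, 0)), 0)
  m <- generate_vessel_mask(spec, 5, vessel_radius = 2)
  expect_equal(attr(label_components(m), "n_components"), 5L)
  # impossible request fails loudly
  expect_error(generate_vessel_mask(spec, 500, vessel_radius = 3,
                                    max_tries = 50), "could not place")
})

test_that("generated series round-trip through NIfTI bit-exactly", {
  spec <- tiny_spec(noise_sd = 0.02, n_repeats = 3)
  asl <- generate_asl_series(spec)
  path <- file.path(tempdir(), "rt_test.nii.gz")
  write_series(asl$control, path)
  back <- read_series(path)
  expect_identical(back$data, asl$control$data)
  expect_equal(back$values, asl$control$values)
  expect_equal(back$repeats, asl$control$repeats)
})
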