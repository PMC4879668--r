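test_that("surrogate reflectance is monotone over the LUT target range", {
  for (sds in c(374, 730)) {
    ms <- seq(5, 26, by = 0.5); ma <- seq(0, 10, by = 0.5)
    for (a in ma) expect_true(all(diff(surrogate_reflectance(ms, a, sds)) > 0))
    for (s in ms) expect_true(all(diff(surrogate_reflectance(s, ma, sds)) < 0))
  }
  expect_lt(surrogate_reflectance(15, 1000, 374), 1e-30)  # opaque limit
  expect_error(surrogate_reflectance(-5, 1, 374), class = "sdrs_domain_error")
})

test_that("surrogate reflectance matches an independent formula transcription", {
  # hand-coded evaluation of the documented closed form, written separately
  musp <- 10; mua <- 1; sds <- 730
  n <- 1.4
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  rho <- 730e-4
  z0 <- 1 / musp; zb <- 2 * A / (3 * musp)
  mueff <- sqrt(3 * mua * (mua + 15))
  r1 <- sqrt(z0^2 + rho^2); r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  expected <- 0.01 * (musp / (musp + mua)) / (4 * pi) *
    (z0 * (1 + mueff * r1) * exp(-mueff * r1) / r1^3 +
       (z0 + 2 * zb) * (1 + mueff * r2) * exp(-mueff * r2) / r2^3)
  expect_equal(surrogate_reflectance(musp, mua, sds), expected,
               tolerance = 1e-12)
})

test_that("detected depth fraction is a proper CDF with the stated median", {
  for (sds in c(374, 730)) {
    expect_equal(detected_depth_fraction(10, 1, sds, 0), 0)
    expect_equal(detected_depth_fraction(10, 1, sds, 1e6), 1,
                 tolerance = 1e-6)
    d50 <- sampling_depth_median(10, 1, sds)
    expect_equal(detected_depth_fraction(10, 1, sds, d50), 0.5,
                 tolerance = 1e-12)
    z <- seq(0, 2000, by = 50)
    expect_true(all(diff(detected_depth_fraction(10, 1, sds, z)) > 0))
  }
})

test_that("median sampling depth orders with absorption, scattering and SDS", {
  ms <- seq(5, 26, by = 3); ma <- seq(0, 10, by = 2)
  for (sds in c(374, 730)) {
    for (s in ms) expect_true(all(diff(sampling_depth_median(s, ma, sds)) < 0))
    for (a in ma) expect_true(all(diff(sampling_depth_median(ms, a, sds)) < 0))
  }
  g <- expand.grid(ms = ms, ma = ma)
  expect_true(all(sampling_depth_median(g$ms, g$ma, 730) >
                    sampling_depth_median(g$ms, g$ma, 374)))
})

test_that("noiseless translation curves rise to the semi-infinite plateau", {
  wl <- seq(450, 750, by = 10)
  a <- sdrslut:::calibration_anchors()
  for (sds in c(374, 730)) {
    for (i in c(1, 5)) {
      spec <- phantom_spec("x", solve_volume_fraction(a$dye_anchor[i]),
                           list(type = "dye", peak_mua = a$dye_peak[i]))
      props <- phantom_optical_properties(spec, wl, fx_table())
      curve <- simulate_translation_curve(props, sds, fx_config0())
      rsemi <- surrogate_reflectance(props$musp, props$mua, sds)
      expect_true(all(apply(curve$reflectance, 2, function(col)
        all(diff(col) >= 0) && col[2] > col[1])))
      expect_equal(curve$reflectance[1, ], 0 * wl)   # no specular at contact
      frac2mm <- curve$reflectance[nrow(curve$reflectance), ] / rsemi
      # the deeper channel saturates more slowly; absorbing phantoms still
      # reach the plateau to within a few percent at 2 mm
      expect_true(all(frac2mm > if (sds == 374) 0.99 else 0.95))
    }
  }
})

test_that("translation curves are reproducible under a fixed seed", {
  wl <- seq(500, 700, by = 25)
  props <- list(wavelengths = wl, musp = power_law_musp(10, 1, wl),
                mua = rep(1, length(wl)))
  c1 <- simulate_translation_curve(props, 374, instrument_config(),
                                   noise = TRUE, seed = 11)
  c2 <- simulate_translation_curve(props, 374, instrument_config(),
                                   noise = TRUE, seed = 11)
  expect_identical(c1$reflectance, c2$reflectance)
})

test_that("two-layer simulation reduces to its limits and orders stages", {
  wl <- seq(450, 750, by = 2)
  homog <- layered_sample(list(
    list(thickness_um = 150, musp = power_law_musp(7, 1, wl), mua = 0 * wl),
    list(thickness_um = 150, musp = power_law_musp(7, 1, wl), mua = 0 * wl),
    list(thickness_um = Inf, musp = power_law_musp(7, 1, wl), mua = 0 * wl)))
  two <- simulate_two_layer(homog, 374, wl)
  expect_equal(approx(wl, two$musp_va, xout = 630)$y, 7, tolerance = 1e-12)
  thick_top <- layered_sample(list(
    list(thickness_um = 5e5, musp = power_law_musp(14, 1, wl), mua = 0 * wl),
    list(thickness_um = Inf, musp = power_law_musp(7, 1, wl), mua = 0 * wl)))
  two2 <- simulate_two_layer(thick_top, 374, wl)
  expect_equal(approx(wl, two2$musp_va, xout = 630)$y, 14, tolerance = 1e-3)
  # stage ordering of volume-averaged scattering, stronger at the shorter SDS
  ph <- sdrslut:::dysplasia_phantoms()
  va <- sapply(c(374, 730), function(sds) sapply(c("P1", "P2", "P3"),
    function(st) {
      s <- sdrslut:::resolve_layers(ph[[st]], ph$B, wl)
      approx(wl, simulate_two_layer(s, sds, wl)$musp_va, xout = 630)$y
    }))
  expect_true(all(diff(va[, 1]) > 0) && all(diff(va[, 2]) > 0))
  inc <- (va["P3", ] - va["P1", ]) / va["P1", ]
  expect_gt(inc[1], inc[2])
  expect_gt(va["P3", 1], 7); expect_lt(va["P3", 1], 14)
  expect_error(layered_sample(list(list(thickness_um = 100, musp = 7,
                                        mua = 0))),
               class = "sdrs_structural_error")
})

test_that("measurement simulation is exact without noise and seed-stable", {
  wl <- seq(500, 700, by = 10)
  props <- list(wavelengths = wl, musp = power_law_musp(12, 0.9, wl),
                mua = rep(0.8, length(wl)))
  m <- simulate_measurement(props, 374, fx_config0(), seed = 5)
  cal <- sdrslut:::calibrate_measurement(m)
  expect_equal(cal$value, surrogate_reflectance(props$musp, props$mua, 374),
               tolerance = 1e-12)
  m1 <- simulate_measurement(props, 374, instrument_config(), seed = 9)
  m2 <- simulate_measurement(props, 374, instrument_config(), seed = 9)
  expect_identical(m1$sample$value, m2$sample$value)
})

test_that("averaging reduces calibrated variance like 1/n", {
  wl <- c(600)
  props <- list(wavelengths = wl, musp = 12, mua = 1)
  draw <- function(n_avg, n = 200, seed = 3) {
    cfg <- instrument_config(n_averages = n_avg,
                            noise_additive_sigma = 0)
    with_seed <- sdrslut:::with_seed
    with_seed(seed, vapply(seq_len(n), function(i)
      sdrslut:::calibrate_measurement(
        simulate_measurement(props, 374, cfg))$value, numeric(1)))
  }
  v1 <- var(draw(1)); v5 <- var(draw(5))
  # ratio ~ 5 within 3x the sampling error of a 200-draw variance ratio
  expect_gt(v1 / v5, 2.5)
  expect_lt(v1 / v5, 10)
})

test_that("lamp shape cancels through absolute calibration", {
  wl <- seq(500, 700, by = 10)
  props <- list(wavelengths = wl, musp = power_law_musp(10, 1, wl),
                mua = rep(0.5, length(wl)))
  ref <- sdrslut:::calibrate_measurement(
    simulate_measurement(props, 374, fx_config0()))$value
  set.seed(21)
  for (i in 1:5) {
    lamp <- exp(runif(length(wl), -2, 2))
    got <- sdrslut:::calibrate_measurement(
      simulate_measurement(props, 374, fx_config0(), lamp_values = lamp))
    expect_equal(got$value, ref, tolerance = 1e-10)
  }
})
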