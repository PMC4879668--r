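spectrum_from_params <- function(par, sds, wl = seq(450, 750, by = 2),
                                 table = fx_table()) {
  musp <- power_law_musp(par[["musp_ref"]], par[["B"]], wl)
  mua <- hemoglobin_mu_a(par[["hb_conc"]], par[["sao2"]], wl, table)
  spectrum(wl, surrogate_reflectance(musp, mua, sds), kind = "absolute",
           sds = sds)
}

test_that("model reflectance composes power law, hemoglobin and LUT lookup", {
  lut <- fx_luts0()[["374"]]
  wl <- seq(500, 750, by = 10)
  par <- c(musp_ref = 10, B = 1, hb_conc = 0, sao2 = 0.5)
  pred <- predicted_reflectance(par, lut, wl, fx_table())
  expect_equal(as.numeric(pred),
               lut_lookup(lut, power_law_musp(10, 1, wl), rep(0, length(wl))))
  expect_equal(attr(pred, "excursion"), 0)
  # increasing B tilts the model down beyond the reference wavelength
  p2 <- par; p2[["B"]] <- 2
  long <- wl > 630
  expect_true(all(as.numeric(predicted_reflectance(p2, lut, wl,
                                                   fx_table()))[long] <
                    as.numeric(pred)[long]))
  # out-of-range trajectories are clipped and reported
  p3 <- c(musp_ref = 25, B = 2, hb_conc = 0, sao2 = 0.5)
  expect_gt(attr(predicted_reflectance(p3, lut, seq(450, 750, 10),
                                       fx_table()), "excursion"), 0)
})

test_that("noiseless four-parameter fits recover the truth within 1%", {
  # self-generated round trip: the spectrum comes from the LUT-based forward
  # model itself, so recovery isolates the inversion machinery from LUT
  # construction error (which criterion-level LUT oracle tests cover)
  truth <- c(musp_ref = 10, B = 1.2, hb_conc = 2.5, sao2 = 0.9)
  wl <- seq(450, 750, by = 2)
  for (sds in c("374", "730")) {
    r <- as.numeric(predicted_reflectance(truth, fx_luts0()[[sds]], wl,
                                          fx_table()))
    f <- fit_spectrum(spectrum(wl, r, kind = "absolute",
                               sds = as.numeric(sds)),
                      fx_luts0()[[sds]], fx_table())
    expect_true(f$converged)
    expect_equal(unname(coef(f)), unname(truth), tolerance = 0.01)
    expect_lt(f$residual_rms / mean(f$observed), 0.01)
  }
})

test_that("surrogate-generated noiseless fits carry only the LUT/model floor", {
  # through the instrument surrogate the recovery additionally absorbs the
  # LUT reconstruction error (~0.5% RMS) and the power-law approximation to
  # the Mie scattering spectrum; parameters stay within a few percent
  truth <- c(musp_ref = 10, B = 1.2, hb_conc = 2.5, sao2 = 0.9)
  for (sds in c("374", "730")) {
    f <- fit_spectrum(spectrum_from_params(truth, as.numeric(sds)),
                      fx_luts0()[[sds]], fx_table())
    expect_equal(unname(coef(f)), unname(truth), tolerance = 0.03)
  }
})

test_that("an absorber-free spectrum fits to near-zero hemoglobin", {
  truth <- c(musp_ref = 14, B = 0.8, hb_conc = 0, sao2 = 0.5)
  f <- fit_spectrum(spectrum_from_params(truth, 374), fx_luts0()[["374"]])
  expect_lte(coef(f)[["hb_conc"]], 0.05)
})

test_that("fits are invariant to spectral decimation on noiseless data", {
  truth <- c(musp_ref = 12, B = 1.0, hb_conc = 3, sao2 = 0.95)
  f2 <- fit_spectrum(spectrum_from_params(truth, 374,
                                          wl = seq(450, 750, by = 2)),
                     fx_luts0()[["374"]])
  f035 <- fit_spectrum(spectrum_from_params(truth, 374,
                                            wl = seq(450, 750, by = 0.35)),
                       fx_luts0()[["374"]])
  expect_equal(coef(f2), coef(f035), tolerance = 0.005)
})

test_that("the winning start achieves the lowest multi-start objective", {
  truth <- c(musp_ref = 18, B = 0.6, hb_conc = 1.5, sao2 = 1)
  sp <- spectrum_from_params(truth, 374)
  lut <- fx_luts0()[["374"]]
  f <- fit_spectrum(sp, lut)
  keep <- sp$wavelengths >= 500
  robs <- sp$value[keep]
  ss_at <- function(par) {
    pred <- predicted_reflectance(par, lut, sp$wavelengths[keep], fx_table())
    sum(((robs - as.numeric(pred)) / robs)^2)
  }
  ss_best <- ss_at(coef(f))
  for (ms in c(6, 24)) for (B in c(0.15, 3.2))
    expect_lte(ss_best, ss_at(c(musp_ref = ms, B = B, hb_conc = 2,
                                sao2 = 0.8)) + 1e-12)
})

test_that("parameter recovery degrades monotonically with injected noise", {
  truth <- c(musp_ref = 11, B = 1.1, hb_conc = 2.5, sao2 = 0.9)
  wl <- seq(450, 750, by = 4)
  props <- list(wavelengths = wl,
                musp = power_law_musp(truth[["musp_ref"]], truth[["B"]], wl),
                mua = hemoglobin_mu_a(truth[["hb_conc"]], truth[["sao2"]],
                                      wl, fx_table()))
  rms_at <- function(sigma, reps = 20, seed = 31) {
    cfg <- instrument_config(noise_multiplicative_sigma = sigma,
                             noise_additive_sigma = if (sigma == 0) 0 else 1)
    errs <- sdrslut:::with_seed(seed, vapply(seq_len(reps), function(r) {
      m <- simulate_measurement(props, 374, cfg)
      f <- fit_spectrum(sdrslut:::calibrate_measurement(m),
                        fx_luts0()[["374"]])
      sqrt(mean(((coef(f) - truth) / truth)^2))
    }, numeric(1)))
    sqrt(mean(errs^2))
  }
  rms <- vapply(c(0, 0.005, 0.01, 0.02), rms_at, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("property percent errors apply the absorption floor and guards", {
  same <- list(musp = c(10, 10), mua = c(2, 2))
  expect_equal(property_percent_errors(same, same)$musp_pct, 0)
  expect_equal(property_percent_errors(same, same)$mua_pct, 0)
  e <- property_percent_errors(list(musp = c(9.2, 9.2), mua = c(2, 2)),
                               list(musp = c(10, 10), mua = c(2, 2)))
  expect_equal(e$musp_pct, 8.0)
  zero_mua <- list(musp = c(10, 10), mua = c(0, 0))
  g <- property_percent_errors(list(musp = c(10, 10), mua = c(1, 1)),
                               zero_mua)
  expect_true(is.na(g$mua_pct))
  expect_equal(g$n_excluded, 2)
  floor_mix <- property_percent_errors(
    list(musp = c(10, 10), mua = c(0.3, 2.2)),
    list(musp = c(10, 10), mua = c(0.2, 2)))
  expect_equal(floor_mix$mua_pct, 10)    # only the above-floor wavelength
  expect_error(property_percent_errors(list(musp = 1:3, mua = 1:3),
                                       list(musp = 1:2, mua = 1:2)),
               class = "sdrs_structural_error")
})

test_that("fit interface validates spectra, windows and channel pairing", {
  sp <- spectrum_from_params(c(musp_ref = 10, B = 1, hb_conc = 2,
                               sao2 = 0.9), 374)
  expect_error(fit_spectrum(sp, fx_luts0()[["730"]]),
               class = "sdrs_structural_error")
  expect_error(fit_spectrum(sp, fx_luts0()[["374"]], window = c(900, 1000)),
               class = "sdrs_structural_error")
  raw <- sp; raw$kind <- "raw"
  expect_error(fit_spectrum(raw, fx_luts0()[["374"]]),
               class = "sdrs_structural_error")
})

test_that("sdrs_fit methods expose coefficients, predictions and depths", {
  truth <- c(musp_ref = 9, B = 1.4, hb_conc = 2, sao2 = 0.85)
  f <- fit_spectrum(spectrum_from_params(truth, 374), fx_luts0()[["374"]],
                    depth_lut = fx_depth_luts()[["374"]])
  expect_named(coef(f), c("musp_ref", "B", "hb_conc", "sao2"))
  expect_length(residuals(f), length(f$wavelengths))
  expect_equal(fitted(f) + residuals(f), f$observed)
  expect_equal(predict(f, what = "musp", wavelengths = 630),
               coef(f)[["musp_ref"]], ignore_attr = TRUE)
  expect_true(all(f$depth_um > 100 & f$depth_um < 800))
  out <- capture.output({ print(f); print(summary(f)) })
  expect_true(any(grepl("musp", out)))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "sdrs_spectrum")
})
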