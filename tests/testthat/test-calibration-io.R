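mk_spec <- function(values, kind, wl = seq(500, 510, by = 1), sds = 374)
  spectrum(wl, values, kind = kind, sds = sds)

test_that("absolute calibration honors the 20% standard identity and linearity", {
  wl <- seq(500, 510, by = 1)
  std <- mk_spec(rep(1000, 11), "standard")
  bg <- mk_spec(rep(0, 11), "background")
  same <- mk_spec(rep(1000, 11), "raw")
  expect_equal(to_absolute_reflectance(same, bg, std)$value, rep(0.20, 11))
  expect_equal(to_absolute_reflectance(mk_spec(rep(0, 11), "raw"), bg,
                                       std)$value, rep(0, 11))
  half <- to_absolute_reflectance(mk_spec(rep(500, 11), "raw"), bg, std)
  expect_equal(half$value, rep(0.10, 11))
  bg2 <- mk_spec(rep(100, 11), "background")
  expect_equal(to_absolute_reflectance(mk_spec(rep(600, 11), "raw"), bg2,
                                       mk_spec(rep(1100, 11), "standard"))$value,
               rep(0.10, 11))
  expect_error(to_absolute_reflectance(mk_spec(rep(1, 5), "raw",
                                               wl = seq(1, 5)), bg, std),
               class = "sdrs_structural_error")
  expect_error(to_absolute_reflectance(same, mk_spec(rep(2000, 11),
                                                     "background"), std),
               "calibration error")
})

test_that("overlap checker applies the 90% band-continuity rule with margins", {
  r <- check_overlap(list(c(3.0, 4.9), c(4.4, 7.1)))
  expect_true(r$pass[1])                       # 4.4 <= 0.9 * 4.9 = 4.41
  expect_equal(r$margin[1], 0.01, tolerance = 1e-12)
  r2 <- check_overlap(list(c(4.4, 7.1), c(6.4, 10.2)))
  expect_false(r2$pass[1])                     # 6.4 > 0.9 * 7.1 = 6.39
  expect_equal(r2$margin[1], -0.01, tolerance = 1e-12)
  r3 <- check_overlap(list(c(5, 8), c(5, 8)))
  expect_true(r3$pass[1])
  expect_error(check_overlap(list(c(5, 8))), class = "sdrs_structural_error")
  expect_error(check_overlap(list(c(9, 10), c(5, 8))),
               class = "sdrs_structural_error")
  expect_error(check_overlap(list(c(8, 5), c(5, 8))),
               class = "sdrs_structural_error")
})

test_that("calibration set delivers 12 phantoms with the designed recipes", {
  cal <- fx_cal0()
  expect_length(cal$phantoms, 12)
  expect_equal(vapply(cal$phantoms, function(p) p$id, character(1)),
               paste0("C.P.", 1:12))
  for (i in 1:6)
    expect_equal(cal$properties[[i]]$mua, rep(0, length(cal$wavelengths)))
  peak_mua <- vapply(cal$properties[7:12], function(p) max(p$mua), numeric(1))
  expect_equal(max(peak_mua), 47, tolerance = 1e-3)
  expect_true(all(peak_mua > 0))
  expect_length(cal$spectra, 2)
  expect_length(cal$spectra[["374"]], 12)
})

test_that("validation set is 9 hemoglobin phantoms inside the LUT rectangle", {
  val <- generate_validation_set(5, fx_config0(), 2, noise = FALSE,
                                 table = fx_table())
  expect_length(val$phantoms, 9)
  expect_true(all(vapply(val$phantoms,
                         function(p) p$absorber$type, character(1)) ==
                    "hemoglobin"))
  keep <- val$wavelengths >= 500 & val$wavelengths <= 750
  for (p in val$properties) {
    expect_true(all(p$musp[keep] >= 5 & p$musp[keep] <= 26))
    expect_true(all(p$mua[keep] >= 0 & p$mua[keep] <= 10))
  }
  # the set jointly spans most of both target ranges
  all_musp <- unlist(lapply(val$properties, function(p) p$musp[keep]))
  all_mua <- unlist(lapply(val$properties, function(p) p$mua[keep]))
  expect_lt(min(all_musp), 6); expect_gt(max(all_musp), 23)
  expect_lt(min(all_mua), 0.1); expect_gt(max(all_mua), 9)
})

test_that("phantom sets are deterministic per seed", {
  cfg <- instrument_config()
  a <- generate_calibration_set(3, cfg, 8)
  b <- generate_calibration_set(3, cfg, 8)
  expect_identical(a$spectra[["730"]][[7]]$value,
                   b$spectra[["730"]][[7]]$value)
  c3 <- generate_calibration_set(4, cfg, 8)
  expect_false(identical(a$spectra[["730"]][[7]]$value,
                         c3$spectra[["730"]][[7]]$value))
})

test_that("spectra CSV round trip is lossless and rejects malformed files", {
  wl <- seq(450, 460, by = 0.5)
  sp <- list(spectrum(wl, exp(sin(wl)), kind = "absolute", sds = 374),
             spectrum(wl, wl * pi, kind = "raw", sds = 730))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$value, sp[[1]]$value, tolerance = 1e-12)
  expect_equal(back[[2]]$sds, 730)
  expect_equal(back[[1]]$kind, "absolute")
  writeLines("", path)
  expect_error(read_spectra(path), "empty")
  writeLines(c("wavelength_nm,value,kind,sds_um,integration_ms",
               "510,1,raw,374,400", "500,1,raw,374,400"), path)
  expect_error(read_spectra(path), "non-monotone")
  writeLines(c("wavelength_nm,value", "500,1"), path)
  expect_error(read_spectra(path), "missing columns")
  expect_error(read_spectra(file.path(tempdir(), "nope.csv")), "no such file")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(500, 499), c(1, 1), "raw", 374),
               class = "sdrs_structural_error")
  expect_error(spectrum(numeric(0), numeric(0), "raw", 374),
               class = "sdrs_structural_error")
  expect_error(spectrum(c(500, 501), c(-1, 1), "absolute", 374),
               class = "sdrs_domain_error")
})
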