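#' Build both LUT channels from a calibration set
#'
#' Convenience wrapper: pairs each phantom's theoretical optical properties
#' with its calibrated spectrum and builds one reflectance LUT per SDS.
#'
#' @param cal result of [generate_calibration_set()].
#' @param step LUT grid resolution, cm\eqn{^{-1}}.
#' @param musp_range,mua_range LUT target ranges.
#' @return named list of `sdrs_lut`, one per SDS.
#' @export
build_luts_from_calibration <- function(cal, step = 0.02,
                                        musp_range = c(5, 26),
                                        mua_range = c(0, 10)) {
  out <- list()
  for (sds in names(cal$spectra)) {
    pairs <- lapply(seq_along(cal$phantoms), function(i)
      list(props = cal$properties[[i]], spectrum = cal$spectra[[sds]][[i]]))
    out[[sds]] <- build_reflectance_lut(pairs, as.numeric(sds),
                                        musp_range, mua_range, step,
                                        provenance = list(seed = cal$seed))
  }
  out
}

#' Phantom-validation round trip
#'
#' The full calibration/validation study on synthetic phantoms: generate the
#' 12-phantom calibration set, build a reflectance LUT per SDS, generate the
#' 9-phantom hemoglobin validation set, fit every validation spectrum with
#' the LUT-based inverse model, and report per-SDS percent-error statistics
#' for the recovered \eqn{\mu_s'} and \eqn{\mu_a} spectra against theory.
#'
#' @param seed RNG seed controlling every stochastic step.
#' @param config an [instrument_config()]; set
#'   `noise_multiplicative_sigma = 0` for a noiseless round trip.
#' @param lut_step LUT grid resolution, cm\eqn{^{-1}} (default 0.02).
#' @param wavelength_step_nm spectral decimation of simulated spectra.
#' @param window fit window, nm.
#' @param mua_floor theoretical-\eqn{\mu_a} exclusion floor for the
#'   \eqn{\mu_a} percent error.
#' @param luts optional precomputed LUT list (skips calibration).
#' @return list with `per_fit` (data frame: phantom, sds, errors,
#'   parameters), `summary` (per-SDS and overall means/min/max), `luts`,
#'   `seed`.
#' @export
run_phantom_validation <- function(seed = 1, config = instrument_config(),
                                   lut_step = 0.02, wavelength_step_nm = 2,
                                   window = c(500, 750), mua_floor = 0.5,
                                   luts = NULL) {
  table <- load_chromophore_table()
  if (is.null(luts)) {
    cal <- generate_calibration_set(seed, config, wavelength_step_nm,
                                    noise = config$noise_multiplicative_sigma > 0,
                                    table = table)
    luts <- build_luts_from_calibration(cal, step = lut_step)
  }
  val <- generate_validation_set(seed + 1000L, config, wavelength_step_nm,
                                 noise = config$noise_multiplicative_sigma > 0,
                                 table = table)
  rows <- list()
  for (sds in names(val$spectra)) {
    for (i in seq_along(val$phantoms)) {
      sp <- val$spectra[[sds]][[i]]
      fit <- fit_spectrum(sp, luts[[sds]], table, window = window)
      keep <- val$wavelengths >= window[1] & val$wavelengths <= window[2]
      theo <- list(musp = val$properties[[i]]$musp[keep],
                   mua = val$properties[[i]]$mua[keep])
      err <- property_percent_errors(list(musp = fit$musp, mua = fit$mua),
                                     theo, mua_floor)
      rows[[length(rows) + 1]] <- data.frame(
        phantom = val$phantoms[[i]]$id, sds = as.numeric(sds),
        musp_pct = err$musp_pct, mua_pct = err$mua_pct,
        n_mua_excluded = err$n_excluded,
        musp_ref = fit$par[["musp_ref"]], B = fit$par[["B"]],
        hb_conc = fit$par[["hb_conc"]], sao2 = fit$par[["sao2"]],
        residual_rms = fit$residual_rms, converged = fit$converged)
    }
  }
  per_fit <- do.call(rbind, rows)
  summarise <- function(d) data.frame(
    sds = d$sds[1],
    musp_mean = mean(d$musp_pct), musp_min = min(d$musp_pct),
    musp_max = max(d$musp_pct),
    mua_mean = mean(d$mua_pct, na.rm = TRUE),
    mua_min = min(d$mua_pct, na.rm = TRUE),
    mua_max = max(d$mua_pct, na.rm = TRUE))
  summary <- do.call(rbind, lapply(split(per_fit, per_fit$sds), summarise))
  summary <- rbind(summary,
                   data.frame(sds = NA, musp_mean = mean(per_fit$musp_pct),
                              musp_min = min(per_fit$musp_pct),
                              musp_max = max(per_fit$musp_pct),
                              mua_mean = mean(per_fit$mua_pct, na.rm = TRUE),
                              mua_min = min(per_fit$mua_pct, na.rm = TRUE),
                              mua_max = max(per_fit$mua_pct, na.rm = TRUE)))
  list(experiment = "phantom_validation", per_fit = per_fit,
       summary = summary, luts = luts, seed = seed,
       noise_sigma = config$noise_multiplicative_sigma)
}

#' Sampling-depth validation round trip
#'
#' Simulates translation curves for the six absorbing calibration phantoms,
#' estimates per-wavelength sampling depths with the 50%-crossing estimator,
#' builds a sampling-depth LUT per SDS, then repeats curve simulation and
#' depth estimation for the nine validation phantoms and reports percent
#' errors of their estimated depths against the LUT predictions at the
#' theoretical optical properties, together with the deep/shallow channel
#' depth-ratio statistics.
#'
#' @inheritParams run_phantom_validation
#' @param lut_step depth-LUT grid resolution, cm\eqn{^{-1}}.
#' @return list with `per_phantom` errors, `summary`, `depth_luts`,
#'   `ratio` (730/374 grid statistics), `depth_bands` (per-SDS min/max of
#'   the depth LUT, um), `seed`.
#' @export
run_depth_validation <- function(seed = 1, config = instrument_config(),
                                 lut_step = 0.05, wavelength_step_nm = 4,
                                 window = c(500, 750)) {
  table <- load_chromophore_table()
  noise <- config$noise_multiplicative_sigma > 0
  wl <- config_wavelengths(config, wavelength_step_nm)
  a <- calibration_anchors()
  cal_specs <- lapply(seq_along(a$dye_anchor), function(i)
    phantom_spec(paste0("C.P.", i + 6),
                 solve_volume_fraction(a$dye_anchor[i]),
                 list(type = "dye", peak_mua = a$dye_peak[i])))
  val <- generate_validation_set(seed + 1000L, config, wavelength_step_nm,
                                 noise = FALSE, table = table)

  depth_luts <- list(); rows <- list()
  for (sds in config$sds_list) {
    records <- with_seed(seed + match(sds, config$sds_list), {
      lapply(cal_specs, function(spec) {
        props <- phantom_optical_properties(spec, wl, table)
        curve <- simulate_translation_curve(props, sds, config,
                                            noise = noise, seed = NULL)
        est <- estimate_sampling_depth(curve, on_fail = "na")
        list(props = props, depth_um = est$depth_um, id = spec$id)
      })
    })
    depth_luts[[as.character(sds)]] <- build_sampling_depth_lut(
      records, sds, step = lut_step, provenance = list(seed = seed))
  }
  keep <- wl >= window[1] & wl <= window[2]
  for (sds in config$sds_list) {
    lut <- depth_luts[[as.character(sds)]]
    ests <- with_seed(seed + 100L + match(sds, config$sds_list), {
      lapply(seq_along(val$phantoms), function(i) {
        curve <- simulate_translation_curve(val$properties[[i]], sds, config,
                                            noise = noise, seed = NULL)
        estimate_sampling_depth(curve, on_fail = "na")
      })
    })
    for (i in seq_along(val$phantoms)) {
      pr <- val$properties[[i]]
      predicted <- lut_lookup(lut,
                              pmin(pmax(pr$musp[keep], min(lut$musp_axis)),
                                   max(lut$musp_axis)),
                              pmin(pmax(pr$mua[keep], min(lut$mua_axis)),
                                   max(lut$mua_axis)))
      err <- depth_percent_error(ests[[i]]$depth_um[keep], predicted)
      rows[[length(rows) + 1]] <- data.frame(
        phantom = val$phantoms[[i]]$id, sds = sds,
        depth_pct = mean(err, na.rm = TRUE),
        n_na = sum(!is.finite(err)))
    }
  }
  per_phantom <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_phantom, per_phantom$sds),
    function(d) data.frame(sds = d$sds[1], depth_mean = mean(d$depth_pct),
                           depth_min = min(d$depth_pct),
                           depth_max = max(d$depth_pct))))
  ratio <- if (length(depth_luts) >= 2)
    lut_ratio_stats(depth_luts[[1]], depth_luts[[2]])[c("mean", "sd",
                                                        "min", "max")]
  bands <- lapply(depth_luts, function(l) range(l$values))
  list(experiment = "depth_validation", per_phantom = per_phantom,
       summary = summary, depth_luts = depth_luts, ratio = ratio,
       depth_bands = bands, seed = seed,
       overall_mean = mean(per_phantom$depth_pct))
}

# layered dysplasia-progression phantom geometries: two 150-um epithelial
# sublayers over a 1-cm (optically semi-infinite) stromal base; scattering
# power law anchored at 630 nm, no absorber
dysplasia_phantoms <- function(musp_healthy = 7, musp_dysplastic = 14,
                               B = 1, layer_um = 150) {
  mk_layer <- function(musp_ref, th) list(
    thickness_um = th,
    musp_ref = musp_ref)
  geo <- function(top, bottom) {
    layered_sample(list(
      list(thickness_um = layer_um, musp_ref = top),
      list(thickness_um = layer_um, musp_ref = bottom),
      list(thickness_um = Inf, musp_ref = musp_healthy)))
  }
  list(P1 = geo(musp_healthy, musp_healthy),
       P2 = geo(musp_healthy, musp_dysplastic),
       P3 = geo(musp_dysplastic, musp_dysplastic),
       B = B)
}

# resolve the power-law layers of a dysplasia phantom on a grid
resolve_layers <- function(sample, B, wavelengths) {
  layered_sample(lapply(sample$layers, function(l)
    list(thickness_um = l$thickness_um,
         musp = power_law_musp(l$musp_ref, B, wavelengths),
         mua = rep(0, length(wavelengths)))))
}

#' Layered dysplastic-progression experiment
#'
#' Simulates the three-stage layered phantom model of epithelial dysplasia
#' (a two-fold scattering heterogeneity proliferating upward through two
#' 150-um sublayers over a semi-infinite base at the healthy level) at both
#' SDS, fits the volume-averaged \eqn{\mu_s'} of repeated noisy measurements
#' with the LUT-based inverse model, and reports percent increases in
#' volume-averaged \eqn{\mu_s'} at 630 nm between stages with paired t-tests
#' (374 vs 730 um channel) at `alpha`.
#'
#' @inheritParams run_phantom_validation
#' @param n_reps repeated measurements per geometry and SDS.
#' @param alpha significance level of the paired tests.
#' @param musp_healthy,musp_dysplastic scattering levels at 630 nm.
#' @return list with `musp_va` (fitted volume-averaged \eqn{\mu_s'}(630) per
#'   rep), `oracle` (noiseless generator ground truth), `increases`
#'   (per-pair per-SDS mean/sd of percent increases), `tests` (paired
#'   t-tests), `seed`.
#' @export
run_dysplasia_progression <- function(seed = 1, config = instrument_config(),
                                      n_reps = 10, luts = NULL,
                                      lut_step = 0.02,
                                      wavelength_step_nm = 2,
                                      window = c(500, 750), alpha = 0.01,
                                      musp_healthy = 7,
                                      musp_dysplastic = 14) {
  table <- load_chromophore_table()
  if (is.null(luts)) {
    cal <- generate_calibration_set(seed, config, wavelength_step_nm,
                                    noise = config$noise_multiplicative_sigma > 0,
                                    table = table)
    luts <- build_luts_from_calibration(cal, step = lut_step)
  }
  wl <- config_wavelengths(config, wavelength_step_nm)
  ph <- dysplasia_phantoms(musp_healthy, musp_dysplastic)
  stages <- c("P1", "P2", "P3")
  fits <- list(); oracle <- list()
  for (sds in config$sds_list) {
    for (st in stages) {
      sample <- resolve_layers(ph[[st]], ph$B, wl)
      two <- simulate_two_layer(sample, sds, wl)
      oracle[[paste(st, sds)]] <- stats::approx(wl, two$musp_va,
                                                xout = 630)$y
      vals <- with_seed(seed + 10L * match(sds, config$sds_list) +
                          match(st, stages), {
        vapply(seq_len(n_reps), function(r) {
          m <- simulate_measurement(NULL, sds, config, seed = NULL,
                                    wavelengths = wl,
                                    reflectance = two$reflectance)
          f <- fit_spectrum(calibrate_measurement(m),
                            luts[[as.character(sds)]], table,
                            window = window)
          f$par[["musp_ref"]]
        }, numeric(1))
      })
      fits[[paste(st, sds)]] <- vals
    }
  }
  pairs <- list(c("P1", "P2"), c("P2", "P3"), c("P1", "P3"))
  inc_rows <- list(); tests <- list()
  for (p in pairs) {
    lab <- paste0(p[1], "_to_", p[2])
    inc_by_sds <- lapply(config$sds_list, function(sds) {
      100 * (fits[[paste(p[2], sds)]] - fits[[paste(p[1], sds)]]) /
        fits[[paste(p[1], sds)]]
    })
    names(inc_by_sds) <- as.character(config$sds_list)
    for (sds in names(inc_by_sds))
      inc_rows[[length(inc_rows) + 1]] <- data.frame(
        pair = lab, sds = as.numeric(sds),
        mean = mean(inc_by_sds[[sds]]), sd = stats::sd(inc_by_sds[[sds]]))
    if (length(inc_by_sds) >= 2) {
      tt <- stats::t.test(inc_by_sds[[1]], inc_by_sds[[2]], paired = TRUE)
      tests[[lab]] <- data.frame(pair = lab, t = unname(tt$statistic),
                                 p_value = tt$p.value,
                                 significant = tt$p.value < alpha)
    }
  }
  list(experiment = "dysplasia_progression",
       musp_va = fits, oracle = unlist(oracle),
       increases = do.call(rbind, inc_rows),
       tests = do.call(rbind, tests), alpha = alpha, seed = seed)
}

#' Cohort specification for the synthetic in-vivo study
#'
#' Subject-level parameter distributions of the synthetic oral-mucosa
#' cohort: each subject draws a shared base value per parameter plus a
#' channel offset for the deeper SDS, emulating depth-dependent sampling of
#' the vascularized sub-epithelium (lower scattering exponent, higher
#' hemoglobin at the longer separation; saturation essentially
#' depth-independent).
#'
#' @param n_subjects cohort size (default 13).
#' @param B_mean,B_sd scattering exponent distribution (shallow channel).
#' @param B_delta deep-channel offset of B.
#' @param hb_mean,hb_sd hemoglobin concentration, mg/mL.
#' @param hb_delta deep-channel offset of `[Hb]`, mg/mL.
#' @param sao2_mean,sao2_sd oxygen saturation (fraction).
#' @param sao2_delta deep-channel offset of saturation.
#' @param musp_ref_mean,musp_ref_sd reference scattering at 630 nm.
#' @param channel_jitter_sd subject-independent jitter of each deep-channel
#'   offset.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13,
                        B_mean = 0.80, B_sd = 0.19, B_delta = -0.32,
                        hb_mean = 2.39, hb_sd = 0.44, hb_delta = 0.52,
                        sao2_mean = 0.941, sao2_sd = 0.08,
                        sao2_delta = -0.024,
                        musp_ref_mean = 10, musp_ref_sd = 1.5,
                        channel_jitter_sd = c(B = 0.08, hb = 0.15,
                                              sao2 = 0.05)) {
  structure(as.list(environment()), class = "cohort_spec")
}

#' Synthetic cohort fitting study
#'
#' Draws per-subject tissue parameters from a [cohort_spec()], synthesizes
#' one spectrum per subject and SDS through the instrument surrogate, fits
#' every spectrum with the LUT-based inverse model, and reports per-SDS
#' means and SDs of `B`, `[Hb]` and `SaO2` with across-subject paired
#' t-tests between the two channels, plus recovery errors against the
#' generating parameters.
#'
#' @inheritParams run_phantom_validation
#' @param spec a [cohort_spec()].
#' @param alpha significance level.
#' @param depth_luts optional sampling-depth LUTs for depth bands.
#' @return list with `truth` and `recovered` data frames, `summary`,
#'   `tests`, `recovery` (per-subject percent errors), `seed`.
#' @export
run_cohort_fit <- function(seed = 1, spec = cohort_spec(),
                           config = instrument_config(), luts = NULL,
                           lut_step = 0.02, wavelength_step_nm = 2,
                           window = c(500, 750), alpha = 0.01,
                           depth_luts = NULL) {
  table <- load_chromophore_table()
  if (is.null(luts)) {
    cal <- generate_calibration_set(seed, config, wavelength_step_nm,
                                    noise = config$noise_multiplicative_sigma > 0,
                                    table = table)
    luts <- build_luts_from_calibration(cal, step = lut_step)
  }
  wl <- config_wavelengths(config, wavelength_step_nm)
  sds_pair <- config$sds_list
  truth <- with_seed(seed + 7L, {
    n <- spec$n_subjects
    base_B <- stats::rnorm(n, spec$B_mean, spec$B_sd)
    base_hb <- pmax(stats::rnorm(n, spec$hb_mean, spec$hb_sd), 0.2)
    base_sao2 <- pmin(pmax(stats::rnorm(n, spec$sao2_mean, spec$sao2_sd),
                           0.5), 1)
    musp_ref <- pmin(pmax(stats::rnorm(n, spec$musp_ref_mean,
                                       spec$musp_ref_sd), 6), 24)
    j <- spec$channel_jitter_sd
    rows <- list()
    for (i in seq_len(n)) {
      for (ch in seq_along(sds_pair)) {
        deep <- ch == length(sds_pair) && length(sds_pair) > 1
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, sds = sds_pair[ch],
          musp_ref = musp_ref[i],
          B = max(base_B[i] + if (deep) spec$B_delta +
                    stats::rnorm(1, 0, j[["B"]]) else 0, 0.05),
          hb_conc = max(base_hb[i] + if (deep) spec$hb_delta +
                          stats::rnorm(1, 0, j[["hb"]]) else 0, 0.1),
          sao2 = min(max(base_sao2[i] + if (deep) spec$sao2_delta +
                           stats::rnorm(1, 0, j[["sao2"]]) else 0, 0), 1))
      }
    }
    do.call(rbind, rows)
  })
  rec <- with_seed(seed + 11L, {
    rows <- list()
    for (r in seq_len(nrow(truth))) {
      tr <- truth[r, ]
      props <- list(wavelengths = wl,
                    musp = power_law_musp(tr$musp_ref, tr$B, wl),
                    mua = hemoglobin_mu_a(tr$hb_conc, tr$sao2, wl, table))
      m <- simulate_measurement(props, tr$sds, config, seed = NULL)
      f <- fit_spectrum(calibrate_measurement(m),
                        luts[[as.character(tr$sds)]], table,
                        window = window,
                        depth_lut = depth_luts[[as.character(tr$sds)]])
      rows[[r]] <- data.frame(subject = tr$subject, sds = tr$sds,
                              musp_ref = f$par[["musp_ref"]],
                              B = f$par[["B"]], hb_conc = f$par[["hb_conc"]],
                              sao2 = f$par[["sao2"]],
                              depth_min = if (!is.null(f$depth_um))
                                min(f$depth_um) else NA,
                              depth_max = if (!is.null(f$depth_um))
                                max(f$depth_um) else NA)
    }
    do.call(rbind, rows)
  })
  summary <- do.call(rbind, lapply(split(rec, rec$sds), function(d)
    data.frame(sds = d$sds[1], B_mean = mean(d$B), B_sd = stats::sd(d$B),
               hb_mean = mean(d$hb_conc), hb_sd = stats::sd(d$hb_conc),
               sao2_mean = mean(d$sao2), sao2_sd = stats::sd(d$sao2))))
  tests <- NULL
  if (length(sds_pair) >= 2) {
    a <- rec[rec$sds == sds_pair[1], ]
    b <- rec[rec$sds == sds_pair[length(sds_pair)], ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    tests <- do.call(rbind, lapply(c("B", "hb_conc", "sao2"), function(v) {
      tt <- stats::t.test(a[[v]], b[[v]], paired = TRUE)
      data.frame(parameter = v, t = unname(tt$statistic),
                 p_value = tt$p.value, significant = tt$p.value < alpha)
    }))
  }
  recovery <- merge(truth, rec, by = c("subject", "sds"),
                    suffixes = c("_true", "_fit"))
  recovery$B_pct <- 100 * abs(recovery$B_fit - recovery$B_true) /
    pmax(recovery$B_true, 1e-6)
  recovery$hb_pct <- 100 * abs(recovery$hb_conc_fit - recovery$hb_conc_true) /
    recovery$hb_conc_true
  recovery$sao2_pct <- 100 * abs(recovery$sao2_fit - recovery$sao2_true) /
    recovery$sao2_true
  list(experiment = "cohort_fit", truth = truth, recovered = rec,
       summary = summary, tests = tests, recovery = recovery,
       alpha = alpha, seed = seed)
}

#' Write an experiment report to disk
#'
#' JSON summary plus CSV tables, so every reported statistic stays
#' recomputable from archived intermediates.
#'
#' @param report a list returned by one of the `run_*` pipelines.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- !vapply(report, function(x)
    inherits(x, "sdrs_lut") || (is.list(x) && length(x) &&
                                  inherits(x[[1]], "sdrs_lut")), logical(1))
  jsonlite::write_json(report[keep],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (nm in names(report)[keep]) {
    if (is.data.frame(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
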