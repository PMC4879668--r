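#' Synthetic dye absorption spectrum
#'
#' Smooth stand-in for the food-dye absorber of the calibration phantoms: the
#' sum of two Gaussian absorption bands centered at 520 and 630 nm (relative
#' amplitudes 1 and 0.8, widths 45 and 40 nm), peak-normalized and scaled so
#' the maximum over 450-750 nm equals `peak_mua`. This is an arbitrary smooth
#' spectrum playing the dye's role in LUT construction, not a reconstruction
#' of any real dye.
#'
#' @param peak_mua maximum absorption over the band, cm\eqn{^{-1}}.
#' @param wavelengths nm grid.
#' @return absorption coefficients, cm\eqn{^{-1}}.
#' @export
dye_mu_a <- function(peak_mua, wavelengths) {
  check_number(peak_mua, "peak_mua", lower = 0)
  shape <- exp(-0.5 * ((wavelengths - 520) / 45)^2) +
    0.8 * exp(-0.5 * ((wavelengths - 630) / 40)^2)
  ref <- seq(450, 750, by = 0.5)
  smax <- max(exp(-0.5 * ((ref - 520) / 45)^2) +
                0.8 * exp(-0.5 * ((ref - 630) / 40)^2))
  peak_mua * shape / smax
}

#' Phantom specification
#'
#' Recipe for a homogeneous liquid phantom: a scatterer (microsphere
#' suspension or named power law) plus an absorber (none, synthetic dye, or
#' hemoglobin). Resolvable to per-wavelength optical properties on any grid
#' within 450-750 nm via [phantom_optical_properties()].
#'
#' @param id phantom identifier (e.g. `"C.P.3"`, `"V.P.7"`).
#' @param scatterer a [microsphere_suspension()], or a list
#'   `list(type = "power_law", musp_ref =, B =)`.
#' @param absorber one of `list(type = "none")`,
#'   `list(type = "dye", peak_mua =)`,
#'   `list(type = "hemoglobin", hb_conc =, sao2 =)`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(id, scatterer, absorber = list(type = "none")) {
  if (!inherits(scatterer, "microsphere_suspension") &&
      !identical(scatterer$type, "power_law"))
    stop_structural("scatterer must be a microsphere_suspension or power_law")
  if (!absorber$type %in% c("none", "dye", "hemoglobin"))
    stop_structural("unknown absorber type '", absorber$type, "'")
  structure(list(id = id, scatterer = scatterer, absorber = absorber),
            class = "phantom_spec")
}

#' Optical properties of a phantom on a wavelength grid
#'
#' @param phantom a [phantom_spec()].
#' @param wavelengths nm grid within 450-750 nm.
#' @param table chromophore table used for hemoglobin absorbers.
#' @return list with `wavelengths`, `musp`, `mua` (cm\eqn{^{-1}}).
#' @export
phantom_optical_properties <- function(phantom, wavelengths,
                                       table = load_chromophore_table()) {
  stopifnot(inherits(phantom, "phantom_spec"))
  musp <- if (inherits(phantom$scatterer, "microsphere_suspension")) {
    microsphere_musp(phantom$scatterer, wavelengths)
  } else {
    power_law_musp(phantom$scatterer$musp_ref, phantom$scatterer$B,
                   wavelengths)
  }
  mua <- switch(phantom$absorber$type,
    none = rep(0, length(wavelengths)),
    dye = dye_mu_a(phantom$absorber$peak_mua, wavelengths),
    hemoglobin = hemoglobin_mu_a(phantom$absorber$hb_conc,
                                 phantom$absorber$sao2, wavelengths, table))
  list(wavelengths = wavelengths, musp = musp, mua = mua)
}

#' Check scattering-band overlap of an ordered phantom series
#'
#' For consecutive scattering bands, the next band's minimum must not exceed
#' 90% of the previous band's maximum for the series to span a continuous
#' \eqn{\mu_s'} range. The report carries the margin
#' `0.9 * max(n) - min(n+1)` for each pair (positive margin = pass).
#'
#' @param ranges list (or 2-column matrix) of `(musp_min, musp_max)` pairs,
#'   ordered by increasing band.
#' @return data frame with one row per consecutive pair: `pair`, `max_prev`,
#'   `min_next`, `margin`, `pass`.
#' @export
check_overlap <- function(ranges) {
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
  if (length(ranges) < 2) stop_structural("need at least two ranges")
  m <- do.call(rbind, lapply(ranges, function(r) {
    if (r[1] >= r[2]) stop_structural("each range needs min < max")
    as.numeric(r[1:2])
  }))
  if (any(diff(m[, 1]) < 0))
    stop_structural("ranges must be ordered by increasing band minimum")
  n <- nrow(m)
  data.frame(pair = paste(seq_len(n - 1), seq(2, n), sep = "-"),
             max_prev = m[-n, 2], min_next = m[-1, 1],
             margin = 0.9 * m[-n, 2] - m[-1, 1],
             pass = m[-1, 1] <= 0.9 * m[-n, 2])
}

# fixed recipe anchors: musp at 750 nm (cm^-1) of the six scattering levels
# used for the scattering-only phantoms, and the (anchor, dye peak) pairs of
# the six dye phantoms. Dye levels place high absorption against both low
# and high scattering so the pooled phantom trajectories cover the LUT
# target rectangle; the last pair is a low-dye high-scatter phantom covering
# the low-absorption high-scattering corner.
calibration_anchors <- function() {
  list(scatter_only = c(3.0, 4.4, 6.4, 9.2, 13.2, 19.5),
       dye_anchor = c(4.4, 6.4, 9.2, 13.2, 19.8, 20.5),
       dye_peak = c(16, 22, 28, 38, 47, 3))
}

#' Generate the 12-phantom calibration set
#'
#' Builds the six scattering-only microsphere phantoms (C.P.1-6, anchored at
#' the printed band minima 3.0-19.5 cm\eqn{^{-1}} at 750 nm, bands spanning
#' roughly 3-26 cm\eqn{^{-1}} over 450-750 nm) and six microsphere+dye
#' phantoms (C.P.7-12) whose absorption spans 0-47 cm\eqn{^{-1}}, then
#' simulates their spectra at every configured SDS with the instrument
#' surrogate.
#'
#' @param seed RNG seed for the simulated measurements.
#' @param config an [instrument_config()].
#' @param wavelength_step_nm spectral decimation for the simulated spectra
#'   (default 2 nm; parameter recovery is insensitive to decimation).
#' @param noise simulate measurement noise?
#' @param table chromophore table (unused by these phantoms, kept for
#'   signature symmetry).
#' @return list with `phantoms` (12 [phantom_spec()]s), `properties`
#'   (per-phantom optical property lists), and `spectra`: per-SDS lists of
#'   calibrated absolute-reflectance `sdrs_spectrum` objects.
#' @export
generate_calibration_set <- function(seed = 1, config = instrument_config(),
                                     wavelength_step_nm = 2, noise = TRUE,
                                     table = load_chromophore_table()) {
  a <- calibration_anchors()
  specs <- c(
    lapply(seq_along(a$scatter_only), function(i)
      phantom_spec(paste0("C.P.", i),
                   solve_volume_fraction(a$scatter_only[i]))),
    lapply(seq_along(a$dye_anchor), function(i)
      phantom_spec(paste0("C.P.", i + 6),
                   solve_volume_fraction(a$dye_anchor[i]),
                   list(type = "dye", peak_mua = a$dye_peak[i])))
  )
  simulate_phantom_set(specs, seed, config, wavelength_step_nm, noise, table)
}

#' Generate the 3x3 hemoglobin validation set
#'
#' Nine phantoms (V.P.1-9) crossing three microsphere scattering levels with
#' three hemoglobin concentrations, chosen so that over the 500-750 nm fit
#' window every (\eqn{\mu_s'}, \eqn{\mu_a}) pair lies inside the LUT target
#' rectangle (5-26 and 0-10 cm\eqn{^{-1}}) while jointly spanning it.
#'
#' @inheritParams generate_calibration_set
#' @param sao2 oxygen saturation of the hemoglobin absorber (default 1).
#' @return same shape as [generate_calibration_set()].
#' @export
generate_validation_set <- function(seed = 2, config = instrument_config(),
                                    wavelength_step_nm = 2, noise = TRUE,
                                    sao2 = 1.0,
                                    table = load_chromophore_table()) {
  musp_anchor <- c(5.1, 9.5, 19.3)      # musp at 750 nm
  hb_levels <- c(1.0, 2.6, 5.0)         # mg/mL
  specs <- list(); k <- 0
  for (i in seq_along(musp_anchor)) for (j in seq_along(hb_levels)) {
    k <- k + 1
    specs[[k]] <- phantom_spec(paste0("V.P.", k),
                               solve_volume_fraction(musp_anchor[i]),
                               list(type = "hemoglobin",
                                    hb_conc = hb_levels[j], sao2 = sao2))
  }
  simulate_phantom_set(specs, seed, config, wavelength_step_nm, noise, table)
}

# simulate + calibrate a list of phantom specs at every configured SDS
simulate_phantom_set <- function(specs, seed, config, wavelength_step_nm,
                                 noise, table) {
  wl <- config_wavelengths(config, wavelength_step_nm)
  props <- lapply(specs, phantom_optical_properties, wavelengths = wl,
                  table = table)
  cfg <- config
  if (!noise) {
    cfg$noise_multiplicative_sigma <- 0
    cfg$noise_additive_sigma <- 0
  }
  spectra <- with_seed(seed, {
    out <- list()
    for (sds in config$sds_list) {
      out[[as.character(sds)]] <- lapply(seq_along(specs), function(i) {
        m <- simulate_measurement(props[[i]], sds, cfg, seed = NULL)
        s <- calibrate_measurement(m)
        s$metadata$phantom_id <- specs[[i]]$id
        s
      })
    }
    out
  })
  list(phantoms = specs, properties = props, spectra = spectra,
       wavelengths = wl, seed = seed)
}
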