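#' Instrument configuration
#'
#' Geometry, spectral sampling, averaging and noise settings of the synthetic
#' sDRS instrument. Defaults mirror the probe the package emulates: two
#' presented source-detector separations (374 and 730 um; the probe supports
#' up to four), 200 um fibers with NA 0.22, 450-750 nm spectral range, and
#' five averaged frames per measurement. Noise defaults are 1% multiplicative
#' plus a small additive dark term.
#'
#' @param sds_list source-detector separations, um, strictly increasing.
#' @param wavelength_range nm `c(min, max)`.
#' @param spectral_resolution_nm native spectral sampling, nm.
#' @param n_averages frames averaged per measurement (>= 1).
#' @param noise_multiplicative_sigma fractional multiplicative noise per frame.
#' @param noise_additive_sigma additive dark noise, counts per frame.
#' @param fiber_diameter_um,numerical_aperture probe fiber parameters (carried
#'   as metadata; the surrogate collapses them into a fixed collection constant).
#' @param gain,dark_counts,integration_ms raw-signal model settings.
#' @return an object of class `instrument_config`.
#' @export
instrument_config <- function(sds_list = c(374, 730),
                              wavelength_range = c(450, 750),
                              spectral_resolution_nm = 0.35,
                              n_averages = 5,
                              noise_multiplicative_sigma = 0.01,
                              noise_additive_sigma = 1,
                              fiber_diameter_um = 200,
                              numerical_aperture = 0.22,
                              gain = 1e6,
                              dark_counts = 100,
                              integration_ms = 400) {
  if (length(sds_list) < 1 || length(sds_list) > 4 || any(diff(sds_list) <= 0))
    stop_structural("sds_list must be 1-4 strictly increasing separations (um)")
  check_number(spectral_resolution_nm, "spectral_resolution_nm",
               lower = 0, strict_lower = TRUE)
  if (n_averages < 1) stop_domain("n_averages must be >= 1")
  structure(list(sds_list = sds_list,
                 wavelength_range = wavelength_range,
                 spectral_resolution_nm = spectral_resolution_nm,
                 n_averages = as.integer(n_averages),
                 noise_multiplicative_sigma = noise_multiplicative_sigma,
                 noise_additive_sigma = noise_additive_sigma,
                 fiber_diameter_um = fiber_diameter_um,
                 numerical_aperture = numerical_aperture,
                 gain = gain, dark_counts = dark_counts,
                 integration_ms = integration_ms),
            class = "instrument_config")
}

config_wavelengths <- function(config, step_nm = NULL) {
  step <- step_nm %||% config$spectral_resolution_nm
  seq(config$wavelength_range[1], config$wavelength_range[2], by = step)
}

# smooth broadband lamp shape (tungsten-halogen-like), peak-normalized
lamp_shape <- function(wavelengths) {
  l <- wavelengths * 1e-9
  b <- l^-5 / (exp(4.799e-6 / (l * 3000)) - 1)   # 3000 K Planck shape
  b / max(b)
}

# surrogate model constants (documented stand-in, not tissue physics)
.surrogate <- list(
  n_rel = 1.4,          # refractive-index mismatch for boundary reflection
  mus0 = 15,            # cm^-1, fixed scattering scale inside mu_eff
  collection = 0.01,    # dimensionless collection constant
  depth_c1 = 80.126,    # um scale of the depth model
  depth_c2 = 0.37257,   # SDS exponent
  depth_c3 = 0.039417,  # cm, attenuation weight
  depth_p = 1.5,        # stretch exponent of the saturating depth profile
  depth_ws = 0.05       # scattering weight inside the depth attenuation
)

#' Surrogate absolute reflectance of a semi-infinite medium
#'
#' Closed-form reflectance of the synthetic instrument at source-detector
#' separation `sds`. The form is a Farrell-type extrapolated-boundary dipole
#' whose transport depth is taken from scattering alone and whose effective
#' attenuation is decoupled from \eqn{\mu_s'}:
#' \deqn{R = k\,\frac{\mu_s'}{\mu_s'+\mu_a}\,\frac{1}{4\pi}
#'   \left[z_0 f(r_1) + (z_0 + 2 z_b) f(r_2)\right],\quad
#'   f(r) = (1+\mu_{eff} r)\,e^{-\mu_{eff} r}/r^3}
#' with \eqn{z_0 = 1/\mu_s'}, \eqn{z_b = 2A/(3\mu_s')} (internal-reflection
#' parameter `A` from a fixed 1.4/1.0 index mismatch),
#' \eqn{\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_{s0})}} with \eqn{\mu_{s0}}
#' fixed at 15 cm\eqn{^{-1}}, and collection constant `k = 0.01`. This is an
#' explicitly non-physical stand-in for the probe's empirical response
#' (diffusion theory is not valid at sub-diffuse separations): it is smooth,
#' strictly decreasing in \eqn{\mu_a} and strictly increasing in
#' \eqn{\mu_s'} over the lookup-table target range, which is what the
#' empirical LUT pipeline requires of a data source.
#'
#' @param musp reduced scattering, cm\eqn{^{-1}} (> 0); vectorized.
#' @param mua absorption, cm\eqn{^{-1}} (>= 0); vectorized.
#' @param sds source-detector separation, um (> 0).
#' @return absolute reflectance (dimensionless).
#' @export
surrogate_reflectance <- function(musp, mua, sds) {
  check_number(musp, "musp", lower = 0, strict_lower = TRUE)
  check_number(mua, "mua", lower = 0)
  check_number(sds, "sds", lower = 0, strict_lower = TRUE)
  s <- .surrogate
  rho <- sds * 1e-4                                  # um -> cm
  rd <- -1.440 / s$n_rel^2 + 0.710 / s$n_rel + 0.668 + 0.0636 * s$n_rel
  A <- (1 + rd) / (1 - rd)
  z0 <- 1 / musp
  zb <- 2 * A / (3 * musp)
  mueff <- sqrt(3 * mua * (mua + s$mus0))
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  f <- function(r) (1 + mueff * r) * exp(-mueff * r) / r^3
  s$collection * (musp / (musp + mua)) / (4 * pi) *
    (z0 * f(r1) + (z0 + 2 * zb) * f(r2))
}

# scale depth (um) of the saturating detected-photon profile
depth_scale <- function(musp, mua, sds) {
  s <- .surrogate
  att <- sqrt(3 * (mua + s$depth_ws * musp) * (mua + musp))
  s$depth_c1 * sds^s$depth_c2 / (1 + s$depth_c3 * att)
}

#' Cumulative detected-signal fraction above a depth
#'
#' Two-parameter saturating depth profile of the synthetic instrument:
#' \deqn{F(z) = 1 - \exp\!\left[-(z/z_s)^{p}\right]},
#' with stretch exponent `p = 1.5` and scale
#' \eqn{z_s = c_1\, sds^{c_2} / (1 + c_3\, \mu_{att})},
#' \eqn{\mu_{att} = \sqrt{3(\mu_a + 0.05\mu_s')(\mu_a + \mu_s')}}. The
#' constants are fixed package defaults chosen so the resulting
#' sampling-depth tables span a few hundred micrometres, deeper for the
#' longer separation, decreasing with absorption and scattering. `F(0) = 0`,
#' `F` is strictly increasing, and `F(z) -> 1` as `z` grows.
#'
#' @param musp,mua optical properties, cm\eqn{^{-1}}.
#' @param sds source-detector separation, um.
#' @param depth depth below the probe face, um (>= 0); vectorized.
#' @return fractions in `[0, 1]`.
#' @export
detected_depth_fraction <- function(musp, mua, sds, depth) {
  check_number(depth, "depth", lower = 0)
  zs <- depth_scale(musp, mua, sds)
  1 - exp(-(depth / zs)^.surrogate$depth_p)
}

#' Median sampling depth of the surrogate depth profile
#'
#' The depth above which half of the detected signal originates:
#' \eqn{D_{50} = z_s (\ln 2)^{1/p}}. This is the generator-side ground truth
#' recovered by the translation-curve estimator.
#'
#' @inheritParams detected_depth_fraction
#' @return median depths, um.
#' @export
sampling_depth_median <- function(musp, mua, sds) {
  depth_scale(musp, mua, sds) * log(2)^(1 / .surrogate$depth_p)
}

#' Layered sample specification
#'
#' An ordered stack of homogeneous layers over a semi-infinite base. Each
#' layer is a list with `thickness_um` (or `Inf` for the base), `musp` and
#' `mua` (scalars or per-wavelength vectors, cm\eqn{^{-1}}).
#'
#' @param layers list of layers, top first; exactly the last layer must have
#'   infinite thickness.
#' @return an object of class `layered_sample`.
#' @export
layered_sample <- function(layers) {
  if (length(layers) < 1) stop_structural("at least one layer required")
  th <- vapply(layers, function(l) l$thickness_um, numeric(1))
  if (!is.infinite(th[length(th)]))
    stop_structural("bottom layer must be semi-infinite (thickness_um = Inf)")
  if (any(is.infinite(th[-length(th)])))
    stop_structural("only the bottom layer may be semi-infinite")
  if (any(th <= 0)) stop_structural("layer thicknesses must be > 0")
  structure(list(layers = layers), class = "layered_sample")
}

#' Two-layer (layered) reflectance simulation
#'
#' Reflectance of a layered sample from depth-weighted effective properties:
#' layer weights are increments of the detected-depth profile
#' \eqn{w_i = F(z_{bottom,i}) - F(z_{top,i})} evaluated with the *top* layer's
#' properties, and the effective \eqn{\mu_s'}, \eqn{\mu_a} are the
#' weight-averaged layer properties, fed through the semi-infinite surrogate.
#' The weighted \eqn{\mu_s'} is returned as the ground-truth volume-averaged
#' scattering oracle.
#'
#' @param sample a [layered_sample()] with 1-3 finite layers over the base.
#' @param sds source-detector separation, um.
#' @param wavelengths nm grid on which layer properties are defined.
#' @return list with `wavelengths`, `reflectance`, `musp_va` (volume-averaged
#'   \eqn{\mu_s'} oracle), `mua_va`, and the weight matrix `weights`
#'   (layers x wavelengths).
#' @export
simulate_two_layer <- function(sample, sds, wavelengths) {
  stopifnot(inherits(sample, "layered_sample"))
  nl <- length(sample$layers)
  if (nl < 2 || nl > 4)
    stop_structural("sample must have 1-3 finite layers over the base")
  nw <- length(wavelengths)
  get_prop <- function(l, field) rep_len(l[[field]], nw)
  musp_l <- t(vapply(sample$layers, get_prop, numeric(nw), field = "musp"))
  mua_l <- t(vapply(sample$layers, get_prop, numeric(nw), field = "mua"))
  th <- vapply(sample$layers, function(l) l$thickness_um, numeric(1))
  zb <- cumsum(th)                       # layer bottoms (last Inf)
  zt <- c(0, zb[-nl])                    # layer tops
  w <- matrix(NA_real_, nl, nw)
  for (j in seq_len(nw)) {
    Fz <- function(z) ifelse(is.infinite(z), 1,
                             detected_depth_fraction(musp_l[1, j], mua_l[1, j],
                                                     sds, z))
    w[, j] <- vapply(seq_len(nl), function(i) Fz(zb[i]) - Fz(zt[i]),
                     numeric(1))
  }
  musp_va <- colSums(w * musp_l)
  mua_va <- colSums(w * mua_l)
  list(wavelengths = wavelengths,
       reflectance = surrogate_reflectance(musp_va, mua_va, sds),
       musp_va = musp_va, mua_va = mua_va, weights = w)
}

#' Simulate a probe-translation curve
#'
#' Reflectance versus distance between the probe tip and a highly absorbing
#' boundary, from 0 to 2 mm in 50 um steps by default:
#' `R(d) = R_semi_infinite * F(d)` per wavelength, with the instrument noise
#' model applied when `noise = TRUE`. The contact point `d = 0` carries no
#' specular contribution (specular reflection is treated as negligible).
#'
#' @param props list with `wavelengths`, `musp`, `mua` (the phantom's
#'   per-wavelength optical properties).
#' @param sds source-detector separation, um.
#' @param config an [instrument_config()].
#' @param distances_um translation distances, um.
#' @param noise apply the measurement noise model?
#' @param seed RNG seed for the noisy path (required if `noise = TRUE`).
#' @return an object of class `translation_curve`: list with `distances_um`,
#'   `wavelengths`, `reflectance` (distances x wavelengths matrix), `sds`.
#' @export
simulate_translation_curve <- function(props, sds, config = instrument_config(),
                                       distances_um = seq(0, 2000, by = 50),
                                       noise = FALSE, seed = NULL) {
  if (any(diff(distances_um) <= 0))
    stop_structural("distances must be strictly increasing")
  wl <- props$wavelengths
  rsemi <- surrogate_reflectance(props$musp, props$mua, sds)
  Fmat <- vapply(seq_along(wl), function(j)
    detected_depth_fraction(props$musp[j], props$mua[j], sds, distances_um),
    numeric(length(distances_um)))
  R <- sweep(Fmat, 2, rsemi, `*`)
  if (noise) {
    R <- with_seed(seed, {
      out <- R
      for (i in seq_along(distances_um)) {
        m <- simulate_measurement(list(wavelengths = wl,
                                       musp = props$musp, mua = props$mua),
                                  sds, config, seed = NULL,
                                  reflectance = R[i, ])
        out[i, ] <- calibrate_measurement(m)$value
      }
      out
    })
  }
  structure(list(distances_um = distances_um, wavelengths = wl,
                 reflectance = R, sds = sds),
            class = "translation_curve")
}

#' Simulate a raw measurement with paired standard and background frames
#'
#' Raw detector counts for a sample, `counts = gain * R * lamp(lambda) + dark
#' + noise`, averaged over `n_averages` frames, together with a paired
#' Spectralon-standard frame (20% flat reflectance) and a dark background
#' frame generated under the same lamp shape, so absolute calibration cancels
#' the lamp. Noise per frame is multiplicative (fraction
#' `noise_multiplicative_sigma` of the signal) plus additive dark noise.
#'
#' @param props either a list with `wavelengths`, `musp`, `mua`, or a
#'   [layered_sample()] (then `wavelengths` must be supplied via
#'   `props$wavelengths` of the layered simulation; see
#'   [simulate_two_layer()]).
#' @param sds source-detector separation, um.
#' @param config an [instrument_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param wavelengths optional nm grid (defaults to the instrument grid).
#' @param reflectance optional precomputed true reflectance (overrides props).
#' @param lamp_values optional strictly positive lamp spectrum (one value per
#'   wavelength) replacing the built-in tungsten-halogen shape; calibration
#'   against the paired standard frame cancels any such shape.
#' @return list of three `sdrs_spectrum` objects: `sample`, `background`,
#'   `standard`, plus `true_reflectance`.
#' @export
simulate_measurement <- function(props, sds, config = instrument_config(),
                                 seed = NULL, wavelengths = NULL,
                                 reflectance = NULL, lamp_values = NULL) {
  wl <- wavelengths %||% props$wavelengths %||% config_wavelengths(config)
  if (is.null(reflectance)) {
    if (inherits(props, "layered_sample")) {
      reflectance <- simulate_two_layer(props, sds, wl)$reflectance
    } else {
      reflectance <- surrogate_reflectance(rep_len(props$musp, length(wl)),
                                           rep_len(props$mua, length(wl)), sds)
    }
  }
  lamp <- lamp_values %||% lamp_shape(wl)
  if (any(lamp <= 0)) stop_domain("lamp_values must be strictly positive")
  with_seed(seed, {
    frame <- function(signal) {
      acc <- 0
      for (i in seq_len(config$n_averages)) {
        acc <- acc + signal * (1 + stats::rnorm(length(wl), 0,
                                  config$noise_multiplicative_sigma)) +
          config$dark_counts +
          stats::rnorm(length(wl), 0, config$noise_additive_sigma)
      }
      acc / config$n_averages
    }
    mk <- function(values, kind) spectrum(wl, values, kind = kind, sds = sds,
                                          integration_ms = config$integration_ms)
    list(sample = mk(frame(config$gain * reflectance * lamp), "raw"),
         background = mk(frame(0 * wl), "background"),
         standard = mk(frame(config$gain * 0.20 * lamp), "standard"),
         true_reflectance = reflectance)
  })
}

# convenience: absolute reflectance from a simulate_measurement() triple
calibrate_measurement <- function(m, standard_reflectance = 0.20) {
  to_absolute_reflectance(m$sample, m$background, m$standard,
                          standard_reflectance)
}
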