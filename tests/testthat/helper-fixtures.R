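# shared fixtures, built lazily once per test run
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_table <- function() fx("table", function() load_chromophore_table())

fx_config0 <- function() instrument_config(noise_multiplicative_sigma = 0,
                                           noise_additive_sigma = 0)

# noiseless calibration set at 2 nm decimation
fx_cal0 <- function() fx("cal0", function()
  generate_calibration_set(42, fx_config0(), wavelength_step_nm = 2,
                           noise = FALSE, table = fx_table()))

# noiseless reflectance LUTs at the full 0.02 cm^-1 resolution
fx_luts0 <- function() fx("luts0", function()
  build_luts_from_calibration(fx_cal0(), step = 0.02))

# noiseless sampling-depth records and LUTs (coarser, for speed)
fx_depth_records <- function() fx("depth_records", function() {
  wl <- config_wavelengths(fx_config0(), 8)
  a <- sdrslut:::calibration_anchors()
  out <- list()
  for (sds in c(374, 730)) {
    out[[as.character(sds)]] <- lapply(seq_along(a$dye_anchor), function(i) {
      spec <- phantom_spec(paste0("C.P.", i + 6),
                          solve_volume_fraction(a$dye_anchor[i]),
                          list(type = "dye", peak_mua = a$dye_peak[i]))
      props <- phantom_optical_properties(spec, wl, fx_table())
      curve <- simulate_translation_curve(props, sds, fx_config0())
      est <- estimate_sampling_depth(curve, on_fail = "na")
      list(props = props, depth_um = est$depth_um, id = spec$id)
    })
  }
  out
})

fx_depth_luts <- function() fx("depth_luts", function() {
  rec <- fx_depth_records()
  lapply(stats::setNames(nm = names(rec)), function(sds)
    build_sampling_depth_lut(rec[[sds]], as.numeric(sds), step = 0.1))
})

# independent Lorenz-Mie oracle built on half-integer-order Bessel functions
# (base R besselJ/besselY), a different route than the package's downward
# log-derivative recurrence; valid for real relative index
mie_bessel_oracle <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  n <- 1:nmax
  sj <- function(ord, z) sqrt(pi / (2 * z)) * besselJ(z, ord + 0.5)
  sy <- function(ord, z) sqrt(pi / (2 * z)) * besselY(z, ord + 0.5)
  psi <- x * sj(n, x);  psi0 <- x * sj(n - 1, x)
  chi <- -x * sy(n, x); chi0 <- -x * sy(n - 1, x)
  mpsi <- (m * x) * sj(n, m * x); mpsi0 <- (m * x) * sj(n - 1, m * x)
  dpsi <- psi0 - n / x * psi
  dchi <- chi0 - n / x * chi
  dmpsi <- mpsi0 - n / (m * x) * mpsi
  xi <- complex(real = psi, imaginary = -chi)
  dxi <- complex(real = dpsi, imaginary = -dchi)
  an <- (m * dmpsi * psi - mpsi * dpsi) / (m * dmpsi * xi - mpsi * dxi)
  bn <- (dmpsi * psi - m * mpsi * dpsi) / (dmpsi * xi - m * mpsi * dxi)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  k <- n[-nmax]
  g <- (4 / (x^2 * qsca)) *
    (sum(k * (k + 2) / (k + 1) *
           Re(an[k] * Conj(an[k + 1]) + bn[k] * Conj(bn[k + 1]))) +
       sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn))))
  c(qsca = qsca, g = g)
}

# a tiny synthetic LUT with prescribed node values, for lookup contracts
toy_lut <- function(values, musp_axis = seq(5, 7, by = 1),
                    mua_axis = seq(0, 2, by = 1), sds = 374,
                    kind = "reflectance") {
  structure(list(musp_axis = musp_axis, mua_axis = mua_axis,
                 values = values, sds = sds, kind = kind,
                 provenance = list(schema_version = "1")),
            class = "sdrs_lut")
}
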