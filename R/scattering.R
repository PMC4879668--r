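#' Power-law reduced scattering spectrum
#'
#' Evaluates the scattering power law
#' \deqn{\mu_s'(\lambda) = \mu_s'(\lambda_0)\,(\lambda/\lambda_0)^{-B}}
#' with reference wavelength `lambda_ref` (630 nm by default) and scattering
#' exponent `B`. `B > 0` gives the usual monotone decrease of scattering with
#' wavelength; the law is exact at the reference wavelength for any `B`.
#'
#' @param musp_ref reduced scattering coefficient at `lambda_ref`, cm\eqn{^{-1}} (> 0).
#' @param B dimensionless scattering exponent.
#' @param wavelengths nm grid (> 0).
#' @param lambda_ref reference wavelength, nm (default 630).
#' @return reduced scattering coefficients, cm\eqn{^{-1}}.
#' @export
power_law_musp <- function(musp_ref, B, wavelengths, lambda_ref = 630) {
  check_number(musp_ref, "musp_ref", lower = 0, strict_lower = TRUE)
  check_number(B, "B")
  check_number(wavelengths, "wavelengths", lower = 0, strict_lower = TRUE)
  check_number(lambda_ref, "lambda_ref", lower = 0, strict_lower = TRUE)
  musp_ref * (wavelengths / lambda_ref)^(-B)
}

# dispersion constant sets; wavelengths in nm inside the formulas
.dispersion <- list(
  # two-term Cauchy fit for polystyrene, lambda in micrometres
  polystyrene = function(lam_nm) {
    lu <- lam_nm / 1000
    1.5725 + 0.0031080 / lu^2 + 0.00034779 / lu^4
  },
  # four-term fit for water, lambda in nm
  water = function(lam_nm) {
    1.3199 + 6878 / lam_nm^2 - 1.132e9 / lam_nm^4 + 1.11e14 / lam_nm^6
  }
)

#' Refractive index of phantom materials
#'
#' Real refractive index from documented dispersion fits: a two-term Cauchy
#' formula for polystyrene and a four-term formula for water. Both give
#' normal dispersion (index decreasing with wavelength) over 400-800 nm.
#'
#' @param material `"polystyrene"` or `"water"`.
#' @param wavelengths nm grid.
#' @return refractive indices, one per wavelength.
#' @export
refractive_index <- function(material, wavelengths) {
  f <- .dispersion[[material]]
  if (is.null(f))
    stop_structural("unknown material '", material, "'; available: ",
                    paste(names(.dispersion), collapse = ", "))
  check_number(wavelengths, "wavelengths", lower = 0, strict_lower = TRUE)
  f(wavelengths)
}

#' Lorenz-Mie scattering efficiency and anisotropy
#'
#' Scattering efficiency \eqn{Q_{sca}} and anisotropy factor \eqn{g} of a
#' homogeneous sphere from the Lorenz-Mie partial-wave series, truncated at
#' the Wiscombe criterion \eqn{n_{max} = \lceil x + 4x^{1/3} + 2\rceil}. The
#' logarithmic derivative is evaluated by downward recurrence (started 15
#' orders above the truncation), the Riccati-Bessel functions by upward
#' recurrence.
#'
#' @param size_param dimensionless size parameter `x = pi * d * n_medium / lambda` (> 0).
#' @param rel_index relative refractive index `m = n_sphere / n_medium`
#'   (real or complex with non-negative imaginary part).
#' @return named numeric vector `c(qsca, g)`.
#' @export
mie_efficiencies <- function(size_param, rel_index) {
  x <- size_param
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stop_domain("size_param must be a single value > 0")
  m <- rel_index
  if (length(m) != 1 || is.na(m) || !is.finite(Mod(m)))
    stop_domain("rel_index must be a single finite value")
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  # start the downward recurrence well above both the truncation order and
  # |mx|, where the continued fraction has fully converged
  nstart <- max(nmax, ceiling(Mod(mx))) + 20
  D <- complex(length.out = nstart + 1)            # D[n + 1] holds D_n
  for (n in nstart:1) D[n] <- (n / mx) - 1 / (D[n + 1] + n / mx)
  if (any(!is.finite(Re(D[seq_len(nmax + 1)]))))
    stop("Mie logarithmic-derivative recurrence did not converge (x = ",
         x, ", m = ", format(m), ")")
  psi <- numeric(nmax + 1); chi <- numeric(nmax + 1)  # order n at index n + 1
  psi_m1 <- cos(x); chi_m1 <- -sin(x)                 # order -1 seeds
  psi[1] <- sin(x); chi[1] <- cos(x)
  for (n in 1:nmax) {
    pm2 <- if (n == 1) psi_m1 else psi[n - 1]
    cm2 <- if (n == 1) chi_m1 else chi[n - 1]
    psi[n + 1] <- (2 * n - 1) / x * psi[n] - pm2
    chi[n + 1] <- (2 * n - 1) / x * chi[n] - cm2
  }
  xi <- complex(real = psi, imaginary = -chi)
  n <- seq_len(nmax)
  Dn <- D[n + 1]
  fa <- Dn / m + n / x
  fb <- Dn * m + n / x
  an <- (fa * psi[n + 1] - psi[n]) / (fa * xi[n + 1] - xi[n])
  bn <- (fb * psi[n + 1] - psi[n]) / (fb * xi[n + 1] - xi[n])
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  k <- n[-nmax]
  t1 <- sum(k * (k + 2) / (k + 1) *
              Re(an[k] * Conj(an[k + 1]) + bn[k] * Conj(bn[k + 1])))
  t2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn)))
  g <- (4 / (x^2 * qsca)) * (t1 + t2)
  c(qsca = qsca, g = g)
}

#' Microsphere suspension specification
#'
#' A dilute aqueous suspension of polystyrene microspheres, the scattering
#' agent of the calibration and validation phantoms. `cv` is the coefficient
#' of variation of the sphere diameter; manufacturer lots are not perfectly
#' monodisperse, and the small default spread also smooths the Mie ripple
#' structure so that \eqn{\mu_s'(\lambda)} decreases strictly with wavelength.
#'
#' @param diameter_um nominal sphere diameter, micrometres (> 0; default 1.0).
#' @param volume_fraction sphere volume fraction, in (0, 0.05): the dilute
#'   independent-scattering regime.
#' @param cv diameter coefficient of variation (default 0.03).
#' @param sphere_material,medium_material dispersion identifiers.
#' @return an object of class `microsphere_suspension`.
#' @export
microsphere_suspension <- function(diameter_um = 1.0, volume_fraction,
                                   cv = 0.03,
                                   sphere_material = "polystyrene",
                                   medium_material = "water") {
  check_number(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  if (!is.numeric(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 0.05)
    stop_domain("volume_fraction must lie in (0, 0.05), the dilute regime")
  check_number(cv, "cv", lower = 0)
  structure(list(diameter_um = diameter_um,
                 volume_fraction = volume_fraction, cv = cv,
                 sphere_material = sphere_material,
                 medium_material = medium_material),
            class = "microsphere_suspension")
}

# per-unit-volume-fraction musp (cm^-1) of a suspension at given wavelengths;
# quadrature over the diameter distribution (equal-probability normal nodes)
musp_per_vf <- function(suspension, wavelengths, nq = 7) {
  d0 <- suspension$diameter_um
  cv <- suspension$cv
  ds <- if (cv > 0) d0 * (1 + cv * stats::qnorm(seq(0.5 / nq, 1 - 0.5 / nq,
                                                    length.out = nq))) else d0
  n_med <- refractive_index(suspension$medium_material, wavelengths)
  n_sph <- refractive_index(suspension$sphere_material, wavelengths)
  vapply(seq_along(wavelengths), function(i) {
    lam_um <- wavelengths[i] / 1000
    # reduced scattering cross-section per unit sphere volume, averaged over
    # the size distribution at fixed total volume fraction (N_i ~ 1/d^3)
    mean(vapply(ds, function(d) {
      x <- pi * d * n_med[i] / lam_um
      ef <- mie_efficiencies(x, n_sph[i] / n_med[i])
      ef[["qsca"]] * (1 - ef[["g"]]) * (pi / 4 * (d * 1e-4)^2) /
        (pi / 6 * (d * 1e-4)^3)
    }, numeric(1)))
  }, numeric(1))
}

#' Reduced scattering spectrum of a microsphere suspension
#'
#' Mie-theory reduced scattering coefficient
#' \eqn{\mu_s' = N \cdot (\pi d^2/4) \, Q_{sca} (1 - g)} with number density
#' `N` from the volume fraction, evaluated with wavelength-dependent
#' refractive indices of sphere and medium. Exactly linear in the volume
#' fraction (independent scattering).
#'
#' @param suspension a [microsphere_suspension()].
#' @param wavelengths nm grid.
#' @return reduced scattering coefficients, cm\eqn{^{-1}}.
#' @export
microsphere_musp <- function(suspension, wavelengths) {
  stopifnot(inherits(suspension, "microsphere_suspension"))
  check_number(wavelengths, "wavelengths", lower = 0, strict_lower = TRUE)
  suspension$volume_fraction * musp_per_vf(suspension, wavelengths)
}

#' Solve the volume fraction that yields a target scattering level
#'
#' Bisection on the (exactly linear) volume-fraction dependence of
#' \eqn{\mu_s'}; used by the calibration recipe generator to anchor each
#' suspension's \eqn{\mu_s'} at a stated wavelength.
#'
#' @param target_musp target reduced scattering, cm\eqn{^{-1}}.
#' @param at_wavelength anchor wavelength, nm (default 750).
#' @param diameter_um,cv sphere population parameters.
#' @return a [microsphere_suspension()] hitting the target.
#' @export
solve_volume_fraction <- function(target_musp, at_wavelength = 750,
                                  diameter_um = 1.0, cv = 0.03) {
  check_number(target_musp, "target_musp", lower = 0, strict_lower = TRUE)
  base <- microsphere_suspension(diameter_um, 1e-3, cv)
  per <- musp_per_vf(base, at_wavelength)
  f <- function(vf) vf * per - target_musp
  lo <- 1e-8; hi <- 0.049
  if (f(hi) < 0) stop_domain("target_musp unreachable in the dilute regime")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-15) break
  }
  microsphere_suspension(diameter_um, (lo + hi) / 2, cv)
}
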