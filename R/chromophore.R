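#' Load a hemoglobin molar-extinction table
#'
#' Reads a chromophore table with columns `wavelength_nm`, `eps_oxy`,
#' `eps_deoxy` (base-10 molar extinction, cm\eqn{^{-1}} M\eqn{^{-1}}). With no
#' argument, loads the table shipped with the package:
#' `hemoglobin_extinction_synthetic.csv`, a *synthetic* hemoglobin-like
#' spectrum generated from a documented parametric model (Soret and Q-band
#' Gaussians plus red tails) that reproduces the canonical features of adult
#' hemoglobin - Q-band peaks near 542/577 nm (oxy) and 555 nm (deoxy),
#' isosbestic crossings, and a deoxy/oxy extinction ratio far above 1 near
#' 630 nm. It is not a measured compilation; because the same table is used
#' to generate and to fit synthetic spectra, pipeline round trips are
#' unaffected by its deviation from measured hemoglobin.
#'
#' @param path CSV file path, or `NULL` for the packaged table.
#' @param molecular_weight hemoglobin gram molecular weight, g/mol.
#' @return An object of class `chromophore_table`: list with `wavelength`,
#'   `eps_oxy`, `eps_deoxy`, `molecular_weight`.
#' @export
load_chromophore_table <- function(path = NULL, molecular_weight = 64500) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                        package = "sdrslut", mustWork = TRUE)
  }
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_oxy", "eps_deoxy")
  if (!all(need %in% names(df)))
    stop_structural("chromophore table must have columns ",
                    paste(need, collapse = ", "))
  if (any(diff(df$wavelength_nm) <= 0))
    stop_structural("chromophore wavelengths must be strictly increasing")
  if (any(df$eps_oxy < 0) || any(df$eps_deoxy < 0))
    stop_domain("extinction values must be >= 0")
  structure(list(wavelength = df$wavelength_nm,
                 eps_oxy = df$eps_oxy,
                 eps_deoxy = df$eps_deoxy,
                 molecular_weight = molecular_weight),
            class = "chromophore_table")
}

#' Write a chromophore table to CSV
#'
#' @param table a `chromophore_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromophore_table <- function(table, path) {
  stopifnot(inherits(table, "chromophore_table"))
  utils::write.csv(data.frame(wavelength_nm = table$wavelength,
                              eps_oxy = table$eps_oxy,
                              eps_deoxy = table$eps_deoxy),
                   path, row.names = FALSE)
  invisible(path)
}

# interpolate extinction onto a requested grid; range error outside the table
extinction_at <- function(table, wavelengths) {
  rng <- range(table$wavelength)
  if (any(wavelengths < rng[1]) || any(wavelengths > rng[2]))
    stop_range("requested wavelengths outside chromophore table range [",
               rng[1], ", ", rng[2], "] nm")
  list(oxy = linear_interp(table$wavelength, table$eps_oxy, wavelengths),
       deoxy = linear_interp(table$wavelength, table$eps_deoxy, wavelengths))
}

#' Hemoglobin absorption coefficient
#'
#' Beer-Lambert absorption of a two-state (oxy/deoxy) hemoglobin solution,
#' base-10 extinction convention with an explicit ln(10) factor:
#' \deqn{\mu_a(\lambda) = \ln(10)\, C_M \,[\alpha\,\varepsilon_{oxy}(\lambda)
#'   + (1-\alpha)\,\varepsilon_{deoxy}(\lambda)]}
#' where the molar concentration is `C_M = hb_conc / MW`: a concentration in
#' mg/mL is numerically a mass density in g/L, so dividing by the gram
#' molecular weight (default 64,500 g/mol) gives mol/L directly. `alpha` is
#' the oxygen saturation fraction.
#'
#' @param hb_conc hemoglobin concentration, mg/mL (>= 0).
#' @param sao2 oxygen saturation fraction in `[0, 1]`.
#' @param wavelengths nm grid, must lie within the table range.
#' @param table a `chromophore_table` (default: packaged table).
#' @return absorption coefficients, cm\eqn{^{-1}}, one per wavelength.
#' @export
hemoglobin_mu_a <- function(hb_conc, sao2, wavelengths,
                            table = load_chromophore_table()) {
  check_number(hb_conc, "hb_conc", lower = 0)
  check_number(sao2, "sao2", lower = 0, upper = 1)
  check_number(wavelengths, "wavelengths", lower = 0, strict_lower = TRUE)
  eps <- extinction_at(table, wavelengths)
  molar <- hb_conc / table$molecular_weight   # mg/mL == g/L -> mol/L
  log(10) * molar * (sao2 * eps$oxy + (1 - sao2) * eps$deoxy)
}

#' Absorption coefficient from spectrophotometer absorbance
#'
#' Converts base-10 absorbance measured over a known cuvette pathlength to an
#' absorption coefficient: `mu_a = ln(10) * A / pathlength`.
#'
#' @param absorbance base-10 absorbance values (>= 0).
#' @param pathlength_cm cuvette pathlength, cm (> 0).
#' @return absorption coefficients, cm\eqn{^{-1}}.
#' @export
mu_a_from_absorbance <- function(absorbance, pathlength_cm) {
  check_number(absorbance, "absorbance", lower = 0)
  check_number(pathlength_cm, "pathlength_cm", lower = 0, strict_lower = TRUE)
  log(10) * absorbance / pathlength_cm
}

#' Isosbestic wavelengths of a chromophore table
#'
#' Locates wavelengths where the oxy and deoxy extinction curves cross
#' (linear interpolation between table rows). At an isosbestic wavelength the
#' hemoglobin absorption coefficient is independent of oxygen saturation.
#'
#' @param table a `chromophore_table`.
#' @param window optional `c(min, max)` nm restriction.
#' @return numeric vector of crossing wavelengths, nm.
#' @export
isosbestic_wavelengths <- function(table = load_chromophore_table(),
                                   window = NULL) {
  w <- table$wavelength
  d <- table$eps_oxy - table$eps_deoxy
  if (!is.null(window)) {
    keep <- w >= window[1] & w <= window[2]
    w <- w[keep]; d <- d[keep]
  }
  i <- which(d[-length(d)] * d[-1] < 0)
  cross <- w[i] - d[i] * (w[i + 1] - w[i]) / (d[i + 1] - d[i])
  exact <- w[d == 0]
  sort(unique(c(cross, exact)))
}
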