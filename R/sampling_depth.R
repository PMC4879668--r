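#' Estimate sampling depth from a translation curve
#'
#' Implements the 50%-photon criterion: for each wavelength, the reflectance
#' versus probe-to-absorber distance curve is normalized by its plateau (the
#' mean of the last three distances) and the sampling depth is the linearly
#' interpolated distance of the first upward crossing of the normalized
#' fraction through 0.5. The plateau must be settled: if the last three
#' points spread by more than 1% of the plateau *and* are still rising, a
#' plateau error is raised; a spread above 1% without a rising trend is
#' flagged in `qc`. An optional 3-point running-median pre-filter (off by
#' default) robustifies noisy curves and is recorded in `qc` when used.
#'
#' @param curve a `translation_curve` (see [simulate_translation_curve()])
#'   with at least 10 distances including 0 and a plateau region.
#' @param median_filter apply a 3-point median pre-filter along distance?
#' @param on_fail `"error"` (default) raises the plateau/estimation errors;
#'   `"na"` records `NA` with a QC flag for the offending wavelengths
#'   instead, so batch pipelines can drop wavelengths whose signal is too
#'   dim to settle (e.g. under extreme dye absorption).
#' @return an object of class `depth_estimate`: list with `wavelengths`,
#'   `depth_um`, `plateau`, `qc` (character flags per wavelength), `sds`.
#' @export
estimate_sampling_depth <- function(curve, median_filter = FALSE,
                                    on_fail = c("error", "na")) {
  on_fail <- match.arg(on_fail)
  stopifnot(inherits(curve, "translation_curve"))
  d <- curve$distances_um
  if (length(d) < 10 || d[1] != 0)
    stop_structural("curve needs >= 10 distances starting at 0")
  R <- curve$reflectance
  if (median_filter) R <- apply(R, 2, stats::runmed, k = 3)
  nd <- length(d)
  last3 <- (nd - 2):nd
  nw <- ncol(R)
  depth <- plateau <- numeric(nw)
  qc <- character(nw)
  for (j in seq_len(nw)) {
    tail3 <- R[last3, j]
    plateau[j] <- mean(tail3)
    spread <- (max(tail3) - min(tail3)) / plateau[j]
    if (spread > 0.01) {
      if (all(diff(tail3) > 0)) {
        if (on_fail == "error")
          stop("plateau error: curve still rising at the last distances ",
               "(wavelength ", curve$wavelengths[j], " nm, spread ",
               sprintf("%.2f%%", 100 * spread), ")")
        depth[j] <- NA_real_
        qc[j] <- "plateau_not_reached"
        next
      }
      qc[j] <- "plateau_spread"
    }
    f <- R[, j] / plateau[j]
    above <- which(f >= 0.5)
    if (!length(above)) {
      if (on_fail == "error")
        stop("sampling-depth estimation error: normalized curve never ",
             "reaches 0.5 (wavelength ", curve$wavelengths[j], " nm)")
      depth[j] <- NA_real_
      qc[j] <- "no_crossing"
      next
    }
    k <- above[1]
    if (k == 1) {
      depth[j] <- d[1]
    } else {
      depth[j] <- d[k - 1] + (0.5 - f[k - 1]) / (f[k] - f[k - 1]) *
        (d[k] - d[k - 1])
    }
    if (median_filter) qc[j] <- paste(qc[j], "median_filtered", sep = ";")
  }
  structure(list(wavelengths = curve$wavelengths, depth_um = depth,
                 plateau = plateau, qc = qc, sds = curve$sds),
            class = "depth_estimate")
}

#' Check that specular reflection at contact is negligible
#'
#' Passes when the contact-point reflectance `R(0)` is below 2% of the
#' plateau at every wavelength.
#'
#' @param contact_curve a `translation_curve` including distance 0.
#' @return list with `pass` (logical) and `contact_ratio` per wavelength.
#' @export
check_specular_negligible <- function(contact_curve) {
  stopifnot(inherits(contact_curve, "translation_curve"))
  d <- contact_curve$distances_um
  if (d[1] != 0) stop_structural("curve must include the contact point d = 0")
  nd <- length(d)
  plateau <- colMeans(contact_curve$reflectance[(nd - 2):nd, , drop = FALSE])
  ratio <- contact_curve$reflectance[1, ] / plateau
  list(pass = all(ratio < 0.02), contact_ratio = ratio)
}

#' Percent error between estimated and reference depths
#'
#' `100 * |estimated - reference| / reference`, vectorized.
#'
#' @param estimated,reference depths, um; `reference` must be > 0.
#' @return percent errors.
#' @export
depth_percent_error <- function(estimated, reference) {
  check_number(reference, "reference", lower = 0, strict_lower = TRUE)
  100 * abs(estimated - reference) / reference
}

#' Export a depth estimate as CSV
#'
#' @param estimate a `depth_estimate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "depth_estimate"))
  utils::write.csv(data.frame(wavelength_nm = estimate$wavelengths,
                              depth_um = estimate$depth_um,
                              plateau = estimate$plateau,
                              qc_flags = estimate$qc),
                   path, row.names = FALSE)
  invisible(path)
}
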