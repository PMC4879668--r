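#' Spectrum container
#'
#' A single-channel spectrum: a strictly increasing wavelength grid with one
#' value per wavelength (raw counts, background or standard counts, or
#' absolute reflectance), channel geometry and integration time.
#'
#' @param wavelengths nm grid, strictly increasing.
#' @param values counts or absolute reflectance, one per wavelength.
#' @param kind one of `"raw"`, `"background"`, `"standard"`, `"absolute"`.
#' @param sds source-detector separation, um.
#' @param integration_ms integration time, ms.
#' @param metadata optional named list.
#' @return an object of class `sdrs_spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("raw", "background", "standard", "absolute"),
                     sds, integration_ms = 400, metadata = list()) {
  kind <- match.arg(kind)
  if (length(wavelengths) != length(values))
    stop_structural("wavelengths and values must have equal length")
  if (length(wavelengths) == 0) stop_structural("empty spectrum")
  if (any(diff(wavelengths) <= 0))
    stop_structural("wavelengths must be strictly increasing")
  if (kind == "absolute" && any(values < 0))
    stop_domain("absolute reflectance must be >= 0")
  structure(list(wavelengths = as.numeric(wavelengths),
                 value = as.numeric(values), kind = kind, sds = sds,
                 integration_ms = integration_ms, metadata = metadata),
            class = "sdrs_spectrum")
}

#' @export
print.sdrs_spectrum <- function(x, ...) {
  cat(sprintf("<sdrs_spectrum> %s, SDS %g um, %d points (%g-%g nm)\n",
              x$kind, x$sds, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Convert raw counts to absolute reflectance
#'
#' Calibration against a diffuse reflectance standard:
#' \deqn{R(\lambda) = R_{std}\,\frac{S(\lambda) - B(\lambda)}
#'   {Std(\lambda) - B(\lambda)}}
#' with the 20% Spectralon standard by default. Wavelengths where the
#' standard-minus-background denominator falls below five times the additive
#' noise floor are flagged in the result metadata.
#'
#' @param sample,background,standard `sdrs_spectrum` objects sharing grid and
#'   SDS (`raw`, `background`, `standard` kinds).
#' @param standard_reflectance reflectance of the standard (default 0.20).
#' @param noise_floor additive noise floor in counts used for the low-signal
#'   flag (default 2).
#' @return an `sdrs_spectrum` of kind `"absolute"`; `metadata$low_signal`
#'   holds flagged wavelength indices.
#' @export
to_absolute_reflectance <- function(sample, background, standard,
                                    standard_reflectance = 0.20,
                                    noise_floor = 2) {
  for (s in list(sample, background, standard))
    stopifnot(inherits(s, "sdrs_spectrum"))
  if (!isTRUE(all.equal(sample$wavelengths, background$wavelengths)) ||
      !isTRUE(all.equal(sample$wavelengths, standard$wavelengths)))
    stop_structural("sample, background and standard must share one grid")
  if (sample$sds != background$sds || sample$sds != standard$sds)
    stop_structural("sample, background and standard must share one SDS")
  denom <- standard$value - background$value
  if (any(denom <= 0))
    stop("calibration error: standard minus background must be positive ",
         "at every wavelength")
  r <- standard_reflectance * (sample$value - background$value) / denom
  r[r < 0] <- 0    # noise can push near-zero signal slightly negative
  spectrum(sample$wavelengths, r, kind = "absolute", sds = sample$sds,
           integration_ms = sample$integration_ms,
           metadata = c(sample$metadata,
                        list(low_signal = which(denom < 5 * noise_floor))))
}

#' Write spectra to CSV
#'
#' One CSV per call with header `wavelength_nm,value,kind,sds_um,
#' integration_ms`; multiple spectra are stacked and recovered on read by
#' their (kind, sds) runs.
#'
#' @param spectra a single `sdrs_spectrum` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "sdrs_spectrum")) spectra <- list(spectra)
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(wavelength_nm = s$wavelengths, value = s$value, kind = s$kind,
               sds_um = s$sds, integration_ms = s$integration_ms,
               series = i)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra()]; parse errors carry the offending line
#' number, a descending wavelength grid or missing columns are rejected.
#'
#' @param path CSV file written by [write_spectra()].
#' @return list of `sdrs_spectrum` objects.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty spectra file: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("empty or malformed spectra file: ",
                                          path, " (", conditionMessage(e),
                                          ")", call. = FALSE))
  if (nrow(df) == 0) stop("empty spectra file: ", path)
  need <- c("wavelength_nm", "value", "kind", "sds_um", "integration_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$wavelength_nm) | !is.finite(df$value))
  if (length(bad))
    stop("malformed spectra row at line ", bad[1] + 1L, " of ", path)
  if (is.null(df$series))
    df$series <- cumsum(c(TRUE, df$kind[-1] != df$kind[-nrow(df)] |
                            df$sds_um[-1] != df$sds_um[-nrow(df)]))
  lapply(split(df, df$series), function(g) {
    if (any(diff(g$wavelength_nm) <= 0))
      stop("non-monotone wavelengths in ", path, " near line ",
           which(diff(g$wavelength_nm) <= 0)[1] + 1L)
    spectrum(g$wavelength_nm, g$value, kind = as.character(g$kind[1]),
             sds = g$sds_um[1], integration_ms = g$integration_ms[1])
  })
}
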