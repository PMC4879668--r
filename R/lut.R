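#' Build a reflectance lookup table from calibration data
#'
#' Pools the per-wavelength scatter points \eqn{(\mu_s'(\lambda),
#' \mu_a(\lambda), R(\lambda))} of all calibration phantoms and reconstructs
#' the reflectance surface on a regular (\eqn{\mu_s'}, \eqn{\mu_a}) grid in
#' two stages: a global polynomial least-squares fit of the log values
#' (degree 8) captures the smooth surface between phantom trajectories, and
#' the residuals are distributed by triangulation-based (Delaunay) linear
#' interpolation, so the reconstruction is exact at the data points. Grid
#' nodes outside the convex hull of the data are filled by nearest-neighbour
#' propagation from the hull boundary and flagged in the provenance. The
#' build fails if the hull covers less than `min_coverage` of the target
#' rectangle.
#'
#' @param calibration list of `(properties, spectrum)` pairs: each element a
#'   list with `props` (list with `wavelengths`, `musp`, `mua`) and
#'   `spectrum` (absolute `sdrs_spectrum` on the same grid).
#' @param sds source-detector separation, um (provenance; must match spectra).
#' @param musp_range,mua_range LUT target ranges, cm\eqn{^{-1}}.
#' @param step grid resolution, cm\eqn{^{-1}} (default 0.02).
#' @param min_coverage minimum in-hull fraction of grid nodes (default 0.95).
#' @param kind `"reflectance"` or `"depth"` (value semantics).
#' @param provenance optional named list merged into the LUT provenance.
#' @return an object of class `sdrs_lut`: list with `musp_axis`, `mua_axis`,
#'   `values` (musp x mua matrix), `sds`, `kind`, `provenance`.
#' @export
build_reflectance_lut <- function(calibration, sds,
                                  musp_range = c(5, 26), mua_range = c(0, 10),
                                  step = 0.02, min_coverage = 0.95,
                                  kind = "reflectance", provenance = list()) {
  if (length(calibration) < 6)
    stop_structural("need at least 6 calibration phantoms")
  pts <- do.call(rbind, lapply(calibration, function(el) {
    v <- if (inherits(el$spectrum, "sdrs_spectrum")) el$spectrum$value
         else el$values
    cbind(el$props$musp, el$props$mua, v)
  }))
  pts <- pts[is.finite(pts[, 3]) & pts[, 3] > 0, , drop = FALSE]
  # canonical point order: the build is then invariant to the order in
  # which phantoms were supplied (ties in the Delaunay triangulation of
  # degenerate point groups are otherwise order-dependent)
  pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  musp_axis <- seq(musp_range[1], musp_range[2], by = step)
  mua_axis <- seq(mua_range[1], mua_range[2], by = step)
  # Two-stage surface reconstruction in log space (reflectance decays
  # near-exponentially with absorption): a global degree-8 bivariate
  # polynomial least-squares fit of log(values) captures the smooth
  # large-scale surface between the phantom trajectories, and the remaining
  # residuals are spread onto the grid by triangulation-based (Delaunay)
  # linear interpolation, which is exact at the data points. Straight
  # triangulated interpolation of the raw values leaves several-percent
  # errors in the trajectory gaps; the polynomial stage removes them.
  z <- log(pts[, 3])
  sx <- c(mean(range(pts[, 1])), max(diff(range(pts[, 1])) / 2, 1))
  sy <- c(mean(range(pts[, 2])), max(diff(range(pts[, 2])) / 2, 1))
  B <- poly_basis2d((pts[, 1] - sx[1]) / sx[2], (pts[, 2] - sy[1]) / sy[2])
  cf <- qr.coef(qr(B), z)
  cf[!is.finite(cf)] <- 0      # rank-deficient (degenerate) designs
  res <- z - drop(B %*% cf)
  grid <- interp::interp(x = pts[, 1], y = pts[, 2], z = res,
                         xo = musp_axis, yo = mua_axis,
                         duplicate = "mean", output = "grid")
  gg <- expand.grid(x = musp_axis, y = mua_axis)
  zsm <- matrix(drop(poly_basis2d((gg$x - sx[1]) / sx[2],
                                  (gg$y - sy[1]) / sy[2]) %*% cf),
                length(musp_axis))
  vals <- exp(zsm + grid$z)
  inside <- is.finite(vals)
  coverage <- mean(inside)
  if (coverage < min_coverage) {
    stop("LUT build error: calibration trajectories cover only ",
         sprintf("%.1f%%", 100 * coverage), " of the target rectangle ",
         "(need ", sprintf("%.0f%%", 100 * min_coverage), "); largest gaps ",
         "near musp = ", sprintf("%.1f", musp_axis[which.max(rowSums(!inside))]),
         ", mua = ", sprintf("%.1f", mua_axis[which.max(colSums(!inside))]))
  }
  vals <- fill_nearest(vals)
  ids <- unlist(lapply(calibration, function(el)
    el$spectrum$metadata$phantom_id %||% NA_character_))
  structure(list(musp_axis = musp_axis, mua_axis = mua_axis, values = vals,
                 sds = sds, kind = kind,
                 provenance = c(list(phantom_ids = ids,
                                     n_points = nrow(pts),
                                     hull_coverage = coverage,
                                     filled_nodes = sum(!inside),
                                     build_date = format(Sys.Date()),
                                     schema_version = "1"),
                                provenance)),
            class = "sdrs_lut")
}

# complete bivariate monomial basis of total degree `deg` on scaled coords
poly_basis2d <- function(u, v, deg = 8) {
  cols <- vector("list", (deg + 1) * (deg + 2) / 2)
  k <- 0
  for (i in 0:deg) for (j in 0:(deg - i)) {
    k <- k + 1
    cols[[k]] <- u^i * v^j
  }
  do.call(cbind, cols)
}

# fill NA grid nodes by iterative nearest-neighbour dilation (4-neighbour
# sweeps, then 8-neighbour average of available neighbours)
fill_nearest <- function(m) {
  while (anyNA(m)) {
    na <- which(is.na(m), arr.ind = TRUE)
    nr <- nrow(m); nc <- ncol(m)
    repl <- apply(na, 1, function(ij) {
      i <- ij[1]; j <- ij[2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nr) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < nc) m[i, j + 1])
      nb <- nb[is.finite(nb)]
      if (length(nb)) mean(nb) else NA_real_
    })
    if (all(is.na(repl))) stop("LUT fill failed: no finite nodes")
    m[is.na(m)] <- repl
  }
  m
}

#' Build a sampling-depth lookup table
#'
#' Same pooled triangulation scheme as [build_reflectance_lut()], but the
#' third coordinate is the per-wavelength sampling depth (um) estimated from
#' translation curves of the absorbing calibration phantoms.
#'
#' @param depth_records list of elements with `props` (list with
#'   `wavelengths`, `musp`, `mua`) and `depth_um` (per-wavelength depths).
#' @inheritParams build_reflectance_lut
#' @return an `sdrs_lut` with `kind = "depth"`, values in um.
#' @export
build_sampling_depth_lut <- function(depth_records, sds,
                                     musp_range = c(5, 26),
                                     mua_range = c(0, 10), step = 0.02,
                                     min_coverage = 0.95,
                                     provenance = list()) {
  if (length(depth_records) < 6)
    stop_structural("need depth records from at least 6 absorbing phantoms")
  cal <- lapply(depth_records, function(el)
    list(props = el$props, values = el$depth_um,
         spectrum = structure(list(value = el$depth_um,
                                   metadata = list(phantom_id = el$id %||% NA)),
                              class = "depth_record")))
  lut <- build_reflectance_lut(cal, sds, musp_range, mua_range, step,
                               min_coverage, kind = "depth", provenance)
  if (any(lut$values <= 0)) stop_domain("sampling depths must be > 0")
  lut
}

#' Bilinear lookup in a 2-D LUT
#'
#' Bilinear interpolation between the four grid nodes surrounding the query;
#' exact at grid nodes. Queries outside the axis ranges raise a range error
#' naming the violated axis.
#'
#' @param lut an `sdrs_lut`.
#' @param musp,mua query coordinates, cm\eqn{^{-1}}; vectorized.
#' @return interpolated values (reflectance or depth).
#' @export
lut_lookup <- function(lut, musp, mua) {
  stopifnot(inherits(lut, "sdrs_lut"))
  xa <- lut$musp_axis; ya <- lut$mua_axis
  if (any(musp < xa[1]) || any(musp > xa[length(xa)]))
    stop_range("musp query outside LUT range [", xa[1], ", ",
               xa[length(xa)], "]")
  if (any(mua < ya[1]) || any(mua > ya[length(ya)]))
    stop_range("mua query outside LUT range [", ya[1], ", ",
               ya[length(ya)], "]")
  dx <- xa[2] - xa[1]; dy <- ya[2] - ya[1]
  i <- pmin(pmax(floor((musp - xa[1]) / dx) + 1, 1), length(xa) - 1)
  j <- pmin(pmax(floor((mua - ya[1]) / dy) + 1, 1), length(ya) - 1)
  tx <- (musp - xa[i]) / dx
  ty <- (mua - ya[j]) / dy
  v <- lut$values
  n <- nrow(v)
  idx <- function(ii, jj) v[(jj - 1) * n + ii]
  (1 - tx) * (1 - ty) * idx(i, j) + tx * (1 - ty) * idx(i + 1, j) +
    (1 - tx) * ty * idx(i, j + 1) + tx * ty * idx(i + 1, j + 1)
}

#' Elementwise ratio statistics of two LUTs
#'
#' Elementwise `b/a` over the full grid, with summary statistics; used to
#' compare channels (e.g. the deep-to-shallow sampling-depth ratio).
#'
#' @param lut_a,lut_b `sdrs_lut` objects on identical axes.
#' @return list with `ratio` (matrix), `mean`, `sd`, `min`, `max`.
#' @export
lut_ratio_stats <- function(lut_a, lut_b) {
  stopifnot(inherits(lut_a, "sdrs_lut"), inherits(lut_b, "sdrs_lut"))
  if (!isTRUE(all.equal(lut_a$musp_axis, lut_b$musp_axis)) ||
      !isTRUE(all.equal(lut_a$mua_axis, lut_b$mua_axis)))
    stop_structural("LUT axes differ")
  r <- lut_b$values / lut_a$values
  list(ratio = r, mean = mean(r), sd = stats::sd(as.vector(r)),
       min = min(r), max = max(r))
}

#' Save a LUT to a portable text file
#'
#' Single-file format: a JSON header line (axes, SDS, kind, provenance,
#' schema version, value checksum) followed by the value matrix in CSV rows.
#'
#' @param lut an `sdrs_lut`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_lut <- function(lut, path) {
  stopifnot(inherits(lut, "sdrs_lut"))
  header <- jsonlite::toJSON(list(
    format = "sdrslut", schema_version = "1",
    musp_axis = list(min = lut$musp_axis[1],
                     max = lut$musp_axis[length(lut$musp_axis)],
                     n = length(lut$musp_axis)),
    mua_axis = list(min = lut$mua_axis[1],
                    max = lut$mua_axis[length(lut$mua_axis)],
                    n = length(lut$mua_axis)),
    sds = lut$sds, kind = lut$kind,
    checksum = value_checksum(lut$values),
    provenance = lut$provenance[setdiff(names(lut$provenance),
                                        "phantom_ids")]),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  utils::write.table(format(lut$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a LUT saved by [save_lut()]
#'
#' Checks the schema version (older or unknown versions raise an explicit
#' upgrade error) and the value checksum (tampered payloads are rejected).
#'
#' @param path file written by [save_lut()].
#' @return an `sdrs_lut`.
#' @export
load_lut <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("not an sdrslut file: ", path)
  h <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (!identical(h$format, "sdrslut")) stop("not an sdrslut file: ", path)
  if (!identical(h$schema_version, "1"))
    stop("unsupported LUT schema version '", h$schema_version,
         "': upgrade required")
  vals <- matrix(scan(text = lines[-1], sep = ",", quiet = TRUE),
                 nrow = h$musp_axis$n, ncol = h$mua_axis$n, byrow = TRUE)
  if (!identical(value_checksum(vals), h$checksum))
    stop("LUT payload corrupted: checksum mismatch in ", path)
  structure(list(
    musp_axis = seq(h$musp_axis$min, h$musp_axis$max,
                    length.out = h$musp_axis$n),
    mua_axis = seq(h$mua_axis$min, h$mua_axis$max, length.out = h$mua_axis$n),
    values = vals, sds = h$sds, kind = h$kind,
    provenance = as.list(h$provenance)), class = "sdrs_lut")
}

#' @export
print.sdrs_lut <- function(x, ...) {
  cat(sprintf(paste0("<sdrs_lut> %s, SDS %g um, %d x %d nodes ",
                     "(musp %g-%g, mua %g-%g cm^-1)\n"),
              x$kind, x$sds, length(x$musp_axis), length(x$mua_axis),
              min(x$musp_axis), max(x$musp_axis),
              min(x$mua_axis), max(x$mua_axis)))
  invisible(x)
}
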