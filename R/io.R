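#' Read a calibration series from CSV
#'
#' Expected columns: `replicate`, `free_ca_nM`, and either
#' (`tau_phi_ns`, `tau_mod_ns`) or (`g`, `s`).
#'
#' @param path CSV path.
#' @param mod Modulation settings (or frequency in MHz).
#' @return A [calibration_series()].
#' @export
read_calibration_csv <- function(path, mod = modulation_settings()) {
  calibration_series(utils::read.csv(path), mod)
}

#' Read a photon arrival-time histogram from CSV
#'
#' Expected columns: `t_ns` (bin centres) and `counts`.
#'
#' @param path CSV path.
#' @return An [arrival_histogram()].
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_ns", "counts") %in% names(df)))
  arrival_histogram(df$t_ns, df$counts)
}

#' Write a photon arrival-time histogram to CSV
#' @param hist An [arrival_histogram()].
#' @param path Output CSV path.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "arrival_histogram"))
  utils::write.csv(
    data.frame(t_ns = hist$bin_centers_ns, counts = hist$counts),
    path, row.names = FALSE
  )
}

#' Read a spectrum from CSV (columns `wavelength_nm`, `value`)
#' @param path CSV path.
#' @param kind Spectrum kind (see [spectrum_data()]).
#' @return A [spectrum_data()] object.
#' @export
read_spectrum_csv <- function(path, kind = "excitation") {
  df <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "value") %in% names(df)))
  spectrum_data(df$wavelength_nm, df$value, kind)
}

#' Write a calibration result to JSON
#'
#' Serialises the fitted Hill parameters, per-parameter 95\% confidence
#' intervals, endpoints (including `R`), modulation frequency and measurable
#' range in a flat, machine-readable layout.
#'
#' @param result A `calibration_result` from [fit_hill()].
#' @param path Output JSON path.
#' @param freq_MHz Modulation frequency recorded alongside.
#' @export
write_calibration_json <- function(result, path, freq_MHz = 40) {
  stopifnot(inherits(result, "calibration_result"))
  p <- result$params
  ci <- result$ci95
  obj <- list(
    kd_nM = p$Kd_nM, hill_n = p$hill_n, f_min = p$F_min, f_max = p$F_max,
    ci95 = stats::setNames(
      lapply(seq_len(nrow(ci)), function(i) c(ci$lo[i], ci$hi[i])),
      ci$parameter
    ),
    endpoints = list(
      g_min = result$endpoints$g_min, s_min = result$endpoints$s_min,
      g_max = result$endpoints$g_max, s_max = result$endpoints$s_max,
      r = result$endpoints$R
    ),
    freq_MHz = freq_MHz,
    measurable_range_nM = result$measurable_range_nM,
    residual_norm = result$residual_norm,
    converged = result$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result from JSON
#' @param path JSON path written by [write_calibration_json()].
#' @return A `calibration_result`-compatible list (fields `params`,
#'   `endpoints`, `ci95`, `measurable_range_nM`).
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      params = hill_params(obj$kd_nM, obj$hill_n, obj$f_min, obj$f_max),
      endpoints = calibration_endpoints(
        phasor_min = c(obj$endpoints$g_min, obj$endpoints$s_min),
        phasor_max = c(obj$endpoints$g_max, obj$endpoints$s_max),
        R = obj$endpoints$r
      ),
      ci95 = obj$ci95,
      measurable_range_nM = obj$measurable_range_nM,
      residual_norm = obj$residual_norm,
      converged = obj$converged
    ),
    class = "calibration_result"
  )
}

#' Write an image stack as multi-page float TIFF with a sidecar scale
#'
#' TIFF float storage in this toolchain clamps values to \[0, 1\], so the
#' data are divided by a scale factor before writing and the factor is
#' recorded in a sidecar JSON (`<path>.json`). Non-finite values are encoded
#' as sentinels: `Inf` as the scale factor itself (i.e. 1.0 in the file) and
#' `NA` as 0; the flag channel, not the payload, is authoritative for those
#' pixels.
#'
#' @param stack Matrix or 3-D array `(row, col, page)`.
#' @param path Output TIFF path.
#' @param scale Scale factor; default the finite maximum of the data.
#' @export
write_image_tiff <- function(stack, path, scale = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  finite_max <- suppressWarnings(max(stack[is.finite(stack)], 0))
  if (is.null(scale)) scale <- if (finite_max > 0) finite_max else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k] / scale
    m[is.infinite(m)] <- 1
    m[is.na(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_tiff()]
#' @param path TIFF path (sidecar `<path>.json` must be present).
#' @return A 3-D array `(row, col, page)` on the original scale.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- jsonlite::read_json(paste0(path, ".json"),
                               simplifyVector = TRUE)$scale
  out <- array(NA_real_, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]] * scale
  out
}

#' Write a concentration map plus its flag channel
#'
#' The concentration payload goes to `<path>` (float TIFF, scaled, sidecar
#' JSON), the flags to `<path_flags>` as 8-bit TIFF (0 ok, 1 below range,
#' 2 saturated, 3 masked).
#'
#' @param camap Output of [phasor_image_to_ca_map()].
#' @param path Concentration TIFF path.
#' @param path_flags Flag TIFF path; default `<path>` with a `_flags`
#'   suffix.
#' @export
write_ca_map <- function(camap, path,
                         path_flags = sub("(\\.tiff?)$", "_flags\\1", path)) {
  write_image_tiff(camap$ca_nM, path)
  tiff::writeTIFF(camap$flags / 255, path_flags, bits.per.sample = 8L)
  invisible(path)
}
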