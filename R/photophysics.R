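#' Spectrum container
#'
#' @param wavelengths_nm Strictly ascending wavelength grid (nm).
#' @param values Non-negative spectral values (arbitrary units unless the
#'   kind implies otherwise).
#' @param kind One of `"excitation"`, `"emission"`, `"absorbance"`,
#'   `"instrument-excitation"`, `"instrument-detection"`.
#' @return An object of class `spectrum_data`.
#' @export
spectrum_data <- function(wavelengths_nm, values,
                          kind = c("excitation", "emission", "absorbance",
                                   "instrument-excitation",
                                   "instrument-detection")) {
  kind <- match.arg(kind)
  stopifnot(length(wavelengths_nm) == length(values),
            length(wavelengths_nm) >= 2L)
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("spectral values must be finite", call. = FALSE)
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         values = as.numeric(values), kind = kind),
    class = "spectrum_data"
  )
}

spectrum_at <- function(sp, wl) {
  stats::approx(sp$wavelengths_nm, sp$values, xout = wl, rule = 2)$y
}

# trapezoid integral of a product of spectra, linearly interpolated onto the
# union grid (resampled at `step` nm)
overlap_integral <- function(spectra, step = 1) {
  rng <- range(unlist(lapply(spectra, function(s) range(s$wavelengths_nm))))
  lo <- max(vapply(spectra, function(s) min(s$wavelengths_nm), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavelengths_nm), 0))
  if (hi <= lo) return(0)
  grid <- seq(lo, hi, by = step)
  vals <- Reduce(`*`, lapply(spectra, spectrum_at, wl = grid))
  if (length(grid) < 2L) return(0)
  sum(diff(grid) * (vals[-1] + vals[-length(vals)]) / 2)
}

#' Quantum yield by origin-forced slope comparison with a reference dye
#'
#' For each dilution series the integrated emission is regressed on the
#' absorbance at the excitation wavelength with the intercept forced through
#' the origin; the quantum yield of the sample is the reference quantum
#' yield scaled by the ratio of emission-per-absorbance slopes:
#' \deqn{QY_s = QY_r \times s_s / s_r.}
#' The standard deviation of the estimate is propagated from the standard
#' errors of both slopes (in quadrature).
#'
#' @param sample,reference Data frames with columns `a450` (absorbance at
#'   the excitation wavelength, OD, all <= 0.05 for linearity) and `i_em`
#'   (integrated emission, arbitrary units); >= 3 dilutions each.
#' @param QY_ref Quantum yield of the reference dye (default 0.85,
#'   rhodamine).
#' @return A list with `QY`, `sd`, and the two fitted slopes.
#' @export
quantum_yield <- function(sample, reference, QY_ref = 0.85) {
  check_series <- function(d, nm) {
    stopifnot(is.data.frame(d), all(c("a450", "i_em") %in% names(d)))
    if (nrow(d) < 3L) stop(nm, " series needs >= 3 dilutions", call. = FALSE)
    if (any(d$a450 > 0.05 + 1e-12)) {
      stop(nm, " series violates the A <= 0.05 linearity condition",
           call. = FALSE)
    }
  }
  check_series(sample, "sample")
  check_series(reference, "reference")
  slope <- function(d) {
    # origin-forced least squares; SE computed directly so that noiseless
    # fixtures (zero residuals) are handled without special-casing
    sxx <- sum(d$a450^2)
    s <- sum(d$a450 * d$i_em) / sxx
    rss <- sum((d$i_em - s * d$a450)^2)
    c(s = s, se = sqrt(rss / (nrow(d) - 1L) / sxx))
  }
  ss <- slope(sample)
  sr <- slope(reference)
  if (sr["s"] == 0) stop("reference slope is zero", call. = FALSE)
  qy <- QY_ref * ss["s"] / sr["s"]
  sd <- abs(qy) * sqrt((ss["se"] / ss["s"])^2 + (sr["se"] / sr["s"])^2)
  list(QY = unname(qy), sd = unname(sd),
       slope_sample = unname(ss["s"]), slope_reference = unname(sr["s"]))
}

#' Extinction coefficient via the denatured-chromophore method
#'
#' Alkaline denaturation frees the chromophore, whose extinction coefficient
#' at 462 nm is known (46,000 M^-1 cm^-1 for the cyan chromophore). The
#' protein concentration follows from Beer-Lambert on the denatured
#' spectrum, and the native-state extinction maximum is the native
#' absorbance peak divided by that concentration and the path length.
#'
#' @param native_spectrum,denatured_spectrum [spectrum_data()] absorbance
#'   spectra of the same sample before/after denaturation.
#' @param path_length_cm Cuvette path length (cm).
#' @param eps_denatured_M Known chromophore extinction coefficient
#'   (M^-1 cm^-1) at `lambda_denatured_nm`.
#' @param lambda_denatured_nm Wavelength of the known coefficient (nm).
#' @return A list with `eps_max_M` (M^-1 cm^-1), `lambda_max_nm`, and the
#'   inferred `concentration_M`.
#' @export
extinction_coefficient <- function(native_spectrum, denatured_spectrum,
                                   path_length_cm = 1,
                                   eps_denatured_M = 46000,
                                   lambda_denatured_nm = 462) {
  stopifnot(inherits(native_spectrum, "spectrum_data"),
            inherits(denatured_spectrum, "spectrum_data"),
            path_length_cm > 0)
  a_denat <- spectrum_at(denatured_spectrum, lambda_denatured_nm)
  if (a_denat <= 0) {
    stop("denatured spectrum has no absorbance at the chromophore wavelength",
         call. = FALSE)
  }
  conc <- a_denat / (eps_denatured_M * path_length_cm)
  i_max <- which.max(native_spectrum$values)
  list(
    eps_max_M = native_spectrum$values[i_max] / (conc * path_length_cm),
    lambda_max_nm = native_spectrum$wavelengths_nm[i_max],
    concentration_M = conc
  )
}

#' Theoretical two-state detected intensity ratio
#'
#' Models the detected brightness of each sensor state as the product of its
#' peak extinction coefficient, quantum yield, the overlap of its
#' (peak-normalised) excitation spectrum with the instrument's excitation
#' profile, and the overlap of its (peak-normalised) emission spectrum with
#' the detection profile:
#' \deqn{B = \varepsilon_{max}\, QY \int \hat{x}(\lambda) X(\lambda)\,
#'   d\lambda \int \hat{m}(\lambda) D(\lambda)\, d\lambda,
#'   \qquad R = B_{sat}/B_{apo}.}
#' Any common normalisation of the instrument profiles cancels in the ratio.
#'
#' @param apo,sat Lists per state with elements `excitation` and `emission`
#'   ([spectrum_data()]), `eps_max_M`, `QY`.
#' @param instrument List with `excitation_profile` and `detection_profile`
#'   ([spectrum_data()]); optionally `excitation_band` and `emission_band`
#'   (length-2 nm vectors) applied as ideal top-hat filters.
#' @param step Resampling step for the overlap integrals (nm).
#' @return The scalar intensity ratio `R` (sat over apo).
#' @export
intensity_ratio <- function(apo, sat, instrument, step = 1) {
  band_filter <- function(profile, band) {
    if (is.null(band)) return(profile)
    v <- profile$values *
      (profile$wavelengths_nm >= band[1] & profile$wavelengths_nm <= band[2])
    spectrum_data(profile$wavelengths_nm, v, profile$kind)
  }
  normalize_peak <- function(sp) {
    m <- max(sp$values)
    if (m <= 0) stop("spectrum has no positive values", call. = FALSE)
    spectrum_data(sp$wavelengths_nm, sp$values / m, sp$kind)
  }
  x_prof <- band_filter(instrument$excitation_profile,
                        instrument$excitation_band)
  d_prof <- band_filter(instrument$detection_profile,
                        instrument$emission_band)
  brightness <- function(state) {
    ex <- overlap_integral(list(normalize_peak(state$excitation), x_prof),
                           step)
    em <- overlap_integral(list(normalize_peak(state$emission), d_prof),
                           step)
    if (ex <= 0 || em <= 0) {
      stop("state spectra do not overlap the instrument bands", call. = FALSE)
    }
    state$eps_max_M * state$QY * ex * em
  }
  brightness(sat) / brightness(apo)
}
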