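#' Modulation settings for frequency-domain FLIM
#'
#' Holds the excitation modulation frequency and the derived angular
#' frequency \eqn{\omega = 2\pi f} used by all lifetime/phasor conversions.
#' Times are in nanoseconds throughout the package, so \eqn{\omega} is in
#' rad/ns.
#'
#' @param frequency_MHz Modulation frequency in MHz. Default 40 MHz, the
#'   standard frequency for wide-field frequency-domain FLIM of fluorescent
#'   proteins.
#' @return An object of class `modulation_settings` with fields
#'   `frequency_MHz` and `omega_rad_per_ns`.
#' @examples
#' mod <- modulation_settings(40)
#' mod$omega_rad_per_ns  # 2*pi*0.04
#' @export
modulation_settings <- function(frequency_MHz = 40) {
  if (!is.numeric(frequency_MHz) || length(frequency_MHz) != 1L ||
      !is.finite(frequency_MHz) || frequency_MHz <= 0) {
    stop("`frequency_MHz` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      frequency_MHz = frequency_MHz,
      omega_rad_per_ns = 2 * pi * frequency_MHz * 1e-3
    ),
    class = "modulation_settings"
  )
}

#' @export
print.modulation_settings <- function(x, ...) {
  cat(sprintf("Modulation: %g MHz (omega = %.6g rad/ns)\n",
              x$frequency_MHz, x$omega_rad_per_ns))
  invisible(x)
}

as_modulation <- function(mod) {
  if (inherits(mod, "modulation_settings")) return(mod)
  if (is.numeric(mod) && length(mod) == 1L) return(modulation_settings(mod))
  stop("`mod` must be a modulation_settings object or a frequency in MHz",
       call. = FALSE)
}

#' Convert phase/modulation lifetimes to phasor coordinates
#'
#' Computes the phasor (G, S) of a decay from its phase lifetime
#' \eqn{\tau_\phi} and modulation lifetime \eqn{\tau_M}:
#' \deqn{\Phi = \arctan(\omega \tau_\phi), \quad
#'       M = \sqrt{1 / (1 + (\omega \tau_M)^2)},}
#' \deqn{G = M \cos\Phi, \quad S = M \sin\Phi.}
#' For a mono-exponential decay \eqn{\tau_\phi = \tau_M} and the phasor lies
#' on the universal semicircle of radius 1/2 centred at (1/2, 0); intensity
#' mixtures of mono-exponentials have \eqn{\tau_M \ge \tau_\phi} and fall
#' strictly inside it.
#'
#' @param tau_phi_ns Phase lifetime(s) in ns (vectorized).
#' @param tau_mod_ns Modulation lifetime(s) in ns, recycled against
#'   `tau_phi_ns`.
#' @param mod A [modulation_settings()] object, or a frequency in MHz.
#' @return A data.frame with columns `g` and `s`.
#' @seealso [phasor_to_lifetime()] for the inverse.
#' @export
lifetime_to_phasor <- function(tau_phi_ns, tau_mod_ns, mod = modulation_settings()) {
  mod <- as_modulation(mod)
  n <- max(length(tau_phi_ns), length(tau_mod_ns))
  tau_phi_ns <- rep_len(as.numeric(tau_phi_ns), n)
  tau_mod_ns <- rep_len(as.numeric(tau_mod_ns), n)
  bad <- !is.na(tau_phi_ns) & !is.na(tau_mod_ns) &
    (tau_phi_ns < 0 | tau_mod_ns < 0)
  if (any(bad)) {
    stop("lifetimes must be non-negative", call. = FALSE)
  }
  w <- mod$omega_rad_per_ns
  phi <- atan(w * tau_phi_ns)
  m <- sqrt(1 / (1 + (w * tau_mod_ns)^2))
  data.frame(g = m * cos(phi), s = m * sin(phi))
}

#' Convert phasor coordinates back to phase/modulation lifetimes
#'
#' Inverse of [lifetime_to_phasor()]:
#' \eqn{\tau_\phi = \tan(\mathrm{atan2}(S, G)) / \omega} and
#' \eqn{\tau_M = \sqrt{1/(G^2+S^2) - 1} / \omega}. The phase angle is taken
#' with `atan2` so that unphysical points with \eqn{S < 0} are rejected
#' rather than silently wrapped into the first quadrant.
#'
#' @param g,s Phasor coordinates (vectorized, recycled to a common length).
#' @param mod A [modulation_settings()] object, or a frequency in MHz.
#' @return A data.frame with columns `tau_phi_ns` and `tau_mod_ns`.
#' @export
phasor_to_lifetime <- function(g, s, mod = modulation_settings()) {
  mod <- as_modulation(mod)
  n <- max(length(g), length(s))
  g <- rep_len(as.numeric(g), n)
  s <- rep_len(as.numeric(s), n)
  ok <- !is.na(g) & !is.na(s)
  if (any(ok & (g <= 0 | s < 0 | g^2 + s^2 > 1 + 1e-12))) {
    stop("phasor out of range: need G > 0, S >= 0 and G^2 + S^2 <= 1",
         call. = FALSE)
  }
  w <- mod$omega_rad_per_ns
  tau_phi <- tan(atan2(s, g)) / w
  msq <- pmin(g^2 + s^2, 1)
  tau_mod <- sqrt(1 / msq - 1) / w
  data.frame(tau_phi_ns = tau_phi, tau_mod_ns = tau_mod)
}

#' Calibration endpoints: the two-state mixing line
#'
#' The apo (calcium-free) and sat (calcium-saturated) sensor states occupy
#' two fixed phasor positions; any mixture of the two states falls on the
#' straight segment between them, at a position weighted by each state's
#' detected intensity. `R` is the detected brightness of the bound state
#' relative to the free state under the instrument settings in use; it is
#' needed to convert the intensity-weighted line position into a molecular
#' bound fraction.
#'
#' @param phasor_min Phasor of the calcium-free (apo) state: a length-2
#'   numeric `c(g, s)`, or a one-row data.frame with columns `g`, `s`.
#' @param phasor_max Phasor of the calcium-saturated state, same formats.
#' @param R Bound-to-free detected intensity ratio (> 0).
#' @param epsilon Minimum allowed Euclidean distance between the endpoints.
#' @return An object of class `calibration_endpoints` with fields `g_min`,
#'   `s_min`, `g_max`, `s_max`, `R`.
#' @examples
#' ends <- calibration_endpoints(
#'   phasor_min = lifetime_to_phasor(2.98, 3.50),
#'   phasor_max = lifetime_to_phasor(1.93, 2.43),
#'   R = 0.836
#' )
#' @export
calibration_endpoints <- function(phasor_min, phasor_max, R = 0.836,
                                  epsilon = 1e-9) {
  p0 <- as_phasor_pair(phasor_min)
  p1 <- as_phasor_pair(phasor_max)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("`R` must be a single positive number", call. = FALSE)
  }
  d <- sqrt((p1[1] - p0[1])^2 + (p1[2] - p0[2])^2)
  if (!is.finite(d) || d <= epsilon) {
    stop("degenerate calibration endpoints: apo and sat phasors coincide",
         call. = FALSE)
  }
  structure(
    list(g_min = p0[1], s_min = p0[2], g_max = p1[1], s_max = p1[2], R = R),
    class = "calibration_endpoints"
  )
}

as_phasor_pair <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L, all(c("g", "s") %in% names(p)))
    p <- c(p$g, p$s)
  }
  if (is.list(p) && all(c("g", "s") %in% names(p))) p <- c(p$g, p$s)
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    stop("a phasor must be two finite numbers (g, s)", call. = FALSE)
  }
  unname(p)
}

#' @export
print.calibration_endpoints <- function(x, ...) {
  cat(sprintf("Calibration endpoints (R = %.4g):\n", x$R))
  cat(sprintf("  apo (min): G = %.5f, S = %.5f\n", x$g_min, x$s_min))
  cat(sprintf("  sat (max): G = %.5f, S = %.5f\n", x$g_max, x$s_max))
  invisible(x)
}

#' Project phasor measurements onto the two-state mixing line
#'
#' Orthogonal projection onto the segment from the apo phasor to the sat
#' phasor, expressed as the line fraction `a`:
#' \deqn{a = \frac{dG\, dG_{max} + dS\, dS_{max}}{dG_{max}^2 + dS_{max}^2}}
#' with \eqn{dG = G - G_{min}} etc. Noisy measurements beyond the extremes
#' yield `a` outside \[0, 1\]; the value is returned unclamped together with
#' an `in_range` flag so that quality control can see how far outside the
#' calibrated span a pixel fell. Clamping happens only at the
#' concentration-conversion stage.
#'
#' @param g,s Phasor coordinates (vectorized).
#' @param ends A [calibration_endpoints()] object.
#' @return A data.frame with columns `a` (unclamped line fraction) and
#'   `in_range` (logical, `a` within \[0, 1\] up to 1e-9).
#' @export
project_line_fraction <- function(g, s, ends) {
  stopifnot(inherits(ends, "calibration_endpoints"))
  dgm <- ends$g_max - ends$g_min
  dsm <- ends$s_max - ends$s_min
  dg <- g - ends$g_min
  ds <- s - ends$s_min
  a <- (dg * dgm + ds * dsm) / (dgm^2 + dsm^2)
  data.frame(a = a, in_range = a >= -1e-9 & a <= 1 + 1e-9)
}

#' Convert a line fraction to the true bound fraction
#'
#' The line fraction `a` weights the two states by detected intensity; the
#' molecular fraction of sensors in the calcium-bound state is
#' \deqn{F = \frac{a}{R(1-a) + a}.}
#' With `R < 1` (the bound state dimmer than the free state) the bound
#' molecules are under-represented on the line, so `F > a` for intermediate
#' mixtures. For `R = 1` the two fractions coincide.
#'
#' @param a Line fraction(s), typically from [project_line_fraction()].
#'   Values outside \[0, 1\] are transformed as-is; values for which the
#'   denominator is non-positive give `NaN`.
#' @param R Bound-to-free intensity ratio (> 0).
#' @return Numeric vector of bound fractions.
#' @export
bound_fraction <- function(a, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("`R` must be a single positive number", call. = FALSE)
  }
  den <- R * (1 - a) + a
  f <- a / den
  f[!is.na(den) & den <= 0] <- NaN
  f
}

#' Convert a bound fraction back to a line fraction
#'
#' Algebraic inverse of [bound_fraction()]:
#' \eqn{a = F R / ((1 - F) + F R)}. Used by the synthetic-data generators to
#' place a known molecular mixture onto the phasor mixing line.
#'
#' @param f Bound fraction(s) in \[0, 1\].
#' @param R Bound-to-free intensity ratio (> 0).
#' @return Numeric vector of line fractions.
#' @export
line_fraction_from_bound <- function(f, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("`R` must be a single positive number", call. = FALSE)
  }
  f * R / ((1 - f) + f * R)
}

#' Phasor of a two-state mixture with a given bound fraction
#'
#' Places a mixture with molecular bound fraction `F` on the mixing line:
#' the intensity-weighted line fraction is computed with
#' [line_fraction_from_bound()] and interpolated between the endpoint
#' phasors.
#'
#' @param f Bound fraction(s) in \[0, 1\].
#' @param ends A [calibration_endpoints()] object (supplies both the
#'   endpoint phasors and `R`).
#' @return A data.frame with columns `g` and `s`.
#' @export
mix_phasor <- function(f, ends) {
  stopifnot(inherits(ends, "calibration_endpoints"))
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  a <- line_fraction_from_bound(f, ends$R)
  data.frame(
    g = ends$g_min + a * (ends$g_max - ends$g_min),
    s = ends$s_min + a * (ends$s_max - ends$s_min)
  )
}
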