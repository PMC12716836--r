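#' Convert per-pixel phasor images to a calcium-concentration map
#'
#' Applies the calibrated phasor-to-concentration transform pixelwise:
#' projection onto the apo-sat mixing line, intensity-ratio correction, and
#' inversion of the fitted Hill curve. Line fractions are clamped to the
#' fitted \[`F_min`, `F_max`\] span at this stage only; pixels at or beyond
#' the extremes are flagged rather than dropped.
#'
#' @param g_img,s_img Numeric matrices (or arrays of matching shape) of
#'   per-pixel phasor coordinates.
#' @param result A `calibration_result` from [fit_hill()], or a list with
#'   elements `params` ([hill_params()]) and `endpoints`
#'   ([calibration_endpoints()]).
#' @param mask Optional logical matrix, `TRUE` for foreground. Background
#'   pixels get `NA` concentration and flag 3.
#' @return A list with `ca_nM` (numeric matrix; `Inf` marks saturation) and
#'   `flags` (integer matrix: 0 ok, 1 below range, 2 saturated, 3 masked).
#' @export
phasor_image_to_ca_map <- function(g_img, s_img, result, mask = NULL) {
  if (!identical(dim(g_img), dim(s_img))) {
    stop("G and S images must have the same shape", call. = FALSE)
  }
  if (!is.null(mask) && !identical(dim(mask), dim(g_img))) {
    stop("mask shape must match the images", call. = FALSE)
  }
  params <- result$params
  ends <- result$endpoints
  stopifnot(inherits(params, "hill_params"),
            inherits(ends, "calibration_endpoints"))

  proj <- project_line_fraction(as.numeric(g_img), as.numeric(s_img), ends)
  f <- bound_fraction(proj$a, ends$R)
  conv <- concentration_from_fraction(
    pmin(pmax(f, params$F_min), params$F_max), params
  )
  ca <- conv$L_nM
  flags <- integer(length(ca))
  flags[conv$flag == "below"] <- 1L
  flags[conv$flag == "saturated"] <- 2L
  if (!is.null(mask)) {
    bg <- !as.logical(mask)
    ca[bg] <- NA_real_
    flags[bg] <- 3L
  }
  dim(ca) <- dim(g_img)
  dim(flags) <- dim(g_img)
  list(ca_nM = ca, flags = flags)
}

#' Estimate calibration endpoints from a saturation-terminated timelapse
#'
#' In-situ alternative to the in-vitro endpoints: when a timelapse ends with
#' a saturating stimulus (e.g. digitonin permeabilisation in saturating
#' calcium), the post-saturation frame samples the sat state and the
#' baseline frames contain near-apo pixels. The sat endpoint is the robust
#' centroid (componentwise median) of the pixels in the lowest-lifetime band
#' of the final frame; the apo endpoint is the robust centroid of the
#' highest-lifetime band across the baseline frames. Phase lifetime orders
#' the pixels; band widths are configurable percentiles.
#'
#' @param g_stack,s_stack 3-D arrays `(x, y, frame)` of phasor coordinates.
#' @param R Intensity ratio to attach to the returned endpoints.
#' @param apo_percentile Pixels with lifetime at or above this percentile of
#'   the baseline frames form the apo band (default 95).
#' @param sat_percentile Pixels with lifetime at or below this percentile of
#'   the final frame form the sat band (default 5).
#' @param n_sat_frames Number of trailing frames treated as post-saturation.
#' @param mod Modulation settings (for the lifetime ordering).
#' @return A [calibration_endpoints()] object.
#' @export
estimate_extremes_from_timelapse <- function(g_stack, s_stack, R = 0.836,
                                             apo_percentile = 95,
                                             sat_percentile = 5,
                                             n_sat_frames = 1L,
                                             mod = modulation_settings()) {
  stopifnot(identical(dim(g_stack), dim(s_stack)), length(dim(g_stack)) == 3L)
  n_fr <- dim(g_stack)[3]
  if (n_fr < 2L) {
    stop("timelapse must have at least 2 frames", call. = FALSE)
  }
  mod <- as_modulation(mod)
  base_idx <- seq_len(n_fr - n_sat_frames)
  sat_idx <- seq(n_fr - n_sat_frames + 1L, n_fr)

  # phase lifetime is monotone in S/G; use it to rank pixels by state
  band <- function(g, s, upper, pct) {
    tau <- atan2(s, g)  # monotone proxy for phase lifetime
    thr <- stats::quantile(tau, pct / 100, names = FALSE, na.rm = TRUE)
    keep <- if (upper) tau >= thr else tau <= thr
    keep[is.na(keep)] <- FALSE
    c(stats::median(g[keep]), stats::median(s[keep]))
  }
  apo <- band(as.numeric(g_stack[, , base_idx]),
              as.numeric(s_stack[, , base_idx]),
              upper = TRUE, pct = apo_percentile)
  sat <- band(as.numeric(g_stack[, , sat_idx]),
              as.numeric(s_stack[, , sat_idx]),
              upper = FALSE, pct = sat_percentile)
  calibration_endpoints(phasor_min = apo, phasor_max = sat, R = R)
}
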