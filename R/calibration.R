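#' Hill binding-model parameters
#'
#' The sensor's bound fraction follows a Hill curve in the free calcium
#' concentration L:
#' \deqn{F(L) = F_{min} + \frac{F_{max} - F_{min}}{(K_d/L)^n + 1}.}
#' `Kd_nM` is the half-saturation (microscopic dissociation) constant in nM
#' and `hill_n` the Hill coefficient. `F_min`/`F_max` are the fractions at
#' zero and saturating calcium; they are fit parameters rather than pinned
#' at 0/1 because residual dark-state sensor or incomplete saturation shifts
#' them in practice.
#'
#' @param Kd_nM Dissociation constant in nM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param F_min,F_max Bound fractions at zero and saturating calcium,
#'   with `0 <= F_min < F_max <= 1`.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(Kd_nM, hill_n, F_min = 0, F_max = 1) {
  stopifnot(
    is.numeric(Kd_nM), length(Kd_nM) == 1L, is.finite(Kd_nM), Kd_nM > 0,
    is.numeric(hill_n), length(hill_n) == 1L, is.finite(hill_n), hill_n > 0,
    F_min >= 0, F_max <= 1, F_min < F_max
  )
  structure(
    list(Kd_nM = Kd_nM, hill_n = hill_n, F_min = F_min, F_max = F_max),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill model: Kd = %.4g nM, n = %.4g, F in [%.4g, %.4g]\n",
              x$Kd_nM, x$hill_n, x$F_min, x$F_max))
  invisible(x)
}

#' Forward Hill curve: bound fraction at a given calcium concentration
#'
#' @param L_nM Free calcium concentration(s) in nM (>= 0). `L = 0` is
#'   handled as the limit `F_min`.
#' @param params A [hill_params()] object.
#' @return Numeric vector of bound fractions.
#' @export
hill_fraction <- function(L_nM, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(!is.na(L_nM) & L_nM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  f <- params$F_min +
    (params$F_max - params$F_min) / ((params$Kd_nM / L_nM)^params$hill_n + 1)
  f[!is.na(L_nM) & L_nM == 0] <- params$F_min
  f
}

#' Invert the Hill curve: concentration from a bound fraction
#'
#' \deqn{L = K_d \left(\frac{F - F_{min}}{F_{max} - F}\right)^{1/n}}
#' for F strictly between `F_min` and `F_max`. Out-of-range fractions carry
#' flags instead of errors, because at the pixel level they are expected
#' (noise and genuinely saturated organelles): `F <= F_min` maps to 0 nM
#' flagged "below", `F >= F_max` maps to `Inf` flagged "saturated".
#'
#' @param f Bound fraction(s).
#' @param params A [hill_params()] object.
#' @return A data.frame with columns `L_nM` and `flag`
#'   (`"ok"`, `"below"`, `"saturated"`).
#' @export
concentration_from_fraction <- function(f, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(!is.finite(f) & !is.na(f))) {
    stop("bound fractions must be finite (or NA)", call. = FALSE)
  }
  L <- params$Kd_nM *
    ((f - params$F_min) / (params$F_max - f))^(1 / params$hill_n)
  flag <- rep("ok", length(f))
  below <- !is.na(f) & f <= params$F_min
  sat <- !is.na(f) & f >= params$F_max
  L[below] <- 0
  L[sat] <- Inf
  flag[below] <- "below"
  flag[sat] <- "saturated"
  flag[is.na(f)] <- NA_character_
  data.frame(L_nM = L, flag = flag)
}

#' Build a calibration series table
#'
#' A calibration series pairs known free calcium concentrations with
#' measured lifetimes or phasors, in replicate. Accepts either lifetime
#' columns (`tau_phi_ns`, `tau_mod_ns`) or phasor columns (`g`, `s`);
#' lifetimes are converted to phasors at the series' modulation frequency.
#'
#' @param df A data.frame with columns `replicate`, `free_ca_nM` and either
#'   (`tau_phi_ns`, `tau_mod_ns`) or (`g`, `s`).
#' @param mod A [modulation_settings()] object, or a frequency in MHz.
#' @return An object of class `calibration_series`: the input table with
#'   guaranteed `g`/`s` columns, plus the modulation settings as an
#'   attribute.
#' @export
calibration_series <- function(df, mod = modulation_settings()) {
  mod <- as_modulation(mod)
  stopifnot(is.data.frame(df), all(c("free_ca_nM") %in% names(df)))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(df$free_ca_nM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!all(c("g", "s") %in% names(df))) {
    if (!all(c("tau_phi_ns", "tau_mod_ns") %in% names(df))) {
      stop("need columns (g, s) or (tau_phi_ns, tau_mod_ns)", call. = FALSE)
    }
    ph <- lifetime_to_phasor(df$tau_phi_ns, df$tau_mod_ns, mod)
    df$g <- ph$g
    df$s <- ph$s
  }
  if (length(unique(df$free_ca_nM)) < 2L) {
    stop("a calibration series needs at least 2 distinct concentrations",
         call. = FALSE)
  }
  structure(df, class = c("calibration_series", "data.frame"),
            modulation = mod)
}

#' Derive calibration endpoints from a series' extreme buffers
#'
#' The apo endpoint is the mean phasor at the lowest concentration of the
#' series and the sat endpoint the mean phasor at the highest, matching the
#' in-vitro procedure where the 0 and saturating buffers define 'min' and
#' 'max'.
#'
#' @param series A [calibration_series()].
#' @param R Bound-to-free intensity ratio to attach to the endpoints.
#' @return A [calibration_endpoints()] object.
#' @export
endpoints_from_series <- function(series, R = 0.836) {
  stopifnot(inherits(series, "calibration_series"))
  lo <- series$free_ca_nM == min(series$free_ca_nM)
  hi <- series$free_ca_nM == max(series$free_ca_nM)
  calibration_endpoints(
    phasor_min = c(mean(series$g[lo]), mean(series$s[lo])),
    phasor_max = c(mean(series$g[hi]), mean(series$s[hi])),
    R = R
  )
}

#' Fit the Hill calibration to a series of lifetime measurements
#'
#' The full in-vitro calibration: each measurement is projected onto the
#' apo-sat mixing line ([project_line_fraction()]), corrected for the
#' two-state intensity ratio ([bound_fraction()]), and the resulting bound
#' fractions are fit against the known free calcium concentrations with the
#' Hill equation by bounded nonlinear least squares (Levenberg-Marquardt).
#' Internally `Kd` and `n` are fit on the log scale to enforce positivity;
#' `F_min` and `F_max` are box-bounded.
#'
#' 95\% confidence intervals come from the Jacobian-based covariance with
#' t quantiles; for `Kd` and `n` the interval is computed on the log scale
#' and exponentiated. The measurable concentration range is derived from the
#' replicate scatter at the two extreme buffers (see [measurable_range()]).
#'
#' @param series A [calibration_series()] (or a data.frame accepted by it).
#' @param ends Optional [calibration_endpoints()]; if `NULL`, endpoints are
#'   derived from the series extremes with [endpoints_from_series()] and
#'   ratio `R`.
#' @param R Intensity ratio used when deriving endpoints from the series.
#' @param fix_extremes If `TRUE`, pin `F_min = 0` and `F_max = 1` instead of
#'   fitting them.
#' @param bounds_F Numeric length-4 `c(F_min_lo, F_min_hi, F_max_lo,
#'   F_max_hi)` box for the fraction endpoints.
#' @param mod Modulation settings, used only when `series` is a plain
#'   data.frame with lifetime columns.
#' @return An object of class `calibration_result`: fields `params`
#'   ([hill_params()]), `ci95` (data.frame per parameter), `endpoints`,
#'   `measurable_range_nM`, `fractions` (the per-measurement F table),
#'   `residual_norm`, `converged`.
#' @export
fit_hill <- function(series, ends = NULL, R = 0.836, fix_extremes = FALSE,
                     bounds_F = c(0, 0.5, 0.5, 1),
                     mod = modulation_settings()) {
  if (!inherits(series, "calibration_series")) {
    series <- calibration_series(series, mod)
  }
  n_conc <- length(unique(series$free_ca_nM))
  if (n_conc < 4L) {
    stop("underdetermined calibration: need >= 4 distinct concentrations",
         call. = FALSE)
  }
  if (is.null(ends)) ends <- endpoints_from_series(series, R)
  stopifnot(inherits(ends, "calibration_endpoints"))

  proj <- project_line_fraction(series$g, series$s, ends)
  fr <- bound_fraction(proj$a, ends$R)
  dat <- data.frame(L = series$free_ca_nM, F_obs = fr)

  # starting values: Kd near the concentration whose F is closest to midway
  f_rng <- range(fr)
  midf <- mean(f_rng)
  pos <- dat$L[dat$L > 0]
  kd0 <- if (length(pos)) {
    dat$L[which.min(abs(fr - midf) + ifelse(dat$L == 0, Inf, 0))]
  } else {
    1
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(pos)
  start <- list(lkd = log(kd0), ln = log(1.5))
  lower <- c(lkd = log(1e-3), ln = log(1e-2))
  upper <- c(lkd = log(1e9), ln = log(20))

  if (fix_extremes) {
    form <- F_obs ~ 1 / ((exp(lkd) / L)^exp(ln) + 1)
  } else {
    form <- F_obs ~ fmin + (fmax - fmin) / ((exp(lkd) / L)^exp(ln) + 1)
    start <- c(start, list(fmin = max(min(fr), 0), fmax = min(max(fr), 1)))
    start$fmin <- min(max(start$fmin, bounds_F[1]), bounds_F[2])
    start$fmax <- min(max(start$fmax, bounds_F[3]), bounds_F[4])
    lower <- c(lower, fmin = bounds_F[1], fmax = bounds_F[3])
    upper <- c(upper, fmin = bounds_F[2], fmax = bounds_F[4])
  }

  fit <- minpack.lm::nlsLM(
    form, data = dat, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  est <- list(
    Kd_nM = exp(cf[["lkd"]]),
    hill_n = exp(cf[["ln"]]),
    F_min = if (fix_extremes) 0 else cf[["fmin"]],
    F_max = if (fix_extremes) 1 else cf[["fmax"]]
  )
  params <- hill_params(est$Kd_nM, est$hill_n, est$F_min, est$F_max)

  ci <- tryCatch({
    sm <- summary(fit)
    se <- sm$coefficients[, "Std. Error"]
    tq <- stats::qt(0.975, stats::df.residual(fit))
    lo <- cf - tq * se
    hi <- cf + tq * se
    out <- data.frame(
      parameter = c("Kd_nM", "hill_n", "F_min", "F_max"),
      estimate = c(est$Kd_nM, est$hill_n, est$F_min, est$F_max),
      lo = NA_real_, hi = NA_real_
    )
    out$lo[1] <- exp(lo[["lkd"]]); out$hi[1] <- exp(hi[["lkd"]])
    out$lo[2] <- exp(lo[["ln"]]);  out$hi[2] <- exp(hi[["ln"]])
    if (!fix_extremes) {
      out$lo[3] <- lo[["fmin"]]; out$hi[3] <- hi[["fmin"]]
      out$lo[4] <- lo[["fmax"]]; out$hi[4] <- hi[["fmax"]]
    }
    out
  }, error = function(e) {
    data.frame(parameter = c("Kd_nM", "hill_n", "F_min", "F_max"),
               estimate = c(est$Kd_nM, est$hill_n, est$F_min, est$F_max),
               lo = NA_real_, hi = NA_real_)
  })

  res <- structure(
    list(
      params = params,
      ci95 = ci,
      endpoints = ends,
      fractions = cbind(dat, replicate = series$replicate),
      residual_norm = sqrt(sum(stats::resid(fit)^2)),
      converged = isTRUE(fit$convInfo$isConv) || inherits(fit, "nls"),
      measurable_range_nM = c(NA_real_, NA_real_)
    ),
    class = "calibration_result"
  )
  mr <- tryCatch(measurable_range(res), error = function(e) NULL)
  if (!is.null(mr)) {
    res$measurable_range_nM <- c(mr$L_lo_nM, mr$L_hi_nM)
    res$range_degenerate <- mr$degenerate
  }
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Hill calibration fit\n")
  print(x$params)
  ci <- x$ci95
  for (i in seq_len(nrow(ci))) {
    cat(sprintf("  %-7s %10.4g  [%.4g, %.4g]\n",
                ci$parameter[i], ci$estimate[i], ci$lo[i], ci$hi[i]))
  }
  cat(sprintf("  residual norm %.3g; measurable range %.3g - %.3g nM\n",
              x$residual_norm, x$measurable_range_nM[1],
              x$measurable_range_nM[2]))
  invisible(x)
}

#' Measurable concentration range from the extreme-buffer scatter
#'
#' Replicate-to-replicate variation at the two extreme buffers limits how
#' close to the asymptotes a fraction can be distinguished from them. The
#' lowest measurable fraction is the mean F at zero calcium plus the 95\%
#' confidence half-width of that mean (t distribution); the highest is the
#' mean F at saturating calcium minus its half-width. Both are pushed
#' through the Hill inverse to concentrations.
#'
#' @param result A `calibration_result` from [fit_hill()].
#' @param extreme_fractions Optional list with numeric vectors `low` and
#'   `high` of replicate bound fractions at the two extremes; defaults to
#'   the fractions stored in `result`.
#' @return A list with `L_lo_nM`, `L_hi_nM`, `F_lo`, `F_hi`, and
#'   `degenerate` (`TRUE` when the replicate scatter is zero, in which case
#'   the full range `(0, Inf)` is returned).
#' @export
measurable_range <- function(result, extreme_fractions = NULL) {
  stopifnot(inherits(result, "calibration_result"))
  if (is.null(extreme_fractions)) {
    fr <- result$fractions
    lo_v <- fr$F_obs[fr$L == min(fr$L)]
    hi_v <- fr$F_obs[fr$L == max(fr$L)]
  } else {
    lo_v <- extreme_fractions$low
    hi_v <- extreme_fractions$high
  }
  if (length(lo_v) < 2L || length(hi_v) < 2L) {
    stop("need >= 2 replicates at each extreme buffer", call. = FALSE)
  }
  half <- function(v) {
    stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
  }
  h_lo <- half(lo_v)
  h_hi <- half(hi_v)
  if (h_lo == 0 && h_hi == 0) {
    return(list(L_lo_nM = 0, L_hi_nM = Inf, F_lo = mean(lo_v),
                F_hi = mean(hi_v), degenerate = TRUE))
  }
  f_lo <- mean(lo_v) + h_lo
  f_hi <- mean(hi_v) - h_hi
  p <- result$params
  clamp <- function(f) min(max(f, p$F_min), p$F_max)
  L_lo <- concentration_from_fraction(clamp(f_lo), p)$L_nM
  L_hi <- concentration_from_fraction(clamp(f_hi), p)$L_nM
  list(L_lo_nM = L_lo, L_hi_nM = L_hi, F_lo = f_lo, F_hi = f_hi,
       degenerate = FALSE)
}
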