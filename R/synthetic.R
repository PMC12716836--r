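#' Reference calibration geometry used by the synthetic generators
#'
#' Default fixture reproducing the in-vitro calibration conditions: endpoint
#' phase/modulation lifetimes of the apo and sat states at 40 MHz, a
#' bound-to-free intensity ratio of 0.836, and Hill parameters Kd = 209 nM,
#' n = 1.53 (the 37 degC values) or Kd = 339 nM, n = 1.67 (room
#' temperature).
#'
#' @param temperature `"37C"` or `"RT"`.
#' @param mod Modulation settings.
#' @return A list with `endpoints` ([calibration_endpoints()]), `truth`
#'   ([hill_params()]) and `mod`.
#' @export
reference_calibration <- function(temperature = c("37C", "RT"),
                                  mod = modulation_settings()) {
  temperature <- match.arg(temperature)
  mod <- as_modulation(mod)
  lt <- switch(temperature,
    "37C" = list(apo = c(2.98, 3.50), sat = c(1.93, 2.43),
                 Kd = 209, n = 1.53),
    "RT"  = list(apo = c(3.52, 3.99), sat = c(2.03, 2.57),
                 Kd = 339, n = 1.67)
  )
  list(
    endpoints = calibration_endpoints(
      phasor_min = lifetime_to_phasor(lt$apo[1], lt$apo[2], mod),
      phasor_max = lifetime_to_phasor(lt$sat[1], lt$sat[2], mod),
      R = 0.836
    ),
    truth = hill_params(lt$Kd, lt$n, F_min = 0, F_max = 1),
    mod = mod
  )
}

#' Default calibration-buffer concentration ladder
#'
#' Zero plus `n - 1` log-spaced free calcium concentrations up to the
#' saturating buffer, emulating a commercial calcium calibration buffer
#' ladder spanning 0-39 uM.
#'
#' @param n Number of concentrations including the zero buffer.
#' @param max_nM Saturating concentration (default 39,000 nM).
#' @param min_nM Lowest non-zero concentration (default 10 nM).
#' @return Numeric vector of concentrations in nM.
#' @export
calibration_concentrations <- function(n = 11L, max_nM = 39000,
                                       min_nM = 10) {
  c(0, exp(seq(log(min_nM), log(max_nM), length.out = n - 1L)))
}

#' Simulate an in-vitro calibration series
#'
#' For each concentration and replicate the true bound fraction follows the
#' Hill curve, the noise-free phasor sits on the mixing line at the
#' intensity-weighted position, and isotropic Gaussian noise of standard
#' deviation `phasor_noise_sd` is added to (G, S) — the standard shot-noise
#' behaviour of phasor estimates. Deterministic given `seed`.
#'
#' @param truth A [hill_params()] ground truth.
#' @param ends A [calibration_endpoints()] object.
#' @param concentrations_nM Concentration ladder (nM); default
#'   [calibration_concentrations()].
#' @param replicates Replicates per concentration.
#' @param phasor_noise_sd Isotropic Gaussian noise sd on G and S.
#' @param seed Integer seed.
#' @param mod Modulation settings attached to the series.
#' @return A [calibration_series()].
#' @export
gen_calibration_series <- function(truth, ends,
                                   concentrations_nM = calibration_concentrations(),
                                   replicates = 3L, phasor_noise_sd = 0.003,
                                   seed = 1L, mod = modulation_settings()) {
  stopifnot(inherits(truth, "hill_params"),
            inherits(ends, "calibration_endpoints"), replicates >= 1L)
  df <- expand.grid(replicate = seq_len(replicates),
                    free_ca_nM = concentrations_nM)
  f <- hill_fraction(df$free_ca_nM, truth)
  ph <- mix_phasor(f, ends)
  if (phasor_noise_sd > 0) {
    rng <- local_rng(seed)
    ph$g <- ph$g + rng$rnorm(nrow(df), sd = phasor_noise_sd)
    ph$s <- ph$s + rng$rnorm(nrow(df), sd = phasor_noise_sd)
  }
  df$g <- ph$g
  df$s <- ph$s
  calibration_series(df, mod)
}

# Seeded RNG scoped to the generator: leaves the global RNG state untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(fn) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", outer, globalenv())
        }
      })
      fn(...)
    }
  }
  list(
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif),
    rexp = with_state(stats::rexp),
    sample_int = with_state(function(n, size, prob) {
      sample.int(n, size, replace = TRUE, prob = prob)
    }),
    rbinom = with_state(stats::rbinom)
  )
}

#' Sample a photon arrival-time histogram from a decay model
#'
#' Each photon is background with probability `eps` (uniform on the window)
#' or belongs to decay component j with probability `f_j / (f1 + f2)`, in
#' which case its arrival time is Gaussian IRF jitter plus an exponential
#' delay. Photons falling outside `[0, t_max]` are redrawn (the window is a
#' hard gate, not a wrap-around), so the sampled density is the model
#' conditioned on the window. Deterministic given `seed`.
#'
#' @param model A [decay_model()].
#' @param n_photons Number of photons (>= 1).
#' @param t_max_ns Window length (ns). Default 12.5 ns (80 MHz pulse
#'   spacing).
#' @param bin_width_ns Histogram bin width (ns). Default 10 ps.
#' @param seed Integer seed.
#' @param wrap If `TRUE`, out-of-window photons are wrapped modulo the
#'   window instead of redrawn (short-window mode).
#' @return An [arrival_histogram()].
#' @export
gen_tcspc_histogram <- function(model, n_photons, t_max_ns = 12.5,
                                bin_width_ns = 0.010, seed = 1L,
                                wrap = FALSE) {
  stopifnot(inherits(model, "decay_model"), n_photons >= 1L, t_max_ns > 0)
  rng <- local_rng(seed)
  probs <- c(model$eps, model$f1, model$f2)
  kind <- rng$sample_int(3L, n_photons, probs)
  t <- numeric(n_photons)
  unif <- kind == 1L
  t[unif] <- rng$runif(sum(unif), 0, t_max_ns)
  for (j in 2:3) {
    idx <- which(kind == j)
    if (!length(idx)) next
    tau <- if (j == 2L) model$tau1_ns else model$tau2_ns
    draw <- function(n) {
      rng$rnorm(n, mean = model$mu_ns, sd = model$sigma_ns) +
        rng$rexp(n, rate = 1 / tau)
    }
    x <- draw(length(idx))
    if (wrap) {
      x <- x %% t_max_ns
    } else {
      for (iter in 1:1000) {
        bad <- which(x < 0 | x > t_max_ns)
        if (!length(bad)) break
        x[bad] <- draw(length(bad))
      }
      x <- pmin(pmax(x, 0), t_max_ns)
    }
    t[idx] <- x
  }
  n_bins <- ceiling(t_max_ns / bin_width_ns)
  edges <- seq(0, by = bin_width_ns, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(t, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  arrival_histogram(edges[-length(edges)] + bin_width_ns / 2, counts)
}

#' Scene specification for synthetic calcium timelapses
#'
#' Describes a field of view with elliptical regions (mitochondria-like
#' blobs) that each follow their own calcium program over time, optionally
#' with a sinusoidal oscillation and a final saturation step emulating
#' digitonin permeabilisation in saturating calcium.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param regions List of region lists, each with `center` (row, col),
#'   `radii` (row, col semi-axes in pixels), `baseline_nM`, and optionally
#'   `oscillation_amp_nM`, `oscillation_period_frames`.
#' @param n_frames Number of frames.
#' @param saturation_frames Number of trailing frames in which every region
#'   is driven to `saturation_nM`.
#' @param saturation_nM Concentration of the saturation step (default
#'   39,000 nM).
#' @param background_nM Concentration assigned to non-region pixels.
#' @param photon_budget Baseline expected photons per pixel (sets the
#'   phasor noise scale `0.3 / sqrt(photons)`).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(48L, 48L), regions,
                       n_frames = 10L, saturation_frames = 2L,
                       saturation_nM = 39000, background_nM = 50,
                       photon_budget = 1e4) {
  stopifnot(length(shape) == 2L, all(shape >= 4L), n_frames >= 1L,
            saturation_frames >= 0L, photon_budget > 0)
  for (r in regions) {
    stopifnot(all(c("center", "radii", "baseline_nM") %in% names(r)),
              r$baseline_nM >= 0,
              r$center[1] >= 1, r$center[1] <= shape[1],
              r$center[2] >= 1, r$center[2] <= shape[2])
  }
  structure(
    list(shape = as.integer(shape), regions = regions,
         n_frames = as.integer(n_frames),
         saturation_frames = as.integer(saturation_frames),
         saturation_nM = saturation_nM, background_nM = background_nM,
         photon_budget = photon_budget),
    class = "scene_spec"
  )
}

region_mask <- function(shape, region) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((rr - region$center[1]) / region$radii[1])^2 +
    ((cc - region$center[2]) / region$radii[2])^2 <= 1
}

scene_truth_frame <- function(scene, frame) {
  truth <- matrix(scene$background_nM, scene$shape[1], scene$shape[2])
  saturated <- frame > scene$n_frames - scene$saturation_frames
  for (r in scene$regions) {
    m <- region_mask(scene$shape, r)
    conc <- if (saturated) {
      scene$saturation_nM
    } else {
      amp <- if (is.null(r$oscillation_amp_nM)) 0 else r$oscillation_amp_nM
      per <- if (is.null(r$oscillation_period_frames)) Inf else r$oscillation_period_frames
      max(r$baseline_nM + amp * sin(2 * pi * frame / per), 0)
    }
    truth[m] <- conc
  }
  if (saturated) truth[] <- scene$saturation_nM
  truth
}

#' Simulate a calcium timelapse as phasor image stacks
#'
#' Per pixel and frame the true concentration (from the scene's program) is
#' mapped to a bound fraction through the calibration's Hill curve, placed
#' on the phasor mixing line, and perturbed with isotropic Gaussian noise of
#' sd `0.3 / sqrt(photons)`. The detected intensity scales with the
#' state-dependent brightness `(1 - F) + F * R`, so the saturated state is
#' dimmer by the factor `R`. Deterministic given `seed`.
#'
#' @param scene A [scene_spec()].
#' @param result A `calibration_result` (or list with `params` and
#'   `endpoints`).
#' @param seed Integer seed.
#' @param noiseless If `TRUE`, omit the phasor noise (exact mixing-line
#'   placement).
#' @return A list of 3-D arrays `(row, col, frame)`: `g`, `s`, `intensity`,
#'   `truth_nM`.
#' @export
gen_ca_timelapse <- function(scene, result, seed = 1L, noiseless = FALSE) {
  stopifnot(inherits(scene, "scene_spec"))
  params <- result$params
  ends <- result$endpoints
  stopifnot(inherits(params, "hill_params"),
            inherits(ends, "calibration_endpoints"))
  dims <- c(scene$shape, scene$n_frames)
  g <- array(NA_real_, dims)
  s <- array(NA_real_, dims)
  intensity <- array(NA_real_, dims)
  truth <- array(NA_real_, dims)
  rng <- local_rng(seed)
  noise_sd <- 0.3 / sqrt(scene$photon_budget)
  for (k in seq_len(scene$n_frames)) {
    tr <- scene_truth_frame(scene, k)
    f <- hill_fraction(as.numeric(tr), params)
    ph <- mix_phasor(f, ends)
    if (!noiseless) {
      ph$g <- ph$g + rng$rnorm(length(f), sd = noise_sd)
      ph$s <- ph$s + rng$rnorm(length(f), sd = noise_sd)
    }
    g[, , k] <- ph$g
    s[, , k] <- ph$s
    intensity[, , k] <- scene$photon_budget * ((1 - f) + f * ends$R)
    truth[, , k] <- tr
  }
  list(g = g, s = s, intensity = intensity, truth_nM = truth)
}

#' Sum-of-Gaussians synthetic spectra
#'
#' @param peaks_nm Peak centres (nm).
#' @param widths_nm Gaussian standard deviations (nm), recycled.
#' @param amplitudes Peak amplitudes, recycled.
#' @param grid Wavelength grid (nm).
#' @param kind Spectrum kind passed to [spectrum_data()].
#' @return A [spectrum_data()] object.
#' @export
gen_spectrum <- function(peaks_nm, widths_nm, amplitudes = 1,
                         grid = seq(300, 750, by = 1),
                         kind = "excitation") {
  stopifnot(all(widths_nm > 0))
  k <- length(peaks_nm)
  widths_nm <- rep_len(widths_nm, k)
  amplitudes <- rep_len(amplitudes, k)
  v <- rep(0, length(grid))
  for (i in seq_len(k)) {
    v <- v + amplitudes[i] * exp(-(grid - peaks_nm[i])^2 / (2 * widths_nm[i]^2))
  }
  spectrum_data(grid, v, kind)
}
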