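#' Time-domain decay model: biexponential with Gaussian IRF plus background
#'
#' Photon arrival times after a laser pulse are modeled as a mixture of a
#' uniform background (fraction `eps`, afterglow/dark counts spread over the
#' whole window) and up to two exponential decay components (fractions `f1`,
#' `f2`, time constants `tau1_ns <= tau2_ns`) each convolved with a Gaussian
#' instrument response of width `sigma_ns` centred at `mu_ns`. The fractions
#' satisfy `eps + f1 + f2 = 1`.
#'
#' @param eps Uniform-background fraction in \[0, 1\].
#' @param f1,f2 Decay-component fractions.
#' @param tau1_ns,tau2_ns Component time constants (ns); reordered so that
#'   `tau1_ns <= tau2_ns` (fractions follow).
#' @param sigma_ns Gaussian IRF standard deviation (ns, > 0).
#' @param mu_ns Gaussian IRF centre (ns, >= 0).
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(eps, f1, f2, tau1_ns, tau2_ns, sigma_ns, mu_ns) {
  vals <- c(eps = eps, f1 = f1, f2 = f2, tau1 = tau1_ns, tau2 = tau2_ns,
            sigma = sigma_ns, mu = mu_ns)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all decay-model fields must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(eps + f1 + f2 - 1) > 1e-9) {
    stop("fractions must satisfy eps + f1 + f2 = 1", call. = FALSE)
  }
  if ((f1 > 0 && tau1_ns == 0) || (f2 > 0 && tau2_ns == 0)) {
    stop("a component with positive fraction needs tau > 0", call. = FALSE)
  }
  if (sigma_ns <= 0) stop("`sigma_ns` must be positive", call. = FALSE)
  if (tau1_ns > tau2_ns) {  # canonical ordering
    tmp <- tau1_ns; tau1_ns <- tau2_ns; tau2_ns <- tmp
    tmp <- f1; f1 <- f2; f2 <- tmp
  }
  structure(
    list(eps = eps, f1 = f1, f2 = f2, tau1_ns = tau1_ns, tau2_ns = tau2_ns,
         sigma_ns = sigma_ns, mu_ns = mu_ns),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "Decay model: eps = %.4g, f1 = %.4g (tau1 = %.4g ns), f2 = %.4g (tau2 = %.4g ns), IRF N(%.4g, %.4g ns)\n",
    x$eps, x$f1, x$tau1_ns, x$f2, x$tau2_ns, x$mu_ns, x$sigma_ns))
  invisible(x)
}

#' Binned photon arrival-time histogram
#'
#' @param bin_centers_ns Ascending, uniformly spaced bin centres (ns). The
#'   window is `[0, t_max]` with `t_max = n_bins * bin_width`, i.e. centres
#'   sit at `(i - 1/2) * bin_width`.
#' @param counts Non-negative photon counts per bin.
#' @return An object of class `arrival_histogram` with fields
#'   `bin_centers_ns`, `counts`, `bin_width_ns`, `t_max_ns`.
#' @export
arrival_histogram <- function(bin_centers_ns, counts) {
  stopifnot(length(bin_centers_ns) == length(counts),
            length(bin_centers_ns) >= 1L)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(bin_centers_ns) > 1L) {
    w <- diff(bin_centers_ns)
    if (any(w <= 0) || (max(w) - min(w)) > 1e-9) {
      stop("bin centres must be ascending and uniformly spaced",
           call. = FALSE)
    }
    width <- mean(w)
  } else {
    width <- 2 * bin_centers_ns[1]
  }
  t_max <- length(bin_centers_ns) * width
  if (bin_centers_ns[1] < -1e-9 || bin_centers_ns[length(bin_centers_ns)] >
      t_max + 1e-9) {
    stop("bin centres must lie within [0, t_max]", call. = FALSE)
  }
  structure(
    list(bin_centers_ns = bin_centers_ns, counts = counts,
         bin_width_ns = width, t_max_ns = t_max),
    class = "arrival_histogram"
  )
}

# Log-density of a single exponential (time constant tau) convolved with a
# Gaussian N(mu, sigma). Evaluated in log space throughout: the erfc factor
# is obtained from the normal log-CDF, which stays accurate in the far tail
# where a direct erfc * exp product over/underflows.
emg_log_density <- function(t, tau, sigma, mu) {
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  log_erfc <- log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  -log(2 * tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau + log_erfc
}

emg_density <- function(t, tau, sigma, mu) {
  exp(emg_log_density(t, tau, sigma, mu))
}

# Upper-tail probability P(T > t) of the Gaussian-convolved exponential;
# survival form avoids cancellation when accumulating bin masses in the tail.
emg_survival <- function(t, tau, sigma, mu) {
  stats::pnorm((t - mu) / sigma, lower.tail = FALSE) +
    tau * emg_density(t, tau, sigma, mu)
}

#' Arrival-time probability density of a decay model
#'
#' \deqn{p(t) = \frac{\epsilon}{t_{max}}
#'   + f_1 F(t; \tau_1, \sigma, \mu) + f_2 F(t; \tau_2, \sigma, \mu)}
#' where `F` is the unit-normalised exponentially-modified-Gaussian density
#' (an exponential decay convolved with the Gaussian instrument response).
#' The density integrates to 1 over `[0, t_max]` up to the mass the IRF and
#' the slow tail leak outside the window (negligible when `mu - 5 sigma > 0`
#' and `t_max >> tau2`).
#'
#' @param t Time(s) in ns, within `[0, t_max]`.
#' @param model A [decay_model()].
#' @param t_max_ns Window length in ns.
#' @return Density values (1/ns).
#' @export
decay_pdf <- function(t, model, t_max_ns) {
  stopifnot(inherits(model, "decay_model"), t_max_ns > 0)
  if (any(t < 0 | t > t_max_ns)) {
    stop("`t` must lie within [0, t_max]", call. = FALSE)
  }
  p <- rep(model$eps / t_max_ns, length(t))
  if (model$f1 > 0) {
    p <- p + model$f1 *
      emg_density(t, model$tau1_ns, model$sigma_ns, model$mu_ns)
  }
  if (model$f2 > 0) {
    p <- p + model$f2 *
      emg_density(t, model$tau2_ns, model$sigma_ns, model$mu_ns)
  }
  p
}

# Per-bin probability mass of the model on the histogram's bin edges.
bin_probabilities <- function(model, edges, t_max_ns) {
  width <- diff(edges)
  p <- model$eps * width / t_max_ns
  for (comp in list(c(model$f1, model$tau1_ns), c(model$f2, model$tau2_ns))) {
    if (comp[1] > 0) {
      s <- emg_survival(edges, comp[2], model$sigma_ns, model$mu_ns)
      p <- p + comp[1] * (s[-length(s)] - s[-1])
    }
  }
  pmax(p, 0)
}

# Pearson chi-squared with tail bins pooled, from the end of the window
# inward, into consecutive groups whose expected counts reach min_expected.
# The statistic (not just its reference distribution) needs adequately
# filled bins: with expected counts near 1 its minimiser is biased, which
# propagates into the background fraction and hence the empirical lifetime.
pearson_chi2 <- function(counts, expected, min_expected = 10) {
  n <- length(counts)
  i <- n
  pool_c <- numeric(0)
  pool_e <- numeric(0)
  acc_c <- 0
  acc_e <- 0
  while (i >= 1L && expected[i] < min_expected) {
    acc_c <- acc_c + counts[i]
    acc_e <- acc_e + expected[i]
    if (acc_e >= min_expected) {
      pool_c <- c(pool_c, acc_c)
      pool_e <- c(pool_e, acc_e)
      acc_c <- 0
      acc_e <- 0
    }
    i <- i - 1L
  }
  if (acc_e > 0) {
    pool_c <- c(pool_c, acc_c)
    pool_e <- c(pool_e, acc_e)
  }
  counts <- c(counts[seq_len(i)], pool_c)
  expected <- c(expected[seq_len(i)], pool_e)
  keep <- expected > 0
  sum((counts[keep] - expected[keep])^2 / expected[keep])
}

softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

# theta -> decay_model for the 2-component parameterization
theta_to_model <- function(theta, n_components) {
  if (n_components == 2L) {
    fr <- softmax(c(theta[1], theta[2], 0))
    decay_model(eps = fr[1], f1 = fr[2], f2 = fr[3],
                tau1_ns = exp(theta[3]), tau2_ns = exp(theta[4]),
                sigma_ns = exp(theta[5]), mu_ns = theta[6])
  } else {
    fr <- softmax(c(theta[1], 0))
    decay_model(eps = fr[1], f1 = fr[2], f2 = 0,
                tau1_ns = exp(theta[2]), tau2_ns = exp(theta[2]),
                sigma_ns = exp(theta[3]), mu_ns = theta[4])
  }
}

#' Fit the decay model to an arrival-time histogram
#'
#' Minimises the Pearson chi-squared statistic between the observed counts
#' and the model's expected per-bin counts (total counts times the per-bin
#' mass, renormalised to the window). The mixture fractions are
#' parameterised on the simplex via a softmax transform so
#' `eps + f1 + f2 = 1` holds by construction; time constants and the IRF
#' width are fit on the log scale. Eight multi-starts spread the initial
#' time constants over decades around the histogram's mean arrival time;
#' ties are broken by lowest chi-squared, then lowest `tau1`. Tail bins are
#' pooled until expected counts reach 1.
#'
#' @param hist An [arrival_histogram()].
#' @param init Optional [decay_model()] used as one of the starts.
#' @param n_components 2 (default) or 1 decay components.
#' @param min_total_counts Guard against under-sampled histograms (default
#'   1e4 photons).
#' @param n_starts Number of multi-starts (default 8).
#' @param maxit Iteration cap per start for the Nelder-Mead search.
#' @return A list of class `decay_fit`: `model` (the fitted
#'   [decay_model()]), `chi2`, `chi2_reduced`, `converged`, `n_bins_pooled`.
#' @export
fit_decay <- function(hist, init = NULL, n_components = 2L,
                      min_total_counts = 1e4, n_starts = 8L, maxit = 2000L) {
  stopifnot(inherits(hist, "arrival_histogram"))
  n_tot <- sum(hist$counts)
  if (n_tot <= 0 || length(hist$counts) < 2L) {
    stop("histogram must have at least 2 bins and positive total counts",
         call. = FALSE)
  }
  if (n_tot < min_total_counts) {
    stop(sprintf("only %d photons; need >= %g for a stable decay fit",
                 n_tot, min_total_counts), call. = FALSE)
  }
  edges <- c(hist$bin_centers_ns - hist$bin_width_ns / 2,
             hist$t_max_ns)
  edges[1] <- max(edges[1], 0)

  objective <- function(theta) {
    m <- tryCatch(theta_to_model(theta, n_components),
                  error = function(e) NULL)
    if (is.null(m) || m$mu_ns < 0 || m$mu_ns > hist$t_max_ns) return(1e12)
    p <- bin_probabilities(m, edges, hist$t_max_ns)
    tot <- sum(p)
    if (!is.finite(tot) || tot <= 0) return(1e12)
    pearson_chi2(hist$counts, n_tot * p / tot)
  }

  # data-driven starts: mean arrival time sets the tau decade, the modal bin
  # locates the IRF centre
  m_arr <- sum(hist$bin_centers_ns * hist$counts) / n_tot
  mu0 <- hist$bin_centers_ns[which.max(hist$counts)]
  tau_scale <- max(m_arr - mu0, 2 * hist$bin_width_ns)
  tau_grid <- tau_scale * c(0.25, 0.5, 1, 2, 4)
  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "decay_model"))
    starts[[1]] <- model_to_theta(init, n_components)
  }
  set_seeded <- function(i) {
    t1 <- tau_grid[1 + (i - 1) %% length(tau_grid)]
    t2 <- t1 * c(2, 4, 8)[1 + (i - 1) %% 3]
    if (n_components == 2L) {
      c(log(0.02 / 0.49), 0, log(t1), log(t2), log(0.1), mu0)
    } else {
      c(log(0.02 / 0.98), log(t1), log(0.1), mu0)
    }
  }
  for (i in seq_len(n_starts)) starts[[length(starts) + 1L]] <- set_seeded(i)

  # stage 1: a moderate search from every start; stage 2: restart the
  # Nelder-Mead simplex from the two best candidates (restarting resets the
  # simplex size, which escapes the premature shrinkage the method is prone
  # to in 6 dimensions)
  stage1 <- lapply(starts, function(st) {
    stats::optim(st, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  })
  ord <- order(vapply(stage1, `[[`, 0, "value"))
  best <- NULL
  for (idx in ord[seq_len(min(2L, length(ord)))]) {
    opt <- stage1[[idx]]
    for (round in 1:2) {
      opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 2L * maxit,
                                         reltol = 1e-12))
    }
    tau1_of <- function(o) exp(o$par[if (n_components == 2L) 3 else 2])
    if (is.null(best) ||
        opt$value < best$value - 1e-9 ||
        (abs(opt$value - best$value) <= 1e-9 &&
         tau1_of(opt) < tau1_of(best))) {
      best <- opt
    }
  }
  model <- theta_to_model(best$par, n_components)
  p <- bin_probabilities(model, edges, hist$t_max_ns)
  expected <- n_tot * p / sum(p)
  n_pooled <- sum(cumprod(rev(expected) < 10))
  n_free <- if (n_components == 2L) 6L else 4L
  structure(
    list(
      model = model,
      chi2 = best$value,
      chi2_reduced = best$value /
        max(length(hist$counts) - n_pooled - n_free, 1L),
      converged = best$convergence == 0L,
      n_bins_pooled = n_pooled
    ),
    class = "decay_fit"
  )
}

model_to_theta <- function(model, n_components) {
  clip <- function(x) max(x, 1e-12)
  if (n_components == 2L) {
    f2 <- clip(model$f2)
    c(log(clip(model$eps) / f2), log(clip(model$f1) / f2),
      log(clip(model$tau1_ns)), log(clip(model$tau2_ns)),
      log(model$sigma_ns), model$mu_ns)
  } else {
    f1 <- clip(model$f1 + model$f2)
    c(log(clip(model$eps) / f1), log(clip(model$tau1_ns)),
      log(model$sigma_ns), model$mu_ns)
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  chi2 = %.4g (reduced %.4g), converged: %s\n",
              x$chi2, x$chi2_reduced, x$converged))
  invisible(x)
}

#' Empirical lifetime of a photon collection
#'
#' The mean photon arrival time of the histogram, corrected for the fitted
#' IRF offset and the uniform background (whose mean arrival time is
#' `t_max/2`):
#' \deqn{L = \langle p \rangle - (\mu + \epsilon\, t_{max}/2).}
#' This estimator needs no full deconvolution and is what per-frame lifetime
#' traces are built from.
#'
#' @param hist An [arrival_histogram()].
#' @param model A fitted or known [decay_model()] (or a `decay_fit`).
#' @return Empirical lifetime in ns.
#' @export
empirical_lifetime <- function(hist, model) {
  stopifnot(inherits(hist, "arrival_histogram"))
  if (inherits(model, "decay_fit")) model <- model$model
  stopifnot(inherits(model, "decay_model"))
  n_tot <- sum(hist$counts)
  if (n_tot <= 0) stop("histogram is empty", call. = FALSE)
  mean_arrival <- sum(hist$bin_centers_ns * hist$counts) / n_tot
  mean_arrival - (model$mu_ns + model$eps * hist$t_max_ns / 2)
}

#' Intensity-weighted mean lifetime over a series of frames
#'
#' Weights each frame's lifetime by its photon count:
#' \deqn{\langle L \rangle = \sum_k \frac{I_k L_k}{n \langle I \rangle}}
#' which reduces to the photon-weighted mean \eqn{\sum I_k L_k / \sum I_k}.
#'
#' @param intensity Per-frame photon counts (>= 0, at least one positive).
#' @param lifetime_ns Per-frame empirical lifetimes (ns).
#' @return Mean intensity-weighted lifetime (ns).
#' @export
intensity_weighted_lifetime <- function(intensity, lifetime_ns) {
  stopifnot(length(intensity) == length(lifetime_ns), length(intensity) >= 1L)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (sum(intensity) <= 0) stop("all frame intensities are zero", call. = FALSE)
  n <- length(intensity)
  sum(intensity * lifetime_ns) / (n * mean(intensity))
}

#' Phasor coordinates of an arrival-time histogram
#'
#' First-harmonic cosine/sine transform of the histogram at the modulation
#' frequency, relative to a zero-time reference:
#' \eqn{G = \sum c_i \cos(\omega (t_i - t_0)) / \sum c_i} and likewise with
#' sine for `S`. Bridges time-domain TCSPC data into the phasor calibration
#' pipeline.
#'
#' @param hist An [arrival_histogram()].
#' @param mod A [modulation_settings()] object, or a frequency in MHz.
#' @param zero_time_ns Zero-time reference `t_0` (e.g. the IRF centre).
#' @return A data.frame with columns `g` and `s`.
#' @export
phasor_from_histogram <- function(hist, mod = modulation_settings(),
                                  zero_time_ns = 0) {
  stopifnot(inherits(hist, "arrival_histogram"))
  mod <- as_modulation(mod)
  n_tot <- sum(hist$counts)
  if (n_tot <= 0) stop("histogram is empty", call. = FALSE)
  w <- mod$omega_rad_per_ns
  t <- hist$bin_centers_ns - zero_time_ns
  data.frame(
    g = sum(hist$counts * cos(w * t)) / n_tot,
    s = sum(hist$counts * sin(w * t)) / n_tot
  )
}

#' Foreground mask from an intensity image
#'
#' Separates signal-bearing pixels from background. The default Otsu method
#' picks the threshold that minimises intra-class intensity variance; the
#' quantile method keeps the brightest `1 - q` of pixels and is invariant
#' under monotone intensity rescaling.
#'
#' @param img Non-negative numeric matrix.
#' @param method `"otsu"` or `"quantile"`.
#' @param q Quantile for the quantile method (default 0.5).
#' @return A list with `mask` (logical matrix, `TRUE` = foreground) and
#'   `threshold`. A constant image yields an all-background mask with a
#'   warning.
#' @export
foreground_mask <- function(img, method = c("otsu", "quantile"), q = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(img))
  if (any(img < 0)) stop("intensity image must be non-negative", call. = FALSE)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant image: returning an all-background mask")
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)), threshold = NA_real_))
  }
  if (method == "otsu") {
    scaled <- (img - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    threshold <- rng[1] + thr01 * (rng[2] - rng[1])
  } else {
    threshold <- stats::quantile(img, q, names = FALSE)
  }
  list(mask = img > threshold, threshold = threshold)
}
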