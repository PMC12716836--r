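test_that("decay_pdf is a proper density over the acquisition window", {
  # pure uniform: constant 1/t_max
  mu_only <- decay_model(1, 0, 0, 1, 1, 0.1, 0)
  t <- seq(0, 50, by = 0.5)
  expect_equal(decay_pdf(t, mu_only, 50), rep(1 / 50, length(t)))

  # adaptive-quadrature check of normalization
  m <- decay_model(0.01, 0.5, 0.49, 1, 3, 0.05, 2)
  q <- integrate(function(x) decay_pdf(x, m, 50), 0, 50,
                 rel.tol = 1e-10, subdivisions = 500L)
  expect_equal(q$value, 1, tolerance = 1e-6)

  # vanishing IRF width: the component collapses to a plain exponential
  m0 <- decay_model(0, 1, 0, 2, 2, 1e-6, 0)
  tt <- seq(0.01, 20, by = 0.01)
  expect_lt(max(abs(decay_pdf(tt, m0, 50) - exp(-tt / 2) / 2)), 1e-6)

  # numerically stable for large sigma/tau ratios
  mw <- decay_model(0, 1, 0, 0.05, 0.05, 0.5, 3)
  v <- decay_pdf(seq(0, 25, by = 0.01), mw, 25)
  expect_true(all(is.finite(v)) && all(v >= 0))

  expect_error(decay_model(0.1, 0.9, 0, 0, 0, 0.1, 1), "tau > 0")
  expect_error(decay_model(0.5, 0.4, 0.4, 1, 2, 0.1, 1), "eps \\+ f1 \\+ f2")
})

test_that("decay_model keeps the canonical component ordering", {
  m <- decay_model(0.01, 0.2, 0.79, 5, 1, 0.1, 1)
  expect_equal(m$tau1_ns, 1)
  expect_equal(m$tau2_ns, 5)
  expect_equal(m$f1, 0.79)  # fractions follow their time constants
  expect_equal(m$f2, 0.2)
})

test_that("fit_decay recovers known models from sampled photons", {
  # two components, 1e6 photons
  truth <- decay_model(0.01, 0.495, 0.495, 1, 3, 0.1, 1.0)
  h <- gen_tcspc_histogram(truth, 1e6, 25, 0.01, seed = 21)
  fit <- fit_decay(h)
  expect_lt(abs(fit$model$tau1_ns - 1) / 1, 0.05)
  expect_lt(abs(fit$model$tau2_ns - 3) / 3, 0.05)
  expect_lt(abs(fit$model$eps - 0.01), 0.005)
  expect_true(fit$converged)

  # degenerate truth: a pure-uniform histogram
  u <- gen_tcspc_histogram(decay_model(1, 0, 0, 1, 1, 0.1, 0), 2e4, 25,
                           0.05, seed = 3)
  fu <- fit_decay(u)
  expect_gt(fu$model$eps, 0.98)
  expect_lt(fu$model$f1 + fu$model$f2, 0.02)

  expect_error(fit_decay(gen_tcspc_histogram(truth, 100, 25, 0.05, seed = 1)),
               "photons")
})

test_that("a mono-exponential fitted with two components stays identifiable", {
  truth <- mono_model(2.0)
  h <- gen_tcspc_histogram(truth, 5e5, 25, 0.01, seed = 31)
  fit <- fit_decay(h)
  # the two recovered time constants collapse onto the truth and the total
  # decay fraction is preserved
  expect_lt(abs(fit$model$tau1_ns - 2) / 2, 0.02)
  expect_lt(abs(fit$model$tau2_ns - 2) / 2, 0.02)
  expect_lt(abs(fit$model$f1 + fit$model$f2 - 0.995), 0.01)
})

test_that("empirical_lifetime matches closed-form oracles", {
  # exactly uniform histogram with eps = 1, mu = 0: zero lifetime
  noise <- decay_model(1, 0, 0, 1, 1, 0.1, 0)
  hu <- arrival_histogram(seq(0.05, 24.95, by = 0.1), rep(10, 250))
  expect_equal(empirical_lifetime(hu, noise), 0, tolerance = 1e-12)

  # noise-free single-component histogram vs the window-truncated
  # exponential mean (truncation measured from the IRF centre)
  m <- decay_model(0, 0.5, 0.5, 2.5, 2.5, 0.05, 1)
  h <- exact_histogram(m, 25, 0.005)
  Tp <- 25 - 1
  oracle <- 2.5 - Tp * exp(-Tp / 2.5) / (1 - exp(-Tp / 2.5))
  expect_equal(empirical_lifetime(h, m), oracle, tolerance = 1e-5)

  # wide-window limit: L converges to tau
  m2 <- decay_model(0, 1, 0, 1, 1, 0.01, 1)
  h2 <- exact_histogram(m2, 100, 0.002)
  expect_equal(empirical_lifetime(h2, m2), 1, tolerance = 1e-6)

  # invariant to rescaling the counts
  h_scaled <- arrival_histogram(h$bin_centers_ns, h$counts * 37.5)
  expect_equal(empirical_lifetime(h_scaled, m), empirical_lifetime(h, m))
})

test_that("decay fitting plus the lifetime estimator is unbiased", {
  truth <- mono_model(2.2)
  target <- empirical_lifetime(exact_histogram(truth, 25, 0.01), truth)
  errs <- vapply(1:6, function(seed) {
    h <- gen_tcspc_histogram(truth, 5e5, 25, 0.01, seed = 200 + seed)
    empirical_lifetime(h, fit_decay(h)) - target
  }, 0)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("intensity weighting of frame lifetimes is the photon-weighted mean", {
  expect_equal(intensity_weighted_lifetime(c(1, 3), c(2, 4)), 3.5)
  expect_equal(intensity_weighted_lifetime(rep(7, 5), 1:5), 3)
  expect_equal(intensity_weighted_lifetime(42, 2.71), 2.71)
  expect_error(intensity_weighted_lifetime(c(0, 0), c(1, 2)), "zero")
})

test_that("phasor_from_histogram matches analytic transforms", {
  mod <- modulation_settings(40)
  w <- mod$omega_rad_per_ns

  # all counts at the zero-time bin
  centers <- seq(0.05, 24.95, by = 0.1)
  counts <- numeric(250); counts[20] <- 500
  ph0 <- phasor_from_histogram(arrival_histogram(centers, counts), mod,
                               zero_time_ns = centers[20])
  expect_equal(c(ph0$g, ph0$s), c(1, 0))

  # dense noise-free mono-exponential vs the closed-form phasor
  tau <- 2.5; dt <- 0.01
  edges <- seq(0, 250, by = dt)
  cexp <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
  ph <- phasor_from_histogram(
    arrival_histogram(edges[-length(edges)] + dt / 2, cexp), mod, 0)
  expect_equal(ph$g, 1 / (1 + (w * tau)^2), tolerance = 1e-4)
  expect_equal(ph$s, w * tau / (1 + (w * tau)^2), tolerance = 1e-4)

  # uniform histogram over one full modulation period averages to zero
  period <- 2 * pi / w  # 25 ns at 40 MHz
  hu <- arrival_histogram(seq(period / 500 / 2, period, by = period / 500),
                          rep(3, 500))
  phu <- phasor_from_histogram(hu, mod, 0)
  expect_lt(abs(phu$g), 1e-9)
  expect_lt(abs(phu$s), 1e-9)

  # linearity: the phasor of a count mixture is the count-weighted average
  c1 <- cexp * 2; c2 <- rev(cexp) * 5
  h1 <- arrival_histogram(edges[-length(edges)] + dt / 2, c1)
  h2 <- arrival_histogram(edges[-length(edges)] + dt / 2, c2)
  hmix <- arrival_histogram(edges[-length(edges)] + dt / 2, c1 + c2)
  p1 <- phasor_from_histogram(h1, mod); p2 <- phasor_from_histogram(h2, mod)
  pm <- phasor_from_histogram(hmix, mod)
  wgt <- sum(c1) / sum(c1 + c2)
  expect_equal(pm$g, wgt * p1$g + (1 - wgt) * p2$g, tolerance = 1e-9)
  expect_equal(pm$s, wgt * p1$s + (1 - wgt) * p2$s, tolerance = 1e-9)
})

test_that("foreground masking separates signal from background", {
  set.seed(13)
  img <- matrix(abs(rnorm(400, 1, 0.2)), 20, 20)
  bright <- matrix(FALSE, 20, 20); bright[6:15, 6:15] <- TRUE
  img[bright] <- rnorm(sum(bright), 10, 0.5)
  fm <- foreground_mask(img, "otsu")
  expect_identical(fm$mask, bright)

  expect_warning(fz <- foreground_mask(matrix(0, 5, 5)), "constant")
  expect_false(any(fz$mask))

  # quantile method is rank-based: invariant under monotone rescaling
  fq1 <- foreground_mask(img, "quantile", q = 0.6)
  fq2 <- foreground_mask(sqrt(img) * 3, "quantile", q = 0.6)
  expect_identical(fq1$mask, fq2$mask)
})
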