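test_that("hill_fraction handles the limits and stays strictly monotone", {
  p <- hill_params(200, 1.5, F_min = 0.05, F_max = 0.95)
  expect_equal(hill_fraction(200, p), (0.05 + 0.95) / 2)
  expect_equal(hill_fraction(0, p), 0.05)
  expect_equal(hill_fraction(1e9 * 200, p), 0.95, tolerance = 1e-9)
  L <- exp(seq(log(1), log(1e6), length.out = 200))
  expect_true(all(diff(hill_fraction(L, p)) > 0))
})

test_that("concentration_from_fraction inverts the Hill curve with flags", {
  p <- hill_params(209, 1.53)
  expect_equal(concentration_from_fraction(0.5, p)$L_nM, 209)
  lo <- concentration_from_fraction(0, p)
  expect_equal(lo$L_nM, 0)
  expect_equal(lo$flag, "below")
  hi <- concentration_from_fraction(1, p)
  expect_equal(hi$L_nM, Inf)
  expect_equal(hi$flag, "saturated")

  f <- seq(0.01, 0.99, by = 0.01)
  back <- hill_fraction(concentration_from_fraction(f, p)$L_nM, p)
  expect_lt(max(abs(back - f) / f), 1e-9)
  # strictly increasing inside (F_min, F_max)
  expect_true(all(diff(concentration_from_fraction(f, p)$L_nM) > 0))
})

test_that("a noiseless calibration series is fitted exactly", {
  truth <- hill_params(200, 1.5, F_min = 0, F_max = 1)
  ends <- ref_37$endpoints
  series <- gen_calibration_series(truth, ends, phasor_noise_sd = 0, seed = 1)
  res <- fit_hill(series, ends = ends)
  expect_equal(res$params$Kd_nM, 200, tolerance = 1e-6)
  expect_equal(res$params$hill_n, 1.5, tolerance = 1e-6)
  expect_lt(res$residual_norm, 1e-10)
  expect_true(res$converged)
})

test_that("degenerate series are rejected as underdetermined", {
  df <- data.frame(replicate = 1:6, free_ca_nM = rep(c(0, 100), 3),
                   g = runif(6), s = runif(6, 0, 0.5))
  expect_error(fit_hill(df), "underdetermined")
  df_same <- data.frame(replicate = 1:3, free_ca_nM = 100,
                        g = 0.6, s = 0.4)
  expect_error(calibration_series(df_same), "distinct")
})

test_that("the full pipeline recovers the 37 degC affinity from noisy phasors", {
  series <- gen_calibration_series(ref_37$truth, ref_37$endpoints,
                                   phasor_noise_sd = 0.003, seed = 101)
  res <- fit_hill(series, ends = ref_37$endpoints)
  expect_lt(abs(res$params$Kd_nM - 209) / 209, 0.05)
  expect_lt(abs(res$params$hill_n - 1.53), 0.1)
  # the confidence interval brackets the point estimate
  ci <- res$ci95
  expect_true(ci$lo[1] < res$params$Kd_nM && res$params$Kd_nM < ci$hi[1])
})

test_that("parameter recovery is unbiased over repeated noisy simulations", {
  errs <- t(vapply(1:100, function(seed) {
    s <- gen_calibration_series(ref_37$truth, ref_37$endpoints,
                                phasor_noise_sd = 0.003, seed = seed)
    r <- fit_hill(s, ends = ref_37$endpoints)
    c(kd = abs(r$params$Kd_nM - 209) / 209,
      n = abs(r$params$hill_n - 1.53))
  }, c(kd = 0, n = 0)))
  expect_lt(median(errs[, "kd"]), 0.05)
  expect_lt(median(errs[, "n"]), 0.1)
})

test_that("measurable_range matches a brute-force oracle and narrows with noise", {
  truth <- hill_params(209, 1.53)
  series <- gen_calibration_series(truth, ref_37$endpoints,
                                   phasor_noise_sd = 0.002, seed = 5)
  res <- fit_hill(series, ends = ref_37$endpoints)

  # brute-force: mean +/- t * sd / sqrt(n) pushed through the Hill inverse
  lo_f <- c(0.001, 0.004, 0.002, 0.006)
  hi_f <- c(0.990, 0.994, 0.988, 0.992)
  mr <- measurable_range(res, list(low = lo_f, high = hi_f))
  p <- res$params
  f_lo <- mean(lo_f) + qt(0.975, 3) * sd(lo_f) / 2
  f_hi <- mean(hi_f) - qt(0.975, 3) * sd(hi_f) / 2
  oracle_lo <- p$Kd_nM * ((f_lo - p$F_min) / (p$F_max - f_lo))^(1 / p$hill_n)
  oracle_hi <- p$Kd_nM * ((f_hi - p$F_min) / (p$F_max - f_hi))^(1 / p$hill_n)
  expect_equal(mr$L_lo_nM, oracle_lo, tolerance = 1e-9)
  expect_equal(mr$L_hi_nM, oracle_hi, tolerance = 1e-9)
  expect_lt(mr$L_lo_nM, p$Kd_nM)
  expect_gt(mr$L_hi_nM, p$Kd_nM)

  # widening the replicate sd strictly narrows the measurable range
  widths <- vapply(c(0.002, 0.005, 0.01, 0.02), function(s) {
    lo <- 0.002 + s * scale(c(-1, 0, 1, 0.5))[, 1]
    hi <- 0.992 + s * scale(c(1, -1, 0.2, -0.4))[, 1]
    m <- measurable_range(res, list(low = lo, high = hi))
    log(m$L_hi_nM) - log(m$L_lo_nM)
  }, 0)
  expect_true(all(diff(widths) < 0))

  # identical replicates: degenerate, full range
  dg <- measurable_range(res, list(low = c(0.01, 0.01), high = c(0.99, 0.99)))
  expect_true(dg$degenerate)
  expect_equal(dg$L_lo_nM, 0)
  expect_equal(dg$L_hi_nM, Inf)
})

test_that("phasor images convert to concentration maps with flags", {
  truth <- hill_params(209, 1.53)
  series <- gen_calibration_series(truth, ref_37$endpoints,
                                   phasor_noise_sd = 0, seed = 1)
  res <- fit_hill(series, ends = ref_37$endpoints)

  # uniform image at the apo endpoint: everything 0 nM, below range
  g0 <- matrix(res$endpoints$g_min, 8, 8)
  s0 <- matrix(res$endpoints$s_min, 8, 8)
  m0 <- phasor_image_to_ca_map(g0, s0, res)
  expect_true(all(m0$ca_nM == 0))
  expect_true(all(m0$flags == 1L))

  # image generated at the fraction for 209 nM recovers 209 nM
  f209 <- hill_fraction(209, res$params)
  ph <- mix_phasor(rep(f209, 64), res$endpoints)
  set.seed(3)
  g <- matrix(ph$g + rnorm(64, sd = 5e-4), 8, 8)
  s <- matrix(ph$s + rnorm(64, sd = 5e-4), 8, 8)
  m <- phasor_image_to_ca_map(g, s, res)
  expect_equal(median(m$ca_nM), 209, tolerance = 0.05)

  # a masked pixel is NA/flag 3 and neighbours are untouched
  mask <- matrix(TRUE, 8, 8)
  mask[3, 4] <- FALSE
  mm <- phasor_image_to_ca_map(g, s, res, mask = mask)
  expect_true(is.na(mm$ca_nM[3, 4]))
  expect_identical(mm$flags[3, 4], 3L)
  expect_equal(mm$ca_nM[-(8 * 3 + 3)], m$ca_nM[-(8 * 3 + 3)])

  # permutation equivariance of the pixel pipeline
  perm <- sample(64)
  gp <- matrix(as.numeric(g)[perm], 8, 8)
  sp <- matrix(as.numeric(s)[perm], 8, 8)
  mp <- phasor_image_to_ca_map(gp, sp, res)
  expect_equal(as.numeric(mp$ca_nM), as.numeric(m$ca_nM)[perm])

  expect_error(phasor_image_to_ca_map(g, s[1:4, ], res), "shape")
})

test_that("in-situ endpoints are recovered from a saturation-terminated timelapse", {
  truth <- hill_params(209, 1.53)
  scene <- scene_spec(
    shape = c(24, 24),
    regions = list(
      list(center = c(8, 8), radii = c(4, 3), baseline_nM = 20),
      list(center = c(17, 16), radii = c(3, 5), baseline_nM = 60)
    ),
    n_frames = 6, saturation_frames = 1, background_nM = 10,
    photon_budget = 1e5
  )
  cal <- list(params = truth, endpoints = ref_37$endpoints)
  tl <- gen_ca_timelapse(scene, cal, seed = 9)
  ends_hat <- estimate_extremes_from_timelapse(tl$g, tl$s, R = 0.836)

  # low concentrations put baseline pixels near apo; the last frame is sat
  noise <- 0.3 / sqrt(scene$photon_budget)
  expect_lt(abs(ends_hat$g_max - ref_37$endpoints$g_max), 2 * noise)
  expect_lt(abs(ends_hat$s_max - ref_37$endpoints$s_max), 2 * noise)
  # apo estimate sits on the generating mixing line within 2 noise sd
  a_hat <- project_line_fraction(ends_hat$g_min, ends_hat$s_min,
                                 ref_37$endpoints)
  seg <- sqrt((ref_37$endpoints$g_max - ref_37$endpoints$g_min)^2 +
              (ref_37$endpoints$s_max - ref_37$endpoints$s_min)^2)
  on_line <- c(ref_37$endpoints$g_min + a_hat$a *
                 (ref_37$endpoints$g_max - ref_37$endpoints$g_min),
               ref_37$endpoints$s_min + a_hat$a *
                 (ref_37$endpoints$s_max - ref_37$endpoints$s_min))
  expect_lt(sqrt(sum((c(ends_hat$g_min, ends_hat$s_min) - on_line)^2)),
            2 * noise)

  # a constant timelapse has no distinct extremes
  const <- array(0.6, c(4, 4, 3))
  expect_error(
    estimate_extremes_from_timelapse(const, array(0.3, c(4, 4, 3))),
    "degenerate"
  )
  expect_error(
    estimate_extremes_from_timelapse(tl$g[, , 1, drop = FALSE],
                                     tl$s[, , 1, drop = FALSE]),
    "2 frames"
  )
})
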