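# Shared fixtures for the test suite. Everything is generated in code; no
# binary files.

ref_37 <- reference_calibration("37C")
ref_rt <- reference_calibration("RT")

# a small mono-exponential decay model for TCSPC tests
mono_model <- function(tau, eps = 0.005, sigma = 0.1, mu = 1.0) {
  decay_model(eps = eps, f1 = 1 - eps, f2 = 0, tau1_ns = tau, tau2_ns = tau,
              sigma_ns = sigma, mu_ns = mu)
}

# noise-free histogram: expected per-bin masses of a model, scaled to n
exact_histogram <- function(model, t_max_ns, bin_width_ns, n = 1e6) {
  n_bins <- round(t_max_ns / bin_width_ns)
  edges <- seq(0, t_max_ns, length.out = n_bins + 1L)
  p <- flimcal:::bin_probabilities(model, edges, t_max_ns)
  arrival_histogram(edges[-length(edges)] + bin_width_ns / 2,
                    n * p / sum(p))
}
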