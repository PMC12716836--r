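# flimcal

Quantitative calcium imaging from fluorescence lifetime data.

Lifetime-based genetically encoded calcium indicators report calcium through
the fluorescence lifetime of the sensor rather than its brightness, which
makes them robust to expression level and illumination — but turning a
lifetime image into a concentration requires a calibration chain. `flimcal`
implements that chain for two-state sensors, for both frequency-domain FLIM
and time-correlated single photon counting (TCSPC):

* **Phasor conversion.** Phase/modulation lifetime pairs
  (τ<sub>φ</sub>, τ<sub>M</sub>) map to phasor coordinates
  G = M cos Φ, S = M sin Φ with Φ = arctan(ωτ<sub>φ</sub>),
  M = (1 + (ωτ<sub>M</sub>)²)<sup>−1/2</sup>.
* **Two-state mixing line.** Measurements are projected onto the segment
  between the calcium-free (apo) and calcium-saturated (sat) phasors, and
  the intensity-weighted line fraction *a* is corrected with the two-state
  brightness ratio *R* into the molecular bound fraction
  F = a / (R(1−a) + a).
* **Hill calibration.** Bound fractions from a buffer series with known free
  calcium L are fitted with
  F = F<sub>min</sub> + (F<sub>max</sub> − F<sub>min</sub>) / ((K<sub>d</sub>/L)<sup>n</sup> + 1)
  by bounded nonlinear least squares, yielding K<sub>d</sub>, the Hill
  coefficient n, 95% confidence intervals and the measurable concentration
  range; phasor images then convert pixelwise to calcium maps with
  below-range/saturated/masked flags.
* **TCSPC decay model.** Arrival-time histograms are modeled as a
  biexponential convolved with a Gaussian instrument response plus uniform
  background, fitted by Pearson chi-squared minimization; the empirical
  lifetime L = ⟨p⟩ − (μ + ε t<sub>max</sub>/2) and intensity-weighted frame
  means summarize responses.
* **Photophysics and synthetic data.** Quantum yield by origin-forced slope
  regression, extinction coefficient via the denatured-chromophore
  Beer–Lambert method, a modeled two-state intensity ratio, and seeded
  generators for every input the pipeline consumes (calibration series,
  photon histograms, calcium timelapses, spectra).

## Worked example

Simulate an in-vitro calibration at 37 °C (published endpoint lifetimes,
R = 0.836), fit it, and convert an image:

```r
library(flimcal)

ref <- reference_calibration("37C")
series <- gen_calibration_series(ref$truth, ref$endpoints,
                                 phasor_noise_sd = 0.003, seed = 7)
res <- fit_hill(series, ends = ref$endpoints)
print(res)
#> Hill calibration fit
#> Hill model: Kd = 198.7 nM, n = 1.443, F in [0, 1]
#>   Kd_nM        198.7  [189.1, 208.7]
#>   hill_n       1.443  [1.356, 1.536]
#>   F_min            0  [-0.01322, 0.01322]
#>   F_max            1  [0.9896, 1.01]
#>   residual norm 0.0874; measurable range 37.5 - 2.12e+03 nM
```

The fitted affinity (198.7 nM, CI 189–209 nM) recovers the generating
K<sub>d</sub> of 209 nM from 33 noisy measurements; the measurable range is
where the extreme-buffer replicate scatter still allows inversion. A phasor
image taken at 500 nM converts back through the calibration:

```r
f <- hill_fraction(500, res$params)
ph <- mix_phasor(f, res$endpoints)
cm <- phasor_image_to_ca_map(matrix(ph$g, 4, 4), matrix(ph$s, 4, 4), res)
median(cm$ca_nM)
#> [1] 500
```

TCSPC side — sample 5×10⁵ photons from a 2.2 ns decay (ε = 0.005 background,
Gaussian IRF at μ = 1 ns, σ = 0.1 ns), fit, and estimate the lifetime:

```r
h <- gen_tcspc_histogram(decay_model(0.005, 0.995, 0, 2.2, 2.2, 0.1, 1),
                         n_photons = 5e5, t_max_ns = 25,
                         bin_width_ns = 0.01, seed = 3)
fit <- fit_decay(h)
empirical_lifetime(h, fit)
#> [1] 2.188
```

2.188 ns is the mean arrival time corrected for the fitted IRF offset and
background — for a mono-exponential truth this sits slightly below τ by the
background and window-truncation terms, which cancel in between-condition
differences (how responses are reported).

A thin command-line wrapper over the same functions lives at
`inst/cli/flimcal.R` (subcommands `simulate-calibration`, `simulate-tcspc`,
`calibrate`, `convert`, `tcspc-fit`, `report-change`; each writes a JSON run
log).

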