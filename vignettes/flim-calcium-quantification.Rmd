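---
title: "Quantifying calcium from fluorescence lifetime data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium from fluorescence lifetime data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimcal)
```

## The measurement problem

Genetically encoded calcium indicators with a lifetime read-out report
calcium not through brightness — which confounds expression level, focus and
illumination — but through the fluorescence lifetime of the sensor, which
changes as calcium binds. A lifetime-based sensor has two photophysical
states: the calcium-free (apo) state with a long lifetime and the
calcium-bound (sat) state with a short one. A pixel's measured decay is an
intensity-weighted mixture of the two. `flimcal` turns such measurements into
absolute calcium concentrations, and provides the time-domain (TCSPC)
machinery needed when the same sensors are imaged by photon counting.

## Phasor representation and the mixing line

Frequency-domain FLIM yields a phase lifetime $\tau_\phi$ and a modulation
lifetime $\tau_M$ per pixel or well, at modulation frequency $f$ (default
40 MHz; $\omega = 2\pi f$). These map to phasor coordinates

$$\Phi = \arctan(\omega\tau_\phi), \qquad
  M = \sqrt{1/(1+(\omega\tau_M)^2)}, \qquad
  G = M\cos\Phi,\; S = M\sin\Phi.$$

Mono-exponential decays land on the universal semicircle; mixtures combine
linearly by detected intensity, so every apo/sat mixture falls on the straight
segment between the two state phasors. A measurement is orthogonally
projected onto that segment to give the line fraction $a$
(`project_line_fraction()`), which is deliberately returned *unclamped* with
an `in_range` flag: points beyond the extremes are information about noise
and calibration drift, and clamping happens only when concentrations are
computed.

Because the bound state is dimmer than the free state (brightness ratio
$R$, 0.836 for the green sensor under its calibration instrument), the line
fraction over-represents the brighter state. The molecular bound fraction is

$$F = \frac{a}{R(1-a) + a},$$

with $F = a$ exactly when $R = 1$. The inverse map (`line_fraction_from_bound()`)
is what the simulators use to place known mixtures on the line.

## Hill calibration

A calibration series measures the sensor in buffers of known free calcium
$L$ (a ladder spanning 0–39 µM). Each measurement is converted to $F$ as
above and fitted with the Hill equation

$$F(L) = F_{\min} + \frac{F_{\max}-F_{\min}}{(K_d/L)^n + 1}.$$

Design choices, where the procedure was genuinely open:

* **Solver and parameterisation.** Bounded nonlinear least squares
  (Levenberg–Marquardt via `minpack.lm::nlsLM`), with $\log K_d$ and
  $\log n$ as internal parameters so positivity holds by construction, and
  box bounds $F_{\min}\in[0,0.5]$, $F_{\max}\in[0.5,1]$. Plain `nls()` was
  rejected because it cannot fit noiseless (zero-residual) series, which the
  closed-loop tests require to be exact.
* **$F_{\min}$, $F_{\max}$ are fitted**, not pinned at 0/1 — incomplete
  saturation or a dark fraction shifts them in real data; pinning is
  available via `fix_extremes = TRUE`.
* **Confidence intervals** come from the Jacobian-based covariance with
  t quantiles, exponentiated for the log-scale parameters. The method for
  the published intervals is not stated; this is the standard NLS choice.
* **Unweighted residuals in fraction space** — no replicate weighting is
  described for the original fit.
* **Endpoints** are explicit: in-vitro (mean phasors of the extreme buffers,
  `endpoints_from_series()`) or in-situ
  (`estimate_extremes_from_timelapse()`, percentile bands of the phase
  lifetime in baseline vs post-saturation frames). Both modes exist because
  in-cell experiments re-estimate extremes from a terminal saturation step
  (e.g. digitonin), and it is not fully specified which mode any given
  published conversion used.

The measurable range derives from replicate scatter at the extreme buffers:
lowest measurable fraction = mean $F$ at zero calcium plus the 95 % CI
half-width of that mean, and symmetrically at saturation; both are pushed
through the Hill inverse. Zero scatter is reported as a degenerate full
range rather than an error. Note the published range (14 nM–16 µM at 37 °C)
depends on the original replicate variances; the package reproduces the
*procedure*, and its numbers depend on the data fed in.

Concentration maps (`phasor_image_to_ca_map()`) apply
projection → ratio correction → Hill inversion pixelwise. Out-of-range
pixels are clamped and flagged (0 ok, 1 below range, 2 saturated, 3 masked);
saturation is encoded as `Inf` in the numeric map with the flag channel
authoritative, because TIFF has no flag semantics (maps are written scaled
into [0, 1] with a sidecar scale factor, since 32-bit float TIFF writing in
this toolchain clamps to that range).

## TCSPC decay model and empirical lifetime

Photon arrival times are modeled as

$$p(t) = \frac{\epsilon}{t_{\max}}
  + f_1 F(t;\tau_1,\sigma,\mu) + f_2 F(t;\tau_2,\sigma,\mu),
  \qquad \epsilon + f_1 + f_2 = 1,$$

where $F$ is an exponential decay convolved with a Gaussian instrument
response $N(\mu, \sigma)$ and $\epsilon$ is uniform background. Each
component is used in its unit-normalised (exponentially-modified-Gaussian
density) form, so $p$ integrates to 1 over the window up to edge leakage —
negligible whenever $\mu - 5\sigma > 0$ and $t_{\max} \gg \tau_2$. The
density is evaluated in log space using the normal log-CDF for the erfc
factor; this stays finite and accurate for $\sigma/\tau$ ratios where a
direct erfc–exponential product over/underflows.

Fitting minimises the Pearson chi-squared statistic between observed counts
and expected per-bin counts (bin masses from the closed-form component CDF,
renormalised to the window). Numerical choices:

* **Tail pooling to expected counts ≥ 10.** Pearson's statistic is biased
  as an *estimator* when expected counts are near 1: its minimiser trades
  background fraction against the decay tail, and the resulting
  $\hat\epsilon$ error propagates directly into the empirical lifetime
  (each unit of $\epsilon$ error shifts $L$ by about $t_{\max}/2$). Pooling
  tail bins into groups of expected ≥ 10 removes the bias at no practical
  cost in resolution; pooling only to ≥ 1 was measurably insufficient.
* **Simplex and log parameterisation.** $(\epsilon, f_1, f_2)$ through a
  softmax so the sum-to-one constraint holds by construction; $\tau_1,
  \tau_2, \sigma$ on the log scale.
* **Multi-start Nelder–Mead.** Eight starts spread over decades of the
  data's mean arrival time, followed by simplex restarts from the two best
  candidates (restarting resets the simplex scale, which escapes premature
  shrinkage in six dimensions). Ties break by lowest chi-squared, then
  lowest $\tau_1$.

The empirical lifetime removes the IRF offset and the background's mean
arrival time ($t_{\max}/2$) from the histogram's mean arrival:

$$L = \langle p \rangle - \left(\mu + \epsilon\,\frac{t_{\max}}{2}\right).$$

Note what this estimator *is*: for a mono-exponential model its population
value is $(1-\epsilon)(\mu + \tilde\tau) - \mu \approx \tilde\tau -
\epsilon(\mu + \tilde\tau)$, with $\tilde\tau$ the window-truncated mean —
close to, but not identical to, $\tau$. Differences of empirical lifetimes
between conditions, which is how responses are reported, cancel most of this
offset. Frame series are summarised by the intensity-weighted mean
$\langle L \rangle = \sum_k I_k L_k / (n \langle I \rangle)$.

`phasor_from_histogram()` provides the cosine/sine transform bridge from
TCSPC histograms into the same phasor calibration used for frequency-domain
data, and `foreground_mask()` (Otsu by default, quantile as the rank-based
alternative) selects signal pixels before mapping.

## Photophysics utilities

Quantum yield is computed from origin-forced regressions of integrated
emission on absorbance, sample slope over reference slope times the
reference's QY (0.85). The source protocol defines the slope in the
inverted direction ($A_{450} = s \times I_{em}$) while using $s_s/s_r$
directly, which is dimensionally inconsistent; the package uses the
physically meaningful emission-per-absorbance slope. The reported standard
deviation propagates both slopes' standard errors in quadrature (the
original propagated only the sample slope).

The extinction coefficient uses the denatured-chromophore Beer–Lambert
method (known ε = 46,000 M⁻¹cm⁻¹ at 462 nm for the free cyan chromophore);
the two-state intensity ratio models detected brightness per state as
$\varepsilon_{max} \cdot QY \cdot \int \hat{x}X \cdot \int \hat{m}D$ with
peak-normalised state spectra and instrument excitation/detection profiles
(ideal top-hat filters when only band edges are given). This is a stated
approximation of the original spectral-weighting computation, whose exact
formula is not public; its output is validated against quadrature oracles,
and the published $R = 0.836$ is used as a constant elsewhere. Spectral
integrals use the trapezoid rule on a linearly interpolated union grid
(1 nm default resampling), so agreement with smooth oracles is limited by
the native sampling of the input spectra, not by the integrator.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, deterministically
per seed and without touching the session RNG stream:

* `gen_calibration_series()`: Hill-true fractions on the mixing line, with
  isotropic Gaussian phasor noise (sd 0.003 by default — the scatter scale
  of well-averaged calibration measurements). Shot-noise phasor scatter is
  approximately isotropic Gaussian; a measured noise model is not available.
* `gen_tcspc_histogram()`: per-photon sampling of the decay model
  (background uniform; components Gaussian-plus-exponential), with
  out-of-window photons redrawn, i.e. the window is a hard gate. A
  wrap-around mode exists for short windows. Defaults: 12.5 ns window
  (80 MHz pulse spacing), 10 ps bins.
* `gen_ca_timelapse()`: elliptical mitochondria-like regions with per-region
  calcium programs (baseline, optional oscillation, terminal saturation
  step), phasor noise scaled $0.3/\sqrt{\text{photons}}$, and intensity
  dimming $(1-F) + F R$ with state.
* The default calibration ladder is 0 plus 10 log-spaced concentrations
  from 10 nM to 39 µM — "log-spaced including zero" is impossible
  literally, and 10 nM is the bottom of the commercial buffer ladder's
  useful range.

They do **not** emulate realistic organelle morphology, optical blur,
detector afterpulsing or dead time, photobleaching, or pH sensitivity of
the sensor. Passing closed-loop tests therefore demonstrates correctness of
the *computational* pipeline under its stated noise model, not robustness
to those instrument effects.

## Problem sizes and reproducibility

The test suite and the acceptance script use desk-scale sizes chosen to
exercise the estimators at realistic signal levels: calibration simulations
with 11 concentrations × 3 replicates; TCSPC fits on 5×10⁵-photon
histograms over a 25 ns window with 10 ps bins (the published guidance is
≥10⁵ photons per decay for stable fits); recovery properties over up to 100
seeded calibration fits and small batches of decay fits. Every stochastic
step takes an explicit integer seed, and the command-line layer writes a
JSON run log (config echo, package version, seed, input hashes) next to its
outputs.

## Known limitations

* The Hill fit's covariance-based CIs are unreliable when an estimate sits
  on a box bound (they are reported as `NA` there).
* `fit_decay` assumes a single Gaussian IRF; measured, asymmetric IRFs are
  out of scope, as are vendor raw formats — the package consumes decoded
  histograms and images.
* Two decay components with nearly equal time constants are not separately
  identifiable; the fit is still well-behaved (the components collapse), and
  the empirical lifetime is insensitive to how the fraction splits.
* Concentrations outside the calibrated measurable range are flags, not
  numbers: the Hill inverse diverges at the asymptotes and no amount of
  averaging recovers information beyond them.
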