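---
title: "A generator-function model of tactile encoding in Merkel cell-neurite complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generator-function model of tactile encoding in Merkel cell-neurite complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(merkelsim)
```

## The model

Slowly adapting type I (SAI) afferents innervate Merkel cells in touch domes
and fire throughout a sustained skin indentation with a gradually declining
rate. `merkelsim` implements a forward model of this response chain with
three stages:

1. **Skin mechanics.** A displacement-clamped ramp-and-hold stimulus is
   converted to compressive stress interior to the skin by a one-dimensional
   quasi-linear viscoelastic (QLV) surrogate: a one-term Ogden hyperelastic
   law in uniaxial compression, filtered through a two-term Prony-series
   reduced relaxation function
   $G(t) = G_\infty + G_1 e^{-t/\tau_1} + G_2 e^{-t/\tau_2}$
   with $\mu = 1.3$ kPa, $\alpha = 7.9$, $\tau_1 = 0.08$ s, $\tau_2 = 1.2$ s,
   $G_1 = 0.59$, $G_2 = 0.10$, $G_\infty = 0.31$ for a 380 µm skin specimen.

2. **Generator function.** The per-complex receptor current is the
   convolution of the stress derivative with the sum of three kernels:
   a rapidly inactivating (RI) component $a\,e^{-t/\tau_{RI}}$ attributed to
   neurite Piezo2 ($\tau_{RI} = 8$ ms), a slowly inactivating (SI) component
   $b\,(K_{peak} e^{-t/\tau_{SI}} + K_{steady})$ attributed to Merkel-cell
   signalling ($\tau_{SI} = 200$ ms, $K_{peak} + K_{steady} = 1$), and an
   ultra-slowly inactivating (USI) component $c\,e^{-t/\tau_{USI}}$ placed in
   the sensory neuron ($\tau_{USI} = 1744.6$ ms). The summed current is
   clamped at a zero baseline. The wildtype coefficients are
   $(a, b, c) = (0.74, 0.24, 0.07)$ pA/Pa; the Atoh1-knockout preset removes
   the SI component entirely (no Merkel cells, $b = 0$).

3. **End organ.** The per-complex current is multiplied by the cluster size
   at each of four heminodes ({8, 5, 3, 1}; 17 complexes in total), and each
   heminode is a leaky integrate-and-fire unit ($R = 5$ GΩ, $C = 30$ pF,
   threshold 30 mV) with cross-heminode reset and a 1 ms refractory period.
   Noise is deliberately absent, so spike trains are deterministic.

Analysis follows the conventions of the electrophysiology it emulates:
instantaneous firing frequency (IFF) as reciprocal inter-spike intervals,
5-sample moving-average smoothing, logarithmic resampling to 50 points for
fitting, and phase-resolved rates over the ramp, early hold (0.5 s after the
ramp), and late hold (2–5 s).

```{r}
run <- run_simulation(sim_config())
run$phase_rates
```

## What replaces the finite-element model, and what that implies

The original response chain drives the generator function with the maximum
compressive stress field of an axisymmetric finite-element model. Because the
generator function consumes only a scalar stress-versus-time trace, the
package replaces the mesh with the 1D QLV surrogate above; users with a real
finite-element stress trace can inject it through `read_stress_csv()` and
`run_simulation(stress = ...)`. The surrogate reproduces the qualitative
stress shape — a ramp to peak followed by viscoelastic relaxation toward
$G_\infty$ times the elastic stress — but not spatial stress concentration.
Absolute stress therefore carries a free calibration factor, `stress_scale`,
because the pA/Pa coefficients presuppose the finite-element stress scale.

### Calibration of the operating regime

Four configuration values are not dictated by the model equations and were
fixed once, before any comparison, to place the surrogate in the operating
regime of the recordings the model emulates:

* **Reference indentation 60 µm** (high magnitude), with the low magnitude at
  50%. Tens of micrometres is a gentle-touch indentation for a ~400 µm skin
  specimen and keeps both magnitudes in the quasi-linear part of the Ogden
  law, so the low stimulus produces roughly half the stress of the high one.
* **Ramp duration 0.3 s.** With the 8 ms RI time constant, the dynamic RI
  peak scales inversely with ramp duration. A 0.3 s ramp (a typical
  displacement-controlled indentation speed) keeps the RI peak below the SI
  and USI peaks, the component ordering reported for this end organ; a much
  faster ramp would let the RI transient dominate.
* **`stress_scale` = 0.22**, giving a wildtype high-magnitude peak
  per-complex current of 17.0 pA — inside the 10–20 pA range expected when a
  ~250 pA whole-afferent current is divided over 17 complexes — and keeping
  late-hold cluster currents above the 6 pA rheobase so that the
  slowly adapting (rather than transient) firing phenotype is expressed,
  even under the strongest skin-relaxation variant ($G_\infty = 0.10$).

These are defaults, not constants; every one is a `sim_config()` /
`skin_params()` argument.

## Numerical scheme

All traces live on a uniform grid (default $\Delta t = 0.1$ ms).

* **QLV filter.** Each Prony branch is integrated by a recursive exponential
  update that is exact for piecewise-linear elastic stress. The tests verify
  agreement with midpoint-rule quadrature of the hereditary integral to a
  relative error below $10^{-6}$ on a 1 s trace.
* **Generator convolution.** Each kernel term keeps an exponentially
  decaying memory of the stress increments,
  $y_k = y_{k-1} e^{-\Delta t/\tau} + \Delta\sigma_k$, which is exact for the
  discretised step-increment construction of the stress trace; the
  non-decaying SI floor integrates exactly to $b\,K_{steady}\,\sigma(t)$
  because the stimulus starts from rest. The implementation matches a direct
  double-loop convolution to floating-point precision. Clamping at zero is
  applied to the summed current only, never per component.
* **LIF integration.** Forward Euler at the trace step with the threshold
  checked after each step; on a spike, all heminode potentials reset to
  baseline (0 mV) and are held there for the refractory period. The
  refractory is applied globally — all heminodes feed one axon, so no
  compound inter-spike interval may undercut it; `end_organ_config()` offers
  a per-heminode variant. Simultaneous crossings resolve deterministically
  to the heminode with the larger instantaneous current, then the lower
  index. Spike count, first-spike time, and every inter-spike interval
  converge to within one grid step when the grid is halved; absolute spike
  phase late in a long regular train accumulates the per-interval $O(\Delta
  t)$ error linearly, which is why convergence is stated per interval.

## Fitting layers

`fit_exponential()` fits the decaying segment of a trace (from its maximum)
with $y = A e^{-x/\tau}$ (voltage-clamp current decays) or
$y = A e^{-x/\tau} + b$ (current-clamp potential decays that settle on a
plateau), by Levenberg–Marquardt least squares. `peak_steady_ratio()` uses
the mean of the final 10% of the trace as the steady state — the window
length is a package choice. `summarize_table_fits()` reduces a table of
fitted constants to mean and sample standard deviation; on the packaged
44-entry RI reference table the mean rounds to 8 ms. (The 12-entry SI table
has an arithmetic mean near 160 ms although its published summary value is
200 ms; the package reports the arithmetic mean and places no target on it.)

`fit_free_parameters()` estimates $(a, b, c)$ in the whole-end-organ
context: reference spike trains at two magnitudes are reduced to smoothed,
log-sampled IFF (50 points, weighting the early hold); the model IFF is
interpolated at those points; Levenberg–Marquardt minimises the residuals
(equivalently maximises $R^2$); and the two per-magnitude estimates are
averaged. Because spike times are grid-quantised, the objective has a small
step-like texture; finite-difference steps of about 1% of each parameter
(`epsfcn = 1e-4`) keep the Jacobian informative. A candidate producing
fewer than three spikes receives a large constant penalty residual. Since
the generator current is linear in $(a, b, c)$ before clamping, the fitter
precomputes three unit-coefficient basis currents per magnitude and only
reruns the spike generator inside the loop.

Real recordings are not distributed with the package, so the fitting layer
is validated by parameter recovery on synthetic references generated by the
forward model itself (`make_reference_spikes()`): initialised at 1.5 times
the generating values, the fit returns within 15% of them with $R^2 >
0.95$. Users can refit to their own data via spike-time CSVs.

## What the synthetic data do and do not show

Synthetic decay traces (`make_synthetic_decay_traces()`) are exact
exponentials plus Gaussian noise; they exercise estimator correctness
(exact recovery at zero noise, bias under noise), not the drift, access
resistance artefacts, or non-exponential tails of real patch-clamp data.
Likewise, the deterministic forward model omits the irregular inter-spike
intervals of real SAI afferents, so recovery results bound estimator
behaviour under ideal conditions only.

## Known limitations

* One shared per-complex current drives all clusters; chains, heterogeneous
  complexes, and architectural remodelling are out of scope.
* The 1D skin surrogate cannot reproduce spatial stress fields, tip-size
  effects, or touch-dome micromechanics; its fidelity claim is limited to
  the stress-versus-time shape.
* Near rheobase the firing rate is a steep function of current, so
  late-hold rates are sensitive to the calibration constants above.
* Problem sizes in the tests (1–5 s traces at 0.1–1 ms steps, 100-replicate
  recovery studies) were chosen to exercise every code path at full default
  resolution where it matters and reduced resolution elsewhere.
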