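---
title: "Finite-loading-rate analysis of stress relaxation and creep with the standard linear solid model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-loading-rate analysis of stress relaxation and creep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slsfit)
```

## The model

The standard linear solid (Zener) model is the simplest viscoelastic model
that exhibits both stress relaxation and creep with finite long-time
limits: a spring $E_1$ in parallel with a Maxwell arm (spring $E_2$ in
series with a dashpot $\eta$). Its governing relation under uniaxial
loading is

$$\sigma + \tau_R \dot\sigma = E_1\,(\varepsilon + \tau_C \dot\varepsilon),
\qquad \tau_R = \frac{\eta}{E_2}, \quad
\tau_C = \frac{\eta\,(E_1+E_2)}{E_1 E_2}.$$

$E_1$ is the equilibrium modulus, $E_1 + E_2$ the instantaneous modulus,
and $\tau_C > \tau_R$ strictly, because $(E_1+E_2)/E_1 > 1$. Finite-element
software usually parameterizes the same material as an elastic modulus $E$
plus a one-branch dimensionless Prony relaxation modulus
$g_R(t) = 1 - g\,(1 - e^{-t/\tau_R})$; the two triples are equivalent via
$E_1 = E$, $E_2 = E g/(1-g)$, $\eta = \tau_R E_2$
(`sls_to_prony()` / `prony_to_sls()` round-trip to machine precision).

## Why the loading rate matters

A ramp-hold test loads at a constant rate $r$ to a hold level and then
holds it. The textbook analysis assumes the loading is a step, i.e. the
rate is infinite. In reality the Maxwell arm relaxes *during* the ramp, so
the hold phase starts from a lower overshoot than the step solutions
assume. Solving the governing relation for a constant-rate ramp gives, for
the relaxation-test hold phase (time restarted at the hold start),

$$\sigma(t) = \underbrace{E_1 r (\tau_C-\tau_R)
\left(1 - e^{-\varepsilon_0/(\tau_R r)}\right)}_{\text{decay amplitude}}
\, e^{-(t/\tau_R)^k} + E_1 \varepsilon_0,$$

and for the creep-test hold phase

$$\varepsilon(t) = \frac{r}{E_1}(\tau_R-\tau_C)
\left(1 - e^{-\sigma_0/(\tau_C r)}\right) e^{-(t/\tau_C)^k}
+ \frac{\sigma_0}{E_1}.$$

Both reduce to the step-loading solutions (with amplitude $E_2\varepsilon_0$
and $-\sigma_0 E_2/(E_1(E_1+E_2))$ respectively) as $r \to \infty$; the
package asserts this limit numerically at $r = 10^9$ to within $10^{-6}$
relative. The stretched-exponential (Kohlrausch) exponent $k \in (0,1]$
broadens the decay for real materials whose relaxation is not
single-exponential; it applies only to the hold-phase decay — the ramp
solutions keep the ordinary exponential, which is where the closed-form
derivation produces it.

## Estimation

`fit_relaxation()` and `fit_creep()` fit the *hold phase only* — the ramp
is characterized by its two known settings (rate and hold level), which
the tester chooses or `estimate_protocol()` reads off the data (ramp slope
by least squares, hold level by the hold mean). Free parameters of the
finite-rate form are $E_1$, $\tau_R$, $\tau_C$ and optionally $k$; $E_2$
and $\eta$ then follow from
$E_2 = E_1(\tau_C-\tau_R)/\tau_R$, $\eta = \tau_R E_2$
(`moduli_from_time_constants()`). The step-loading form frees $E_1$, $E_2$
and the decay time constant directly.

Numerical choices:

- **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  `ftol = ptol = 1e-12`). Moduli and time constants are fitted on the log
  scale, which enforces positivity without constraints; the ordering
  $\tau_C > \tau_R$ is built in by the parameterization
  $\tau_C = \tau_R(1+\delta)$ with $\delta = e^{\text{free}} > 0$; $k$ is
  box-bounded to $(0.001, 1]$.
- **Initialization**: equilibrium level from the last-decile hold mean
  (hence $E_1^0$), decay amplitude from the first hold sample minus the
  equilibrium, time constant from the $1/e$ crossing of the normalized
  decay (linear interpolation; a third of the hold span if the decay is
  degenerate), $k^0 = 1$; $\delta^0$ by inverting the amplitude expression.
- **Multi-start**: up to three deterministic perturbed restarts (time
  constants scaled by 2–5 either way) if the first run does not converge;
  a fit that still fails is returned flagged, and batch sweeps record it
  as a flagged row rather than aborting.
- **Identifiability guard**: when the fitted decay amplitude is below
  $10^{-3}$ of the equilibrium response, the transient carries essentially
  no information about the Maxwell arm and the result carries
  `condition_warning = TRUE`. This is exactly the slow-ramp creep regime:
  as $r \to 0$ the creep amplitude
  $(r/E_1)(\tau_R-\tau_C)(1-e^{-\sigma_0/(\tau_C r)}) \to 0$ and the
  specimen behaves like an elastic solid during the test, so $E_2$ cannot
  be recovered however good the fit.

## The synthetic benchmark

The validation study replaces a finite-element specimen with a
material-point simulation: for a linear, isotropic, homogeneous material
under uniform uniaxial ramp-hold loading every element follows the same
1-D constitutive relations, so the per-element response *is* the
material-point response. What the surrogate deliberately does not model:
near-incompressibility (FE Poisson ratio effects), boundary-condition
artifacts, and element averaging. Consequences worth keeping in mind when
reading the test results:

- Noiseless recovery by the generating form is near-exact at every rate,
  so the finite-form error levels here (~$10^{-13}$%) are far below what a
  discretized FE study reports; the *qualitative* conclusions (which form
  is accurate where, how thresholds move with $\tau_R$) are the
  transferable content.
- In an FE study the creep errors grow with the modulus of elasticity; a
  relative-error analysis of an exact linear material point cannot show
  that effect, so modulus independence is asserted for relaxation and the
  creep modulus effect is only probed under added noise.

`benchmark_materials()` fixes the nine hydrogel-like models
(E ∈ {5, 10, 30} kPa, τR ∈ {0.5, 2, 5} s, g = 0.8 — soft-tissue range);
`benchmark_grid()` crosses them with seven decade-spaced rates (strain
rates $10^{-4}$–$10^2$ 1/s, stress rates $1$–$10^6$ Pa/s, so the ramp
lasts 100 s down to 0.1 ms) at hold strain 0.01 (a 0.1 mm compression of
a 10 mm specimen) and hold stress 100 Pa — 63 trials per test kind.

Generator settings that the study leaves open, chosen once here:

- **Hold duration**: 8 time constants ($8\tau_R$ relaxation, $8\tau_C$
  creep), so the response is within $e^{-8} \approx 0.03\%$ of its
  plateau — comfortably past the 1% plateau criterion and cheap to sample.
- **Sampling**: 200 uniform points on the ramp, 1000 on the hold; a
  user-requested ramp plan below 10 points is raised to 50 so the ramp is
  never unresolved.
- **ODE oracle**: adaptive `lsoda` at relative tolerance $10^{-9}$,
  integrated in two legs so the rate discontinuity at the ramp end is not
  smoothed over; analytic and integrated curves agree within $10^{-6}$
  relative across the grid ($10^{-5}$ at the two fastest rates, where the
  ramp spans a tiny fraction of a time constant).
- **Noise**: multiplicative Gaussian on the measured channel only (stress
  in relaxation, strain in creep), seeded; real load-cell/extensometer
  noise is closer to multiplicative than additive over the decades of
  signal involved. Drift, temperature effects and quantization are not
  modeled.

## What the study shows

Running `run_sweep()` on both grids with both forms reproduces the
qualitative findings the tests assert:

- The finite-rate relaxation fit recovers $E_1$, $E_2$ and $\eta$ within
  the conventional 5% accuracy criterion at *every* strain rate tested.
- The finite-rate creep fit recovers $E_1$ and $\eta$ at every stress
  rate; $E_2$ requires the stress rate to exceed a material-dependent
  threshold (well below 100 Pa/s for these materials) before its transient
  is identifiable.
- The step-loading forms are accurate for $E_2$ and $\eta$ only above a
  rate threshold that *decreases* as $\tau_R$ grows — slower materials
  tolerate slower ramps — and their errors approach 100% at the slowest
  rates.
- $E_1$ is recovered within 5% by both forms at all rates: the equilibrium
  plateau does not depend on how the hold level was reached.
- Errors are relative and the material point is linear, so results are
  independent of the modulus of elasticity in the relaxation study.

`detect_threshold()` reports thresholds as the smallest tested rate with
sustained sub-criterion error, not an interpolated crossing: on a decade
grid an interpolation would suggest precision the study design cannot
support.

## Problem sizes

The packaged tests and the study script run the full 63-trial grids (both
kinds, both forms, ~250 fits), the 126-trial ODE-oracle comparison, and a
noise-robustness check of 20 seeds × 9 materials × 2 test kinds at
mid-grid rates (strain rate 0.01 1/s, stress rate 1000 Pa/s) with 1%
multiplicative noise, asserting the median error per parameter stays
within 5%.

## Limitations

- One Maxwell branch only: materials needing a relaxation spectrum
  (generalized Maxwell/Kelvin, fractional-order models) are out of scope;
  $k < 1$ absorbs mild spectrum broadening but is not a substitute.
- Small-strain linear viscoelasticity; no temperature dependence, no 3-D
  constitutive tensors.
- The fit uses the hold phase only. The ramp data inform the protocol
  estimate but are deliberately not fitted.
- Threshold values are grid-resolution-limited (decade steps) and, as the
  identifiability discussion above explains, depend on the unknown
  material — in practice, load as fast as the instrument allows and use
  the finite-rate forms.
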