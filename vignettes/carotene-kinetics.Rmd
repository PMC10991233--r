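---
title: "Kinetics of growth and beta-carotene accumulation in Dunaliella salina"
author: "carokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of growth and beta-carotene accumulation in Dunaliella salina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carokin)
```

## The model

`carokin` implements a dynamic kinetic model for batch photo-production of
beta-carotene by the halotolerant green microalga *Dunaliella salina*,
co-limited by temperature, average light intensity, nitrate and inorganic
carbon. Two state variables are integrated: biomass dry weight
$X$ (g L$^{-1}$) and intracellular beta-carotene content $W$ (mass fraction
of dry weight).

Biomass follows a growth–decay balance

$$\frac{dX}{dt} = \mu_0 X - \mu_d X^2,$$

where the quadratic term represents respiration and decay (so the culture
approaches the carrying capacity $X^\* = \mu_0/\mu_d$ under constant
conditions), and the specific growth rate is a product of independent
limitation factors:

$$\mu_0 = \mu_{max}\; f(T)\;
  \frac{I_{av}}{I_{av} + K_s + I_{av}^2/K_i}\;
  \frac{C}{K_C + C}\; \frac{N}{K_N + N}.$$

The light term is the Aiba form — saturating in $K_s$, photoinhibited
through $K_i$ — which is unimodal with its optimum at
$I^\* = \sqrt{K_s K_i}$ and peak value $1/(1 + 2\sqrt{K_s/K_i})$; the
nutrient terms are Monod factors; and the temperature response is a
double-Arrhenius difference

$$f(T) = A e^{-E_a/RT} - B e^{-E_b/RT},$$

activation minus thermal inactivation, with $T$ in Kelvin and
$R = 8.3145\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$ so that the tabulated
energies in kJ mol$^{-1}$ apply directly. $\mu_{max}$ is treated as a
constant scalar; the conditions enter only through the factors.

Carotene content follows a single-product rate law combining a nitrogen
prefactor $[b + (1 - K_{NW}/N)](K_{NW}/N)$, a carbon prefactor
$(1 - K_{CW}/C)(K_{CW}/C)$, a logistic ceiling $(1 - W/w_{max})$, an Aiba
light term with its own constants $(K_{sw}, K_{iw})$ and a second
double-Arrhenius temperature factor. The product is implemented exactly in
this printed form — no alternative synthesis/consumption split is offered —
and it is signed: at carbon below $K_{CW}$ or nitrate far above the
favorable window the rate turns negative, which the model reads as net
consumption of the pigment.

Two parameter presets are packaged: `table1_prior`, the constants obtained
from single-factor experiments, and `table2_optimized`, the jointly refined
values. Both reproduce their tabulated numbers bit-exactly and round-trip
through JSON without loss.

```{r}
p <- carokin_preset("table1_prior")
p
```

## Light environment

The kinetics consume an *average* light intensity. For a flat-plate reactor
the package uses the Beer–Lambert depth average

$$I_{av} = I_0 \frac{1 - e^{-k_a X L}}{k_a X L},$$

with light path $L$ (default 0.05 m) and biomass-specific attenuation
$k_a$ (default 0.2 per g L$^{-1}$ per m). The source experiments quote
$I_{av}$ directly and give no explicit averaging formula, so this is a
deliberate modeling choice: the default $k_a$ keeps $I_{av}$ close to the
quoted working intensities at the biomass levels of the validation batches,
and `reactor_config(mode = "incident")` bypasses attenuation entirely,
feeding the incident flux through unchanged — the representation used for
single-factor designs. `attenuation_from_transmission()` calibrates $k_a$
from logged incident/transmitted flux pairs.

Photoperiods are square waves with dawn at $t = 0$; a 14:10 cycle means 14
bright hours then 10 dark hours per day, and the integrator is restarted at
every transition rather than smoothing across the discontinuity.

## Simulation and numerical choices

`simulate_batch()` integrates the coupled system with `lsoda`
(default `rtol = 1e-8`, `atol = 1e-10`), holding nitrate and carbon constant
over the run: the model has no uptake ODEs — carbon is replenished by
pH-stat CO$_2$ dosing and nitrate remains in excess in the experiments the
model describes — so constant concentrations are the faithful reading.

The temperature and nitrogen prefactors can be negative, so the raw rate
laws can push $X$ below 0 or $W$ outside $[0, w_{max}]$. The solver clips:
a state at its bound with an outward rate gets a zero derivative, the event
is tallied, and a run in which more than 1 % of right-hand-side evaluations
were clipped raises a prominent warning. An error would be wrong here —
validation conditions with 5 mM carbon (below $K_{CW} = 10.38$ mM)
legitimately drain $W$ to zero, and that pinned trajectory is the model's
honest prediction. Halving the solver tolerances moves endpoints by less
than $10^{-5}$ relative, and the adaptive solution agrees with an
independent fixed-step RK4 integration at $dt = 0.01$ h to better than
$10^{-6}$ relative (both are exercised in the test suite).

```{r}
cond <- preset_conditions()$C     # 24:0, 20 C, 800 umol m-2 s-1, 200 mM, 50 mg/L
traj <- simulate_batch(cond, p)
tail(traj, 3)
```

## Assay formulas

The measurement layer mirrors the laboratory derivations: interval specific
growth rates as log-differences of dry weight (they telescope to
$\ln(DW_n/DW_0)$ and are invariant to rescaling), carotene concentration
from 453/665 nm absorbances with the chlorophyll correction $A_{665}/3.91$,
the HPLC calibration factor 3.657 and the 3 mL extraction volume frozen as
named constants, and content percent as $C \times 10 / DW$ with both in
mg L$^{-1}$. One bookkeeping quirk is kept deliberately: with the true
carotene mass concentration $C = W \cdot DW$, the printed $\times 10$
formula evaluates to $10\,W$ rather than the mass percentage $100\,W$; the
formula is preserved bit-exactly as the assay defines it, and the unit test
pins this identity so the factor of ten cannot silently drift.

## Parameter estimation

The estimation layer follows a staged design. Single-factor rate curves are
fitted by bounded Levenberg–Marquardt with seeded multi-start (default 10
starts, log-uniform over the parameter box, since half-velocity constants
span orders of magnitude): Monod, Aiba, the double-Arrhenius difference,
and the nitrogen prefactor of the carotene rate law. For the latter the
rate scale is *not* jointly identifiable with $(K_{NW}, b)$ — the response
$a[b + 1 - K/N](K/N)$ has only two independent coefficient combinations —
so the fit fixes the scale at the value the designed experiment implies for
its held factors and estimates $(K_{NW}, b)$. A correlation diagnostic from
the Jacobian warns when parameters are numerically collinear at the
optimum, naming the widest-confidence one.

Joint refinement minimizes the average relative error between simulated and
observed trajectories, pooled over time points and both channels with
configurable per-channel weights, plus a penalty $\Lambda$ (default $10^3$)
times any state-constraint excess; failed simulations return an `Inf`
sentinel. The optimizer is a global-best particle swarm (default 50
particles, 500 iterations, inertia decaying 0.9 to 0.4, accelerations
1.5/1.5, bounds $[0.5\times, 2\times]$ the starting value) with one
particle seeded at the starting point, so the final objective can never
exceed the initial one. The "adaptive" element is a documented heuristic:
a pre-run $\pm5\%$ sensitivity probe assigns each free parameter a velocity
clamp inversely related to its objective sensitivity, so fragile directions
are explored in smaller steps. A derivative-free Nelder–Mead polish of the
swarm optimum is on by default. Everything stochastic flows from one
integer seed, and two runs with the same seed are bit-identical.

Robustness of an optimum is probed the same way it was originally assessed:
`sensitivity_scan()` perturbs each parameter independently $Q$ times
(default 100) by uniform fractions in $\pm\zeta$ (default 5 %),
re-evaluates — never re-optimizes — the objective, and summarizes each
perturbation bin by quartiles for box plots. A parameter whose unperturbed
objective is not beaten by any draw (up to a $10^{-8}$ numerical floor that
absorbs solver noise) is flagged as minimal at zero perturbation; at the
generating parameters on noise-free data this holds for all twenty
constants.

## Synthetic data: what it does and does not show

The study's raw measurements are not deposited, so the package carries a
generator that emulates the two experimental designs: single-factor rate
tables (one factor varied over its experimental range — 10–40 °C light
0–2000 µmol photons m$^{-2}$ s$^{-1}$, nitrate 0–500 mg L$^{-1}$, carbon
0–500 mM, 24 points by default — with the others held at near-optimal
levels, or replaced by exactly 1 in the idealized design where the rate
scale itself is recoverable), and 6-day validation batches under the four
preset conditions A–D, sampled daily or hourly. Noise is multiplicative
lognormal with a 5 % coefficient of variation by default, chosen because
gravimetric and photometric assays have scale-proportional error of about
that size; it is median-preserving in log space and sign-preserving, and a
detection-limit floor applies to measured dry weight and content but never
to derived specific rates, which are legitimately negative in parts of the
carotene response. Every generated file carries a truth-parameter JSON
sidecar.

What passing round-trip tests show is that the estimation machinery inverts
the model: data generated by the rate laws refit to the generating
constants within 2 % noise-free and within 10 % median error at 5 % CV.
What they cannot show is fidelity to real *D. salina* cultures — the
generator has no instrument drift, outliers, missing samples, strain
variation or model error, so recovery here is a necessary, not sufficient,
condition for the pipeline's usefulness on laboratory data.

## Known limitations and open readings

* With the prior preset the growth temperature factor evaluates to
  $f(28\,°C) \approx 0.037$, so $\mu_{max} f(T) \approx 0.006$ h$^{-1}$ —
  far below the reported 0.164 h$^{-1}$ peak interval rate. No
  normalization for $f(T)$ is stated in the source tables; both presets are
  exposed exactly as printed, and simulated validation-condition biomass
  consequently grows slowly. Any rescaling would be invention.
* The carotene temperature block $(A_w, B_w, E_{aw}, E_{bw})$ yields a
  factor that increases over 10–35 °C, at odds with the reported negative
  temperature correlation of accumulation; also kept as printed.
* $w_{max}$ is tabulated with unit h$^{-1}$ but is dimensionally a mass
  fraction (its role is the logistic ceiling on $W$); it is stored as the
  fraction 0.039.
* $\mu_d$ multiplies $X^2$, so its working unit is L g$^{-1}$ h$^{-1}$
  despite the printed h$^{-1}$; the printed value is stored unchanged.
* No Droop quota model, no pH or salinity effects, no two-phase
  green-stage/induction staging, no CO$_2$ mass transfer, no chemostat
  operation.

## Problem sizes used by the checks

The packaged checks run 24-point single-factor grids, 6-day daily-sampled
batches for objective and sensitivity work (conditions C and D), a 400 h
hourly content trajectory for the ceiling fit and a 300 h hourly biomass
trajectory for the decay fit — sizes matching the experimental designs
while keeping every check comfortably fast on a single core.
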