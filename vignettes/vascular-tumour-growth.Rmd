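---
title: "Vascular tumour growth under anti-VEGF therapy: model, numerics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular tumour growth under anti-VEGF therapy: model, numerics and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascgro)
```

## The model

`vascgro` simulates a solid tumour in its vascular phase as two coupled
state variables: the tumour volume $V$ (mm^3^) and the carrying capacity
$K$ (mm^3^), the maximal volume the current vasculature can sustain.  The
tumour grows Gompertz-fashion towards $K$, while $K$ itself is dynamic,
driven by the balance of endogenous pro-angiogenic stimulation and
anti-angiogenic inhibition.  Both variables are floored at the avascular
switch volume $V^*$: a tumour below roughly 1 mm diameter survives on
diffusion alone, and only the volume grown *after* the angiogenic switch
secretes angiogenic factors.  With $I(t)$ the plasma concentration of an
anti-VEGF antibody (mg/kg),

$$\frac{dV}{dt} = -\lambda_1 (V - V^*) \ln\frac{V - V^*}{K - V^*},$$

$$\frac{dK}{dt} = -\lambda_2 (K - V^*)
  + c\,\frac{\bigl(\beta + (V-V^*)^p\bigr)(V-V^*)}
            {\alpha\bigl(\beta + (V-V^*)^p\bigr) + I(t)}
  - d\,(K - V^*)(V - V^*)^{2/3}.$$

The drug acts at the signalling level: it inflates the effective clearance
of angiogenic stimulators (the denominator of the stimulation term) rather
than killing endothelial cells directly.  As $I \to \infty$ the stimulation
term vanishes and the system relaxes to $(V^*, V^*)$ — the tumour retreats
to its avascular size, not to zero.  With $I \equiv 0$ the stimulation term
reduces to $(c/\alpha)(V - V^*)$ and the system has the stable equilibrium

$$V_{SS} = V^* + \left(\frac{c}{\alpha d}\right)^{3/2},$$

the post-vascular dormancy plateau.  Only $c$, $d$ and $\alpha$ move the
plateau; $\lambda_1$ sets how fast it is approached.

### Parameters

| symbol | meaning | units | default |
|---|---|---|---|
| `lambda1` | Gompertzian growth rate | day^-1^ | 0.192 |
| `lambda2` | natural endothelial loss | day^-1^ | 0 |
| `c` | angiogenic stimulation coefficient | mg/(day mm^3p^ kg) | 5.85 |
| `d` | angiogenic inhibition coefficient | day^-1^ mm^-2^ | 0.00873 |
| `alpha` | stimulator clearance parameter | mg/(mm^3p^ kg) | 1 |
| `beta` | vasculature-abnormality parameter | mm^3p^ | 1 |
| `p` | vasculature-abnormality exponent | – | 0 |
| `v_star` | avascular floor volume | mm^3^ | $\pi/6$ |

The defaults are the classical mouse parameterization of this model
family.  `lambda2` is retained for completeness but defaults to zero, the
convention under which all reference numerics here are derived.  Two
conventions deserve a note:

* **`v_star`.** A 1 mm diameter sphere has volume $\pi/6 = 0.5235988$
  mm^3^, usually printed as 0.52.  The package uses the exact value
  internally; every reproduced quantity is insensitive to the difference,
  and exactness simplifies testing.  Setting `v_star = 0` recovers the
  unshifted ancestor model exactly.
* **$x^0 = 1$.** With `p = 0` the abnormality factor is $\beta + 1$
  everywhere, including at $V = V^*$; R's `^` operator implements this
  convention natively.
* **Units of `c`.** The historical literature prints the units of `c`
  inconsistently (a rate in some tables, a stimulator-mass coefficient in
  others).  The numeric value is what matters for the dynamics; the
  package treats it as given and documents the mg/(day mm^3p^ kg) reading.

## The pharmacokinetic module

Bevacizumab disposition is described by a two-compartment model with
first-order elimination from the central compartment and zero-order
absorption during an intravenous infusion: a dose $D$ (mg) is delivered at
constant rate $D/T$ over $[t_D, t_D + T]$.  The central-compartment
concentration is bi-exponential in the hybrid rates $a$ (fast) and $b$
(slow), the roots of $x^2 - (k_{12}+k_{21}+k_e)x + k_{21}k_e = 0$:

$$b = \tfrac12\Bigl(S - \sqrt{S^2 - 4k_{21}k_e}\Bigr),\qquad
  a = \frac{k_{21}k_e}{b},\qquad S = k_{12}+k_{21}+k_e,$$

with coefficients $A = \frac{1}{V_c}\frac{a-k_{21}}{a-b}$ and
$B = \frac{1}{V_c}\frac{b-k_{21}}{b-a}$ satisfying $A + B = 1/V_c$.  The
slow root must be taken with the radical closing over the full
discriminant; any other reading yields a negative rate and violates the
defining identities $ab = k_{21}k_e$, $a + b = S$, which the test suite
asserts against an independent quadratic-root oracle.  During an infusion

$$I(t) = \frac{D}{T}\left[\frac{A}{a}\bigl(1-e^{-a e}\bigr)
       + \frac{B}{b}\bigl(1-e^{-b e}\bigr)\right],\qquad e = t - t_D \le T,$$

and afterwards each exponential decays from its end-of-infusion value.
Multiple doses superpose linearly; overlapping infusion windows are allowed
(the schedule of record never overlaps, but linearity imposes no
restriction).  The closed form is verified against numerical integration of
the compartment mass balances to 10^-6^ relative.

**Units.** The compartment model yields mg/ml; the growth model consumes
mg/kg of plasma.  The conversion divides by the plasma mass density,
default 1.025 g/ml (the standard figure; configurable via
`plasma_density`).  A caution that the package's own numbers make vivid:
with the default mouse PK set ($V_c = 7.975$ ml) a 0.125 mg dose produces
peak plasma concentrations near 15 mg/kg, an order of magnitude above the
stimulation-term scale $\alpha(\beta + 1) = 2$ mg/kg, so the simulated
nine-dose regimen suppresses stimulation strongly (day-32 growth
inhibition ≈ 92 %, growth delay of order 60 days at 95 % of plateau).
Published inhibition figures for this scenario vary with the concentration
convention adopted; because the whole drug pipeline is linear in
$1/\rho_{plasma}$, any alternative convention can be explored through the
`plasma_density` argument without touching the model.

## Numerical solution

The state is propagated in the shifted coordinates $(u, k) = (V - V^*,
K - V^*)$, which is exact and avoids catastrophic cancellation when a
heavily treated tumour approaches the floor.  Integration uses `deSolve`'s
adaptive `lsoda` with relative tolerance 10^-8^ and absolute tolerance
10^-10^ mm^3^ (halving either changes trajectories by < 10^-4^ relative —
asserted in the suite).  The integrator is restarted at every infusion
start and end so the forcing kinks never straddle an internal step; between
breakpoints the solution is sampled onto a uniform 0.1-day output grid.
States at or below $V^*$ raise an error rather than being clamped: the
model is only valid in the vascular phase, and silent clamping would mask
solver excursions.

### Plateau detection

Dormancy is detected on the output grid by the integer-part criterion: the
tumour has plateaued when the whole-number parts of $V$ and $K$ coincide
for at least ten consecutive samples; the first such time is the plateau
time and the shared integer the plateau value.  On a fine fixed grid this
criterion admits two readings, both provided:

* `rule = "first"` (default) — the first qualifying run.  Because $K - V$
  shrinks below 1 mm^3^ while both variables still creep upward jointly,
  this can record the integer one below the converged level (e.g. 17346 at
  day 90 for the reference run, against a limit of 17347.05).
* `rule = "converged"` — the last qualifying run, i.e. the band in which
  both variables have settled; its shared integer is the converged plateau.

The two values never differ by more than the final creep (1 mm^3^ in all
studied cases).  Plateau *times* are inherently solver- and
grid-convention dependent and should only be compared loosely (the suite
allows ±15 % on the reference run); plateau *values* are robust.  For the
perturbation table ([`oat_table()`]) the percentage variation is computed
from the unrounded terminal levels rather than the integerized detection
values, so a 0.5 mm^3^ rounding accident cannot shift a reported variation
percentage.

## Parameter analysis

`one_at_a_time()` perturbs a single coefficient by a signed percentage,
re-simulates free growth from the anchor state $(V_0, K_0) = (200, 625)$
mm^3^, and reports the plateau and its variation against the unperturbed
run (the variation taken from the unrounded levels, as above);
`oat_table()` assembles the full table.  With the reference set, ±20 %
on `c` moves the plateau by +31.45 / −28.44 % and ±20 % on `d` by −23.93 /
+39.75 %, while `lambda1` changes only the attainment time — the dynamics
textbook picture of stimulation and inhibition as the sole plateau
modulators.

`valid_parameter_bounds()` inverts the steady state to bound the
coefficients by biological plausibility: requiring the plateau not to
exceed a cap of 10^6^ mm^3^ gives
$c_{max} = \alpha d\,(\text{cap} - V^*)^{2/3} = 87.3$ and
$d_{min} = c/(\alpha(\text{cap} - V^*)^{2/3}) = 5.85\times 10^{-4}$;
requiring the carrying capacity to be non-decreasing at the anchor (no
self-regressing vasculature without treatment) gives
$c_{min} = \alpha d (K_0-V^*)/(V_0-V^*)^{1/3} = 0.933$ and
$d_{max} = c (V_0-V^*)^{1/3}/(\alpha(K_0-V^*)) = 0.0547$.  The cap is
reduced by $V^*$ for exactness (the difference is far below printed
precision), and the anchor state is an explicit argument because the
monotonicity constraint has no canonical anchoring point; $(200, 625)$ is
the package default.  Bounds are reported at full precision; round to the
display convention of your choice.

## Two-stage calibration

Fitting mirrors the two-arm structure of xenograft experiments.

**Stage 1, control arm** (`fit_control()`): bounded Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`, termination tolerance 10^-6^ on the
sum of squares) over $(\lambda_1, c, d, K_0)$.  $V_0$ is pinned to the
first observed volume; the initial point is the reference coefficient set
with $K_0$ chosen to reproduce the canonical ratio $V_0/K_0 = 200/625$;
lower bounds impose non-negativity and $K_0 \ge V_0$, which excludes
untreated trajectories with an initial decreasing section.

**Stage 2, treated arm** (`fit_treatment()`): free parameters
$(\lambda_1, c, \beta, p, K_0)$, with the inhibition coefficient $d$
*fixed* at the control estimate — endogenous inhibition is taken to be
unaffected by anti-VEGF treatment.  $\lambda_1$ and $c$ start from the
control estimates; $\beta, p$ start from the reference values $(1, 0)$;
the upper bound of $\lambda_1$ is the control estimate, admitting a direct
antitumour effect but never a treatment-accelerated tumour.  $K_0$ is free
only when the first observation coincides with the first dose (the
instantaneous-effect convention); otherwise it is pinned through the
control-arm $V_0/K_0$ ratio.  For dose-escalation experiments the fit of
each arm can be warm-started from the nearest lower dose level
(`warm_start`).

Reported diagnostics: RMSE $=\sqrt{\sum r_i^2/n}$ (the divisor is $n$, not
$n - k$), NRMSE $= 100\,\mathrm{RMSE}/\mathrm{range}(V_{obs})$, and the
first-order optimality, defined here as the infinity norm of the projected
gradient of $\tfrac12\sum r_i^2$ at the solution (components pushing
against an active box bound are zeroed; the gradient is formed as
$J^\top r$ with a finite-difference Jacobian, so a near-perfect fit
reports a near-zero optimality measure regardless of curvature).

### Residual weighting and identifiability

The cost of record is the unweighted difference between predicted and
observed volumes.  Two optional weightings address the strong
heteroscedasticity of tumour-volume series, whose measurement error scales
with size while the volumes span two orders of magnitude:

* `weighting = "sd"` divides by the reported per-time SDs;
* `weighting = "relative"` divides by the observed volumes — a constant-CV
  error model that needs no SD column and avoids amplifying the noise of
  small-cohort SD estimates.

Identifiability is the limiting factor, not optimization.  Three effects
are documented because they shape what any fit of this model can deliver:

1. **The $c$–$d$ ridge.**  The plateau pins only the ratio $c/d$; the two
   coefficients individually are resolved by the curvature of the approach
   to dormancy, a much weaker signal.  Their fitted errors are strongly
   correlated.
2. **$K_0$ forgetting.**  The carrying capacity relaxes towards its
   quasi-equilibrium within a few days, so $K_0$ is informed almost solely
   by the first measurement interval and is the least identifiable
   parameter under sparse sampling.  With the unweighted cost the effect
   is compounded: plateau-scale residuals (hundreds of mm^3^) dominate the
   small early volumes that carry the $K_0$ signal.  A 100-seed synthetic
   power analysis (cohorts of 10, measurement CV 5 %, twice-weekly
   sampling over 0–105 days) gave median relative errors of roughly
   1 % ($\lambda_1$), 7 % ($c$, $d$) and 13 % ($K_0$) under the
   constant-CV weighting, against ~25 % for $K_0$ unweighted — which is
   why the package's recovery regression exercises the `"relative"`
   weighting over a window that covers growth *and* dormancy.
3. **$(\beta, p)$ degeneracy.**  With $p = 0$ the abnormality factor is a
   constant that merges with $\alpha$ and the drug scale, so $(c, \alpha,
   \beta)$ are not jointly identifiable; treated-arm recovery tests assert
   fit quality and the constrained parameters, not uniqueness of
   $(\beta, p)$.

## The synthetic-data generator

`generate_series()` emulates the statistical structure of small-cohort
mouse xenograft experiments: a single truth trajectory per arm, observed
twice weekly by `n_animals` virtual animals under multiplicative lognormal
noise with coefficient of variation `noise_cv`, reported as per-time
cohort mean ± SD.  The lognormal is mean-preserving
($\mu_{log} = \log V - \sigma^2/2$, $\sigma^2 = \log(1 + CV^2)$);
multiplicative noise keeps volumes positive and scales the error with
size, as caliper measurements do.  Defaults (10 animals, CV 5 %,
twice-weekly) mirror the monotherapy efficacy studies this model family
is calibrated against, including a 9 × 5 mg/kg twice-weekly infusion
regimen for treated arms and dose-level chains (e.g. 1/5/25 mg/kg) to
exercise warm-started fitting.

What the generator deliberately does **not** model: inter-animal parameter
heterogeneity (the ODE assumes a homogeneous tumour; one truth per arm),
animal dropout, caliper bias, or digitization error.  Passing recovery
tests therefore demonstrate that the estimation machinery is correct and
well-conditioned under the stated noise model — not that real xenograft
series, with their correlated errors and cohort attrition, would yield
equally tight estimates.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run free-growth simulations of
300–600 days on the 0.1–1 day grids, treated simulations of 35–400 days,
and 20-dataset recovery studies; these sizes were chosen so the full suite
exercises every claim in minutes on one core while leaving all detection
and tolerance conventions at their defaults.

## Known limitations

* The model is a homogeneous two-compartment caricature: no spatial
  structure, no endothelial subpopulations, no time delays, no
  vascular-normalization mechanism.
* Calibration is local (a single bounded LM run, optionally warm-started);
  multistart or global search and profile-likelihood identifiability
  analysis are out of scope.
* Combination therapy (chemotherapy plus anti-VEGF) is not modelled; the
  drug enters only through the stimulation denominator.
* The day-32 inhibition endpoint is sensitive to the plasma-concentration
  convention (see the units note above); comparisons across
  implementations must fix that convention first.
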