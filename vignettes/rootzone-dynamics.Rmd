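---
title: "Root-zone nutrient dynamics, dosing control and composition optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root-zone nutrient dynamics, dosing control and composition optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrodose)
```

## The system and the model

`hydrodose` models the nutrient tank of a closed, water-culture hydroponic
system: one well-mixed reservoir (default 0.3 m^3^) shared by a population of
plants (default 84), tracked over a cultivation season (default 54 days =
1296 h, time zero at transplanting). The state is the water volume $V$ (m^3^)
and the per-ion nutrient masses $M^I$ (mol) over the six macronutrient ions
NO~3~^-^, H~2~PO~4~^-^, SO~4~^2-^, K^+^, Ca^2+^, Mg^2+^ with absolute
valences $(1, 1, 2, 1, 2, 2)$. Concentrations are the derived view
$C^I = M^I / V$ (mol m^-3^, numerically mM).

The continuous dynamics couple four sub-models:

* **Tank balance.** $dV/dt = Q_{in} - n\,Q_{trs}$ and
  $dM^I/dt = F_{in}^I - n\,J^I$, where $n$ is the plant count, $Q_{in}$ and
  $F_{in}$ are water and nutrient inflows, and transpired water carries no
  nutrients. We integrate nutrient *mass*, not concentration: the
  single-equation form $V\,dC/dt = Q_{in}C_{in} - J$ drops the
  $C\,dV/dt$ dilution/concentration term and does not conserve mass. The
  literal form is retained behind `ode_form = "concentration"` for
  comparison; the mass form is the default because conservation is
  physically required and directly testable (the suite closes the per-ion
  balance to better than 10^-6^ relative on every run).
* **Uptake kinetics.** Transporter-limited Michaelis-Menten influx per
  plant, $J^I = P_{RSA}\, J_{max}^I\, C^I / (K_m^I + C^I)$, scaled by the
  absorbing root surface area $P_{RSA} = 2\pi r_0 P_{RL}$ of cylindrical
  roots whose length grows logistically,
  $P_{RL}(t) = R_{max}/(1 + K_1 e^{-k_1 t})$. $K_m$ is carried in
  mol m^-3^ so that the saturation function is dimensionless.
* **Transpiration.** A reduced (Baille-type) Penman-Monteith form,
  $Q_{trs} = a_{trs}(1 - e^{-k_{ext} \cdot LAI})\,K^+ + b_{trs}\cdot LAI
  \cdot VPD$: a radiative term saturating with canopy light interception
  plus an aerodynamic vapour-pressure-deficit term. An alternative reading
  that places the VPD inside the radiative exponent is available via
  `vpd_in_exponent = TRUE`; the default is the standard empirical form, in
  which the night-time rate reduces cleanly to $b_{trs}\cdot LAI\cdot VPD$.
* **Canopy.** A Boltzmann sigmoid leaf area index,
  $LAI(t) = a_{LAI}/(1 + e^{(x_0 - t)/b_{LAI}})$.

## Environment drivers

Two environments are provided. The **controlled room** is a deterministic
24 h square wave: 14 h light at 120 µmol m^-2^ s^-1^ PPFD (converted to
W m^-2^ by a source constant, default 4.6 µmol J^-1^), 23 °C / 60 % RH by
day and 20 °C / 73 % RH by night, giving VPD setpoints of 1.124 and
0.631 kPa through the Tetens saturation curve
$e_s(T) = 0.6108\,e^{17.27T/(T+237.3)}$ kPa. This is the environment the
estimation campaign is simulated under.

The **stochastic weather generator** drives the dosing analyses. Solar
irradiance is a Kasten-Czeplak clear-sky model on the solar elevation
($A \sin h - B$ with $A = 910$, $B = 30$ W m^-2^), attenuated by total
cloud cover $N$ in oktas via $1 - 0.75 (N/8)^{3.4}$, with $N$ following a
reflected Gaussian random walk on $[0, 8]$ (step 0.5 okta per $\sqrt{h}$).
VPD follows an independent reflected random walk on $[0.5, 2.0]$ kPa
(step 0.05 kPa per $\sqrt{h}$). Reflection rather than clamping is used at
the boundaries so the walks do not stick to them. One integer seed fixes a
trajectory bit-for-bit.

Because an open-sky irradiance scale is far above a low-light growing
room, the clear-sky output is multiplied by a scaling factor (default
0.05). `calibrate_irradiance_scale()` chooses it in closed form — the
transpiration model is linear in irradiance — so that the time-mean
simulated transpiration under stochastic weather matches the
controlled-room mean for the same plants. With the calibrated scale, the
ensemble medians of daily-mean transpiration fall inside the range of the
controlled-room daily means (verified in the suite).

## Integration and events

The integrator is a fixed-step classical RK4 with default `dt = 0.1` h
(coarser steps are used internally where the dynamics are slow; see
"Problem sizes" below). The system is non-stiff at realistic parameters:
the fastest time constants are hours, so even `dt = 2` h keeps RK4 error
far below measurement noise. Since transpiration and root growth are
state-independent, their schedules are precomputed on the half-step grid
before the main loop, which makes a 54-day run take a fraction of a
second.

Dosing and replacement are instantaneous events applied at grid times
(never at the start time), so the smooth dynamics between events are
integrated without discontinuities — the reason a fixed-step scheme with
explicit event hooks was chosen over an adaptive library solver. (A test
cross-checks the integrator against an adaptive reference solver on a
smooth no-event scenario.) Nutrient masses are clipped at zero with a
warning; the run aborts if clipped mass exceeds 1 % of throughput, since
Michaelis-Menten uptake vanishes as $C \to 0$ and persistent clipping can
only mean the step is too coarse. A tank drained to zero volume aborts
with a diagnostic.

## Dosing controllers

Three fertigation controllers act at a fixed interval (default 24 h; the
interval is a configuration choice, not a measured value):

* **volume**: tops the tank up to $V_0$ with feed solution, so nutrient
  influx tracks transpired water;
* **time**: adds a fixed water volume and fixed nutrient amounts each
  event. Its dose is calibrated against an EC+volume reference run so the
  controllers supply comparable cumulative amounts — otherwise the
  comparison of their root-zone trajectories would be confounded by
  different totals;
* **ec_volume**: restores the tank's total ionic equivalents to
  $V_0 \cdot EC_0$ with nutrients in the feed's composition ratio
  (normalized on the equivalent scale so the restoration is exact by
  construction), and separately tops water up to $V_0$.

EC is carried as total equivalent concentration (eq m^-3^ ≡ meq L^-1^),
treating conductivity as a linear proxy for total ionic concentration; a
display-only conversion of 0.1 dS m^-1^ per meq L^-1^ is provided. None
of the controllers ever removes solution, so dosing-managed runs emit no
waste; only the weekly full-replacement protocol does, and
`emission_accounting()` reports it.

Reproducibility across stochastic weather replicates is summarized by the
percent coefficient of variation of the root-zone concentrations. The %CV
is computed across replicates at each sampled time and then averaged over
time (headline), with a per-replicate-trajectory variant also reported,
since either axis convention is defensible. The suite verifies, on a
50-replicate ensemble, that volume-based dosing has the highest mean %CV
and that the three controllers show their signature dose-rate patterns:
irregular (volume), constant (time), smoothly increasing with crop uptake
capacity (EC+volume). Signature detection uses the CV of the event sizes,
the Kendall trend, and the residual CV around a loess trend — a linear
detrend would misread the sigmoidal EC+volume ramp as irregular.

## Estimation from weekly depletion records

The measurement campaign mirrors a weekly N/W (depletion) protocol: the
tank starts each week from a freshly prepared solution, is never topped up
within the week, and is fully replaced at the week's end after the final
concentrations and volume are recorded. Per-plant absorption over a week
is $(C_i V_i - C_f V_f)/n$ and water use $(V_i - V_f)/n$.

`fit_params()` minimizes the RMSE between simulated and measured
*accumulated* quantities in two stages: transpiration and canopy
parameters ($a_{trs}, b_{trs}, a_{LAI}, x_0$) against accumulated
transpiration first, then per-ion $(J_{max}, K_m)$ against accumulated
uptake with stage 1 frozen. The stages exploit model structure:
transpiration is state-independent, so stage 1 is pure quadrature with no
ODE solve; given $V(t)$, the per-ion depletion ODEs decouple, so stage 2
is six independent two-parameter fits. Root geometry ($R_{max}, K_1, k_1,
r_0$), $b_{LAI}$ and $k_{ext}$ are held at configured values: tank
depletion identifies only the product $P_{RSA} \cdot J_{max}$, so the
root geometry must come from elsewhere (destructive measurement or
literature), which is also why whether growth parameters should be fitted
jointly is genuinely open — we fit the canopy scale and timing through
transpiration and fix the rest.

Each stage uses multi-start Nelder-Mead on box-transformed (logistic)
coordinates with Latin-hypercube starts plus the reference start,
deterministic given the seed; convergence is by relative objective change
($10^{-10}$) within an evaluation budget.

**Km identifiability.** When the weekly depletion never brings $C$ near
$K_m$ — the usual situation with half-saturation constants of order
0.05–0.1 mol m^-3^ against concentrations of 1–7.5 mol m^-3^ — the
$(J_{max}, K_m)$ objective has a flat ridge and the joint optimum is
noise-driven. The fit therefore profiles the objective at the reference
$K_m$ with $J_{max}$ re-optimized; if the profiled fit is essentially as
good as the joint one (within 10 % of the objective scale), $K_m$ is
flagged unidentified and $J_{max}$ is reported conditional on the
reference $K_m$. Because flatness means exactly that the fit is
insensitive to $K_m$, the conditional $J_{max}$ is stable where the joint
one is not.

## Composition optimization

Under EC+volume dosing the root-zone trajectory is reproducible but —
dosed with the standard composition itself — drifts away from the
standard composition, because uptake selectivity (the $J_{max}$
proportions) differs from the solution proportions.
`optimize_dosing_composition()` searches the product of the anion and
cation percentage simplices for the feed ratio whose root-zone
percentage-molar-ratio trajectory deviates least from the standard. The
deviation metric is the RMS over hourly samples and all six ions on the
percentage-ratio scale, averaged over a small fixed set of weather seeds
(default 5); mean-absolute and final-time variants are available. Molar
(not equivalent) percentages are the default basis, with an
equivalent-basis option since the classical Steiner ratios are
equivalent-based. Aggregation over the whole trajectory (rather than only
the final state) was chosen to match how the estimation stage scores whole
progress curves.

The simplices are handled by softmax reparameterization (one pinned
logit per charge group), which respects non-negativity and the 100 %
constraints without penalty tuning; the absolute feed built from a ratio
is made electroneutral by construction (anion and cation groups each
carry half the equivalents). The standard ratio is always one start, so
the optimum can never be worse than dosing the standard. Subsets of ions
can be frozen at their standard shares, which both expresses practical
constraints and enables a one-dimensional brute-force grid cross-check of
the optimizer (the suite requires agreement within one grid step of a
101-point grid).

`jmax_ratio_cv()` quantifies the stoichiometric observation behind this
analysis: across species, raw $J_{max}$ values vary with overall uptake
capacity, but their within-group percentage ratios — being
scale-invariant — vary much less, so the dosing problem reduces to
matching proportions.

## The synthetic-data generator

No measured campaign ships with the package, so `synthetic_spec()` /
`generate_campaign()` emulate the depletion experiment: 84 plants on a
0.3 m^3^ tank for 1296 h under the controlled-room schedule, eight
measurement periods (seven full weeks plus the 120 h remainder), each
week starting from a fresh solution drawn per-ion around the standard
composition (means 7.5, 3.0, 2.5, 4.0, 1.9, 1.4 mol m^-3^ with SDs 1.0,
1.4, 1.1, 0.4, 0.4, 0.2 — totalling 26.1 meq L^-1^ on average).
Measurement noise is relative Gaussian: 3 % on concentrations and 1 % on
volumes, the precision of ion-chromatography / ICP-OES-grade analytics;
recorded final volumes are truncated at the initial volume since water
leaves only by transpiration. At zero noise the records are exactly the
simulated values, so N/W absorption reproduces the integrator's own
uptake integral — the consistency oracle the suite checks.

The species parameter presets (`pakchoi` > `lacinato_kale` >
`curly_kale` in uptake and transpiration capacity, NO~3~ the most
absorbed ion everywhere, SO~4~ elevated in the kales) are synthetic: no
species parameter values are printed sources we can ship. Their
magnitudes are chosen so that (i) weekly per-plant transpiration sits in
the 10^-4^–10^-3^ m^3^ band, (ii) weekly depletion is pronounced but
incomplete (final-week concentrations fall by roughly a third to a half),
and (iii) $K_m$ sits in the physiological tens-of-µM-to-0.1-mM range,
far below tank concentrations — which deliberately puts $K_m$ in the
weakly identified regime discussed above. Ground-truth draws jitter these
presets by 5 % log-normally.

What the generator does *not* emulate: analytical bias or drift, ion
interactions and efflux, pH- or temperature-dependent uptake, within-week
environmental excursions of the controlled room, or plant-to-plant
variability (the population acts as $n$ identical plants). Passing
recovery tests therefore show that the estimation machinery is correct
and well-conditioned under the stated noise model — not that the model
captures every feature of real depletion data.

## Problem sizes and tolerances

The suite and the acceptance script size their runs to seconds-to-minutes
on a single core while keeping Monte-Carlo error well inside the asserted
margins: 50 weather replicates for the %CV ranking, 10 noisy campaigns
for recovery (medians asserted within 25 %; zero-noise within 10 %),
3-seed scenarios at a 672 h horizon for the optimization contract, and
`dt` between 0.5 and 2 h where the relevant dynamics are slow (RK4 error
at these steps is orders of magnitude below the noise floor; the
steady-state check at `dt = 1` h reproduces the analytic value to
0.1 %). The headline 54-day simulations run at `dt = 0.5` h or finer.

## Known limitations

* The tank is well mixed: no spatial heterogeneity, no root-zone gradients.
* No pH, ballast ions (Na, Cl) or micronutrient dynamics; micronutrients
  appear only as configuration constants.
* No biomass or yield model: growth enters only through root length and
  LAI curves.
* The EC proxy ignores ion-specific conductivity differences.
* Parameter recovery quality depends on depletion depth; campaigns with
  shallow depletion identify $J_{max}$ but say little about $K_m$ (the
  flatness flag makes this explicit rather than hiding it).
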