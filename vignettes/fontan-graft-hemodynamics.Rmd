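---
title: "Modelling Fontan graft stenosis with a closed-loop lumped-parameter circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Fontan graft stenosis with a closed-loop lumped-parameter circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanlpn)
```

## The problem

Children palliated with a Fontan operation live with a single functional
ventricle: systemic venous return passes *passively* through a total
cavopulmonary connection (TCPC) — superior vena cava (Glenn) and an
inferior caval conduit — into the lungs.  When the conduit is a
tissue-engineered vascular graft (TEVG), it commonly narrows during the
first year and then remodels.  The clinical question this package
addresses computationally is: **how much conduit narrowing can this
circulation tolerate, at rest and during exercise, before oxygen delivery
and venous pressures leave the normal range?**

`fontanlpn` answers it at desk scale.  Instead of patient-specific 3D
fluid–structure simulation, it couples a closed-loop lumped-parameter
(0D) model of the whole circulation to a reduced-order graft element, and
derives the same panel of metrics a full simulation study would report:
oxygen extraction ratio (OER), mixed venous saturation (sVO~2~), cardiac
index (CI), caval and aortic pressures, conduit pressure gradient, TCPC
energy efficiency, wall shear descriptors (TAWSS, OSI), wall strain and
residence time.

## The circulation model

The network has nine compartments: single ventricle, atrium,
aorta/systemic arteries, upper-body bed, SVC, lower-body bed (hepatic and
splanchnic return included), IVC/Fontan inlet, pulmonary arteries and
pulmonary veins.  States are *stressed* compartment volumes $V_i$
(volume above the unstressed filling volume), so pressures are
$P_i = V_i / C_i$ for vascular nodes, $P = E(t)\,V$ for the heart
chambers, and total stressed volume is conserved exactly by construction.
Branch flows are resistive, $Q = \Delta P / R$, with three exceptions:

* **Valves** (atrioventricular, aortic) are smoothed diodes,
  $Q = \tfrac{1}{2}\left(\Delta P + \sqrt{\Delta P^2 + \varepsilon^2}\right)/R$
  with $\varepsilon = 10^{-3}$ mmHg, which keeps the system smooth at
  closure while bounding reverse flow at a negligible leak.
* **The ventricle** follows a time-varying elastance
  $E(t) = E_{min} + (E_{max} - E_{min})\,e(t)$ with a C^1^ double-cosine
  activation rising over the first 30% of the beat and relaxing by 45%.
* **The graft element** carries a nonlinear two-term loss (next section),
  inverted in closed form inside the ODE.

Respiration applies a zero-mean sinusoidal intrathoracic pressure offset
(default amplitude 2 mmHg, period 3 s) to the thoracic compartments.
Because the oxygenation and pressure metrics are averaged *across a
respiratory cycle*, the heart period is snapped to the nearest integer
divisor of the respiratory period (at the resting 80 beats/min default,
exactly 4 beats per breath, so no adjustment occurs at rest).

The system is integrated by a fixed-step 4th-order Runge–Kutta scheme in
compiled code (step 0.2 ms), respiratory cycle by respiratory cycle,
until the cycle means of all nine node pressures change by less than a
relative $10^{-3}$ between successive cycles; one further cycle is then
recorded as the reported trace.  `lpn_rhs()` exposes the identical
compiled kernel to external integrators, which is how the test suite
checks the network against analytic RC solutions and its DC
(constant-elastance, linear-valve) limit.

## The baseline parameter set and its provenance

Patient-specific network constants for this population are not publicly
available, so the package ships a *baseline pediatric Fontan set* at a
reference body surface area of 0.67 m², scaled allometrically
(resistances and elastances $\propto 1/\mathrm{BSA}$, capacitances and
volumes $\propto \mathrm{BSA}$).  The baseline was calibrated once,
against published *normal ranges* for pediatric Fontan physiology at
rest — cardiac index 2.5–4.0 L/min/m², mean arterial pressure 60–80 mmHg,
caval pressure 10–16 mmHg, venous saturation 60–80% — with the operating
point placed mid-range at values typical of Fontan series (CI ≈ 3.2–3.4,
MAP ≈ 68–70 mmHg, caval ≈ 13.5–14 mmHg).  No output of the model was
ever fitted to the cohort results it is later compared against.

```{r baseline}
p <- lpn_parameters(bsa = 0.67)
p
trace <- run_to_periodic(p)
trace
```

## Exercise

Exercise intensity is expressed in youth metabolic equivalents
(MET; basal VO~2~ 6.5 mL/kg/min in children; MET 5 is a typical maximal
rate).  Four laws scale the resting circulation (`apply_met()`):

* **Total vascular resistance** follows the closed form
  $\mathrm{TVR}_{MET} = -6.25 \ln(\mathrm{MET})/\mathrm{BSA} +
  \mathrm{TVR}_{MET\,1}$ in Wood units.  For small patients at high MET
  this crosses zero; `tvr_at_met()` floors the result at 10% of the
  resting value and flags it.
* **Heart rate** rises linearly from the resting rate to 190 beats/min at
  MET 5 (a standard pediatric maximum), then re-snaps to the respiratory
  divisor.  Heart rate is a function of MET only — stenosis never alters
  it.
* **Pulmonary resistance** falls 5% per MET step above rest
  (recruitment/distension; 0.8× at MET 5).
* **Contractility and venous tone**: $E_{max}$ rises 25% per MET step,
  and systemic venous capacitances fall 7% per MET step.  The latter is
  the sympathetic venoconstriction / muscle-pump mechanism; without it a
  preload-limited Fontan circulation cannot raise its output or its
  caval pressures on exercise, and exercise CI saturates far below
  observed maxima.

All four slopes are configuration, not physics baked into the network;
only the TVR law has a printed closed form.

## The graft element

The conduit is reduced to (i) a pressure-loss element and (ii) a
Laplace-law compliance.

**Pressure loss.**  A two-term empirical law replaces 3D computation of
the stenotic flow field:
$$\Delta P = K_v\,\mu\,\frac{L_s}{D_s^4}\,Q
 \;+\; \frac{128}{\pi}\,\mu\,\frac{L - L_s}{D_0^4}\,Q
 \;+\; K_t\,\frac{\rho}{2}\left(\frac{A_0}{A_s} - 1\right)^2
 \frac{Q}{A_s}\left|\frac{Q}{A_s}\right|$$
with $D_0, A_0$ the local reference lumen, $D_s, A_s$ the throat, $L_s$
the constriction length.  Defaults: $K_v = 128/\pi$, so an unconstricted
tube reduces exactly to Poiseuille flow over its full length, and
$K_t = 1.52$, the classical empirical expansion coefficient for
constricted tubes.  Two modelling points matter:

* Virtual stenoses are defined *relative to the measured lumen* (a 50%
  level halves the measured minimum diameter); consequently a measured
  geometry carries no expansion loss of its own — its narrowing is
  gradual — and the resting conduit gradient is at the fraction-of-a-mmHg
  scale observed clinically, rather than the tens of mmHg a
  sudden-expansion model of the full implant-to-minimum taper would
  predict.
* The element is odd in $Q$ and strictly increasing in both $|Q|$ and
  severity, which the property tests assert.

**Compliance.**  A thin-wall linear-elastic tube of modulus $E$,
thickness $h$ (default 1.5 mm, overridable; no printed measurement
exists), radius $r$ and length $L$ contributes
$C = 3\pi r^3 L/(2 E h)$, lumped into the IVC-node capacitance.  This
avoids a degenerate zero-capacitance state for the rigid comparison arms
(`rigid`, `eptfe16`), which simply contribute $C = 0$.

**Wall-modulus tuning.**  `tune_wall_modulus()` inverts the same
thin-wall response: given a target luminal fractional area change under a
pressure waveform, bracketed root finding returns the modulus, and
round-trips the four tuned cohort moduli (8.00–17.00 kPa) within 1%.

**Ring-test mechanics.**  The scaffold characterization formulas are
implemented as printed: equivalent pressure $P = mg/(2wr)$ with
$r = L/\pi$, stress $mg/(2wh)$ with $h = V_0/(2\pi r w)$ from
incompressibility, stretch $L/L_0$, secant stiffness between the
diameters interpolated at 5 and 50 mmHg, and burst pressure at the
failure weight.

## Stenosis compensation

The modelled long-term response to conduit narrowing is blood-volume
retention alone: `compensate_blood_volume()` rescales total stressed
volume (bracket 0.5–3.0, bracketed root finding, each evaluation a full
periodic run) until the maximum aortic pressure matches the same
patient's unstenosed reference at the same MET, within 0.5 mmHg.  Every
other parameter is bit-identical before and after — the tests assert
this, plus idempotence and the monotonicity of maximum aortic pressure in
stressed volume that makes the root unique.

## Metrics

* **OER and sVO~2~** are Fick-principle estimates with the printed
  constants (hemoglobin 13.26 g/dL, capacity 1.34 mL O~2~/g, arterial
  saturation 0.94, PO~2~ 90/40 mmHg).  The dissolved-oxygen coefficient
  is 0.003 in the OER denominator but 0.03 in the sVO~2~ numerator; the
  two printed values differ by a dL/L convention and are preserved
  *as printed*, with `oxygen_constants(harmonize_dissolved=)` available
  to force a common value.  OER > 1 and sVO~2~ < 0 are non-physiologic
  and flagged, not clipped.  Cardiac output for both is the
  respiratory-cycle mean aortic flow.
* **CI** is SV × HR / BSA averaged across the respiratory cycle, stroke
  volume from the ventricular volume series.  Note that with breathing
  active the per-beat volume swing slightly exceeds the net ejected
  volume, so CI sits a few percent above mean aortic flow / BSA; without
  respiration the two agree to well under 1%.
* **TCPC energy efficiency** is the ratio of outlet to inlet
  $\int (p + \tfrac{1}{2}\rho u^2)\,Q\,dt$ over the SVC and conduit
  inlets and the two pulmonary outlets, in percent.
* **TAWSS / OSI** operate on wall-shear fields (locations × times); the
  study pipeline builds a quasi-steady Poiseuille shear surrogate
  $4\mu Q(t)/\pi r(x)^3$ along the lumen profile.  OSI of identically
  zero shear is defined as 0 (no oscillation).
* **Green strain invariant** $\mathrm{tr}\!\left(\tfrac{1}{2}(F^TF -
  I)\right)$, time-averaged for magnitude then spatially averaged; the
  pipeline derives the circumferential stretch from the luminal pressure
  waveform through the same thin-wall law (zero for rigid arms).
* **Residence time** solves $\partial_t\tau + u\,\partial_x\tau = 1$
  ($\tau = 0$ at the inflow) on a 1D axisymmetric grid with first-order
  upwinding, repeated over cycles until the cycle-averaged field is
  damped; the reported value is the maximum cycle-averaged $\tau$ in
  cardiac cycles, evaluated on a near-wall streamline of the parabolic
  profile (station $0.9R$, velocity factor $2(1-0.81) = 0.38$).
  $\tau$ is capped at `n_cycles` periods and stagnation is flagged.

## The synthetic cohort

`generate_cohort()` emulates the four-patient trial population: BSA
uniform on [0.53, 0.83] m² (the measured span), implant diameter 16 or
18 mm, tuned wall modulus uniform on [8, 17] kPa, minimum diameter a
uniform 0–60% reduction from implant.  Uniform distributions were chosen
because only ranges, not distributions, are available.  Body mass comes
from the invertible Costeff relation $W = (90\,\mathrm{BSA} - 7)/(4 -
\mathrm{BSA})$, selected because it is an explicit pediatric closed form
(measured weights are not published).  `trial_cohort()` loads the real
four patients (two MRI time points; the 6-month records form the default
4-patient fixture, whose mean minimum diameter, 0.97 cm, matches the
reported cohort geometry).  Measured *area* stenosis percentages are
carried through as data and never recomputed from diameters: the
measured lumens are not circular, and the printed area and diameter
percentages are mutually inconsistent under a circular assumption.

What the generator does **not** emulate: anatomic curvature and
non-circular lumens, measured caval flow splits, intra-patient
correlation between modulus and stenosis, or growth between time points.
Passing tests therefore demonstrate correctness of the pipeline under
idealized axisymmetric conduits and population-scale parameter ranges,
not patient-specific anatomic fidelity.

## A full study

```{r study, eval = FALSE}
cfg <- study_config(cohort = "fixture", arm = "mri",
                    met_levels = c(1, 3, 5),
                    stenosis_levels = c(0.3, 0.5, 0.7))
rep <- run_study(cfg)
rep$summary
```

The shipped study sizes are deliberate: the trial fixture (4 patients) ×
3 MET levels for the metric panel, and 3-level virtual stenosis sweeps
with volume compensation for trend properties.  Each periodic run takes
well under a second, a compensated run a handful of periodic runs, so a
full sweep completes in about a minute on one core.

## Numerical choices and degenerate inputs

* RK4 step 0.2 ms (the shortest network time constants are a few ms);
  trace output every 2 ms; periodicity tolerance $10^{-3}$ (halving the
  tolerance moves cycle-mean pressures by < 0.5%).
* Initial volumes distribute the stressed volume across compartments in
  proportion to capacitance — a neutral start; convergence typically
  takes 5–15 respiratory cycles.
* Non-finite states abort integration with an explicit error;
  non-convergence within the cycle cap reports the last residual.
* Constant-elastance inputs are legal (the DC limit used in testing);
  an exactly zero elastance amplitude is rejected ($E_{max} > E_{min}$),
  use an arbitrarily small amplitude instead.
* `fit_trend()` (two-term exponential, visualization only) flags
  constant data as a degenerate fit family rather than failing.

## Known limitations

* The 0D surrogate cannot resolve 3D junction flow: TCPC efficiency uses
  node pressures and a profile-factor kinetic term, and the residence
  time surrogate cannot capture recirculation in oversized conduits, so
  both are most trustworthy for moderate geometries.
* At extreme virtual stenosis (≳ 60% of an already-narrowed lumen) with
  full volume compensation, venous pressures leave the physiologic range
  (the linear venous capacitances impose no ceiling), and the two-inlet
  energy-efficiency ratio can turn non-monotone as the SVC pathway
  dominates the energy ledger.  Trend properties are therefore asserted
  over the moderate range.
* Conduit pressure gradients at high stenosis represent upper bounds:
  the model includes no compensatory mechanism beyond blood volume
  (no collateral formation, no heart-rate response to stenosis).
* The graft wall is linear-elastic and thin-walled; wall thickness
  defaults to 1.5 mm in the absence of a printed measurement.
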