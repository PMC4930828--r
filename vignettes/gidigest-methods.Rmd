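---
title: "Modelling multiphase digestion in the antroduodenum: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multiphase digestion in the antroduodenum: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gidigest)
```

## The physiological system and the model

`gidigest` simulates the digestion stage in the antroduodenal portion of the
gastrointestinal tract: the distal stomach (antrum), the pyloric sphincter and
the duodenum. The contents are treated as an interpenetrating multiphase
mixture in the Euler-Euler sense:

* **Phase 1** is a multicomponent fluid with ten dissolved components, indexed
  0..9: hydrochloric acid, the inert neutralization product (NaCl + CO2),
  sodium bicarbonate, dissolved proteins, fats, carbohydrates, a trace
  chemical (lead is the exemplar), pepsin, polypeptides and water.
* **Phases 2..6** are food-particle size bins with fixed representative
  diameters 3.6, 2.8, 1.7, 0.7 and 0.2 mm. Particles are modelled as a
  pseudo-fluid of higher viscosity; all bins share one density (1040 kg/m^3
  in the standard scenarios, 1005 kg/m^3 in the light-particle scenario).

Mass balances close over the constraints `sum_i Y_i = 1` within the fluid and
`sum_j alpha_j = 1` over the phases.

The tract wall carries four functional regions: the acid-secreting upper
antrum wall (region 2), the bicarbonate-secreting lower antrum (region 3),
the duodenal wall (region 4), and the pancreatic-inflow segment of the
duodenum (region 5). Each region has functionality factors
`F(l)(m) = 1 - damage` for secretion (m = 1), absorption (m = 2) and motor
activity (m = 3); every source term and the wave amplitude scale linearly
with the corresponding `F`. Six standard scenarios cover the healthy
baseline, two grades of acid-secretion deficit (atrophic gastritis), two
grades of alkaline-secretion deficit (duodenal ulcer / pancreatic
insufficiency), and a light-particle variant.

### Local physics

* **Neutralization.** NaHCO3 + HCl -> (NaCl + CO2) + H2O at a bimolecular
  rate `k02 C0 C2` with `k02 = 1e4 m^3/(kmol s)` (ion exchange is effectively
  instantaneous; this is the configured lower bound). Component mass rates
  are molar rates times molar masses; the product component is treated as
  chemically inert. Because `M(HCl) + M(NaHCO3) = M(product) + M(H2O)`
  exactly (the product's molar mass is defined as NaCl + CO2), the reaction
  conserves mass to machine precision.
* **pH.** `pH = -log10(max(C0, 1e-8))` with the acid concentration in
  kmol/m^3 of mixture (identical to mol/L). The floor caps acid-free fluid
  at pH 8, the alkaline end of the physiological duodenal range; buffering
  beyond acid consumption is deliberately not modelled, so alkalinity is
  expressed through the capacity to neutralize acid rather than through
  pH > 8.
* **Proteolysis.** Michaelis-Menten kinetics in the protein concentration,
  first order in pepsin, modulated by a quadratic pH-activity window
  `f(pH) = max(0, a pH^2 + b pH + c)` with the fitted coefficients
  (-5.786, 26.819, -4.857): optimum at pH 2.32, activity zero outside
  (0.19, 4.45). The rendered rate is exactly `M3` times the molar turnover,
  so polypeptides gain precisely the protein mass lost (the polypeptide
  registry entry reuses the substrate molar mass for this reason).
* **Dissolution.** The particle-to-solution mass transfer coefficient is
  `k = k_phys * 3.246 * pH^(-2.092)` kg/(m^2 s), ~`k_phys` at the normal
  gastric pH 1.8 and zero at neutral/alkaline pH (>= 7). For spherical
  particles the volumetric flux from bin j is `6 k alpha_j / d_j`, split
  over dissolved components by the raw-carrot composition
  (protein 0.013, fat 0.001, carbohydrate 0.093 - beta6, lead 2.8e-7,
  water 0.893). The smallest bin represents nondigestible fibres and is
  exempt.
* **Size cascade.** Dissolving particles shrink past bin boundaries; with
  fixed bin diameters this is a mass flux from bin j to bin j+1,
  `6 d_{j+1}^3 k alpha_j / (d_j (d_j^3 - d_{j+1}^3))`. Among the readings
  the raw formula admits, this placement of the fraction is the one that is
  dimensionally consistent with `k` in kg/(m^2 s), and it is the one
  implemented. Nothing flows into the largest bin or out of the smallest.
* **Secretion.** All glands respond saturably (Michaelis-Menten form) to the
  near-wall concentration that physiologically stimulates them: acid to
  dissolved protein/fat/carbohydrate (maximal output 2.02e-7 kg/s, basal a
  fifth of that), pepsin to dissolved protein, bicarbonate (regions 3, 4 and
  the pancreatic region 5) to the local acid concentration — the feedback
  that neutralizes duodenal acid. Water is co-secreted at fixed ratios
  (171.3 kg water per kg acid, i.e. gastric juice is 0.58% HCl by mass;
  395.5 and 78.3 per kg bicarbonate in the duodenal and pancreatic
  secretions), so gland-fluid composition is constant. The tabulated
  constants are regional totals divided by the wall-layer volume `V(l)`;
  since sources are applied across exactly that layer, `V(l)` cancels from
  every regional mass budget and only sets the local intensity. The layer is
  taken as 10% of the region's cross-section.
* **Absorption.** The trace chemical diffuses through the wall at
  `-F(l)(2) * 3.34e-3 s^-1 * (c6 - h6 C6_blood)`, applied to the wall-layer
  share of each region cell with the local concentration (the trace level,
  beta6 = 2.8e-7 of particle mass, feeds back on nothing; the choice of
  local versus region-mean concentration only affects the absorbed-mass
  ledger). Blood concentration is held at zero: the systemic
  pharmacokinetic compartment is out of scope.

### Motility

Peristalsis is prescribed kinematically. Antral waves start at the proximal
end every 18 s, travel at 2.2 mm/s for 38 s, with width 2 cm and amplitude
9 mm; duodenal waves start at the pylorus exit every 9 s, at 5 mm/s for
36 s, width 4 cm, amplitude 3.5 mm. Waves are sin^2-shaped indentations of
the baseline radius, scaled by the motor functionality of the local region,
and their amplitude ramps linearly over the first/last 2 s of life so the
wall volume rate is continuous (an instantaneous wave death would otherwise
inject a volume step into the 1D continuity balance). The radius never drops
below a 2 mm floor, making the deep antral waves near-occlusive, as terminal
antral contractions are.

The pyloric gate opens for 2 s every 18 s, phased so that an opening
coincides with the antral wave reaching mid-antrum — antral, pyloric and
duodenal motor activity are synchronized. The pylorus wall itself is rigid
(4 mm radius); gating acts as a flux switch at the mid-pylorus interface
rather than as a moving wall, which avoids spurious volume pulses from
squeezing the tiny pyloric segment.

### Geometry

The 3D organ is reduced to a quasi-1D channel of circular cross-sections of
equivalent area along the centerline: an antral bulge (radius 2.2 cm at the
closed proximal end, tapering as cos^2 to 6 mm at the pylorus entrance over
10 cm), a 1 cm pylorus, and an 18 cm duodenal tube of radius 1 cm. These
dimensions were chosen once from typical adult anatomy; with the standard
initial fill (the bolus occupies the bulge, x <= 7 cm) they give an initial
particle load of ~0.04 kg, matching the reference bolus mass. Gravity enters
as a configurable per-cell cosine of the angle between centerline and
vertical (default upright posture: -0.5 in the antrum — "down" points into
the bulge — 0 in the pylorus, +0.3 in the duodenum).

## The reduced momentum closure

The full multiphase momentum equations are deliberately not solved — the
reference results for this system come from a dynamic-mesh 3D CFD, and a
desk-scale reduction cannot and does not aim to reproduce quantitative
velocity fields. Two ingredients replace them:

1. **Mixture velocity from 1D incompressibility.** With prescribed wall
   motion, `dV_i/dt + Phi_{i+1/2} - Phi_{i-1/2} = Q_i` integrates to the
   total volume flux through every face, starting from the closed esophageal
   end. When the gate is closed the antrum is sealed at both ends, which is
   only consistent if its net wall-volume rate vanishes; the residual is
   redistributed over antral cells in proportion to their volume before
   integrating. Physiologically this is receptive relaxation: what the wave
   squeezes, the rest of the stomach wall accommodates. When the gate opens,
   the accumulated imbalance vents through the pylorus — this is the pumping
   mechanism that drives gastric emptying, on top of the net secreted
   volume.
2. **Drift-flux slip.** Each particle bin moves relative to the fluid at its
   terminal velocity, the root of
   `K(j)(1) (v1 - vj) + alpha_j (rho_j - rho_mix) g_axis = 0` with the
   Reynolds-corrected Stokes drag
   `K(j)(1) = 18 alpha_j alpha_1 eta_1 / d_j^2 (1 + 0.15 Re^0.687)`. The
   fluid receives the compensating counterflow so the volume-averaged
   velocity matches the incompressibility solution. The implicit dependence
   of the drag on the slip is resolved by a damped (factor 0.5) fixed-point
   iteration, warm-started from the previous step, tolerance 1e-10 m/s,
   at most 100 iterations; the slip is capped at 0.2 m/s and the fluid
   fraction floored at 0.05 inside the closure for robustness in
   particle-packed cells. Particle-particle drag is implemented and tested
   but inter-bin slip is not applied in transport (drift-flux reduction);
   large-bin settling still elutriates fines toward the gate through the
   fluid counterflow.

This closure reproduces the settling phenomenology — bins >= 0.7 mm
accumulate in the bulge, only the smallest particles reach the gate region in
quantity — which is what the evacuation results depend on.

## Numerics

Operator splitting per substep: (1) wall kinematics and mixture velocity;
(2) upwind advection of the five particle-bin densities and ten component
densities, each with its own phase velocity, using MUSCL/minmod
reconstruction (TVD, second order in smooth regions; plain first-order
upwind available via `numerics$advection_order = 1`); (3) explicit Fickian
diffusion of the dissolved components (shared coefficient 1e-9 m^2/s —
negligible against advection but kept because motor-disorder studies need
it); (4) local sources in the order secretion, absorption,
dissolution/cascade, neutralization, proteolysis.

Numerical choices worth noting:

* **Time step.** Adaptive: `dt = min(0.05 s, 0.4 dx / vmax)` over all phase
  and face velocities. With `dx = 2 mm` (the default; 145 cells) a typical
  306-s run takes ~2e4 substeps.
* **Stiff neutralization.** With `k02 = 1e4` the reaction timescale can be
  ~10 ms; the bimolecular step is integrated exactly (closed-form extent of
  A + B -> products over dt) instead of explicitly, so it never limits dt.
* **Positivity.** Upwind transport at CFL <= 0.4 is positivity-preserving;
  source steps are limited so no mass goes negative (dissolution and
  cascade are scaled down jointly if they would exhaust a bin within a
  step). Stray negatives (roundoff) are clipped to zero and the clipped
  mass is ledgered; runs accumulate it in `ledgers$clip_added`.
* **Volume consistency.** Cell volume is the derived quantity
  `sum_j m_j / rho_j`; the wall-targeting term in the velocity construction
  uses `(V_wall(t+dt) - V_derived)/dt` plus a gentle relaxation
  (tau = 0.5 s), so any drift between derived and prescribed volume is
  self-correcting and mass is conserved exactly by construction. The global
  ledger (in-domain + evacuated + absorbed - secreted = initial) closes to
  machine precision and is asserted to 1e-8 in the tests.
* **Boundaries.** The esophageal end is a closed wall (no reflux during this
  digestion stage); the distal duodenal face is open with zero-gradient
  states — brief inflow during duodenal wave relaxation re-enters with the
  boundary cell's own composition and is netted in the evacuation ledger.
* **Convergence.** Halving dx from 2 mm to 1 mm changes the 306-s per-bin
  mass changes by under 10% (asserted in the test suite); the settled-bed
  and gate fronts are 1-2 cells thick, so per-bin results are
  resolution-sensitive at the few-percent level, consistent with a TVD
  scheme on steep fronts.

## The initial state as the study condition

Runs start from the standard post-ingestion state: the bolus (chewed carrot,
fragment-size distribution over the five bins with fractions
0.044/0.110/0.344/0.088/0.014 and 40% fluid) fills the antral bulge; the
fluid is pure water everywhere. This is deliberately not a physiological
steady state — there are no basal acid, pepsin or bicarbonate
concentrations — so that the spin-up of the secretory fields is itself
observable. Consequently early-time pH values sit at the water cap (8) until
acid spreads, and dissolution switches on only as the stomach acidifies.

## What the reduction does and does not show

The 1D model retains: the secretion feedback loops and their disorder
scaling, full stoichiometric acid-base chemistry, the dissolution cascade
and its pH coupling, axial settling/elutriation, synchronized peristaltic
pumping and gated evacuation. It cannot represent: cross-sectional
recirculation between wave crests, lateral settling to the greater-curvature
wall, the mucous microlayer (and hence near-wall pH gradients), free
air-liquid surfaces, temperature effects, or neural regulation beyond the
built-in concentration feedbacks. Quantities that depend on 3D recirculation
(velocity magnitudes, mixing times) are indicative only; scenario
*orderings* — which disorder dissolves food slower, where pH rises or falls,
which density evacuates small particles better — are the reduction's level
of validity, and those are what the acceptance suite asserts. The
15-minute small-bin evacuated fraction is compared with its reference value
only within a wide (±50%) band for the same reason.

Problem sizes used by the test suite: dx = 2 mm (145 cells) for all scenario
runs (306 s for the disorder comparisons, 900 s for the evacuation stage),
dx = 1 mm for the one refinement check, and a 4 mm grid for fast smoke
tests. A 306-s scenario takes on the order of a minute of wall time on one
core.

## Reproducing a run

```{r example}
library(gidigest)
sim <- gi_run(scenario = 1, T = 306)
print(sim)
summary(sim)
plot(sim)

# disorder comparison
sim3 <- gi_run(scenario = 3, T = 306)
sim3$phase_change_pct   # slower dissolution than scenario 1

# well-mixed reactor mode sharing the same physics
st <- gi_batch_init(volume = 1e-4)
st <- gi_step_batch(st, dt = 0.05, n = 2000)
gi_batch_summary(st)
```
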