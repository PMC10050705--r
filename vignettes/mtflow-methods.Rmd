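---
title: "Methods: 1D pulse-wave haemodynamics, virtual ageing populations and thrombectomy scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D pulse-wave haemodynamics, virtual ageing populations and thrombectomy scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtflow)
```

## The model

`mtflow` simulates blood flow in networks of elastic arteries with the
classical one-dimensional reduction of the incompressible Navier–Stokes
equations. Each vessel is a straight, radially elastic tube; integrating
mass and momentum conservation over the cross-section, and assuming a
power-law axial velocity profile with exponent $\gamma_v$, gives the
hyperbolic system

$$
\partial_t A + \partial_z Q = 0, \qquad
\partial_t Q + \partial_z\!\left(\alpha \frac{Q^2}{A}\right)
 + \frac{A}{\rho}\,\partial_z P
 = -\,2(\gamma_v + 2)\,\pi\,\frac{\mu}{\rho}\,\frac{Q}{A},
$$

closed by the tube law
$P(A) = P_{ext} + \beta\left(\sqrt{A/A_0} - 1\right)$ with
$\beta = \sqrt{\pi}\,E h_0 / \bigl((1-\nu^2)\sqrt{A_0}\bigr)$.
Here $A$ is the lumen area, $Q$ the volumetric flow, $A_0$ the diastolic
area, $h_0$ the wall thickness, $E$ Young's modulus and $\nu$ the Poisson
ratio. The local pulse-wave speed is
$c(A) = \sqrt{\beta\sqrt{A}/(2\rho\sqrt{A_0})}$, reducing to
$c_0 = \sqrt{\beta/(2\rho)}$ at the diastolic area. With the default
parabolic profile ($\gamma_v = 2$, Coriolis coefficient $\alpha = 4/3$) the
friction term is the Poiseuille value $-8\pi\nu_{kin} Q/A$.

Blood is characterised by $\rho$ and $\mu$; the defaults
$\rho = 1060\ \mathrm{kg/m^3}$, $\mu = 4\ \mathrm{mPa\,s}$ are standard
physiological values and both are configurable through
`fluid_properties()`.

## Numerics

The solver (`src/solver.cpp`, driven by `run_to_convergence()`) is a
second-order MUSCL finite-volume scheme: minmod-limited linear
reconstruction, Rusanov (local Lax–Friedrichs) interface fluxes, and
two-stage Heun time integration under a CFL number of 0.9 (configurable via
`solver_settings()`). The explicit time step is the global CFL limit over
all cells, $\Delta t = \mathrm{CFL}\cdot\min_i \Delta x_i/(|u_i| + c_i)$.
A time step that violates the CFL bound raises an explicit stability error
(`muscl_step()`), never a silent blow-up.

Cells are sized at roughly 6 mm by default with a floor of 5 cells per
vessel (10 on the catheter-hosting ICA segments so they remain splittable);
grid-refinement behaviour is checked in the test suite.

**Boundaries and junctions.** Interior cells are updated conservatively;
vessel-end cells are then overwritten from characteristic-compatibility
solves, the standard characteristic-based treatment in 1D pulse-wave solvers. The
outgoing Riemann invariant $u \pm 4c$ is combined with:

* *prescribed flow* (cardiac half-sine inlet, aspiration sink, or zero
  flow) — scalar Newton on the boundary area;
* *three-element windkessel* — the capacitor pressure is advanced by
  backward Euler and the coupled nonlinear equation solved by Newton;
  setting $R_1$ to the characteristic impedance $\rho c_0/A_0$
  (`match_impedance()`) keeps the linear reflection of incident pulses
  below 2%;
* *junctions* — conservation of mass plus continuity of total pressure
  $P + \tfrac{1}{2}\rho u^2$ at conjunctions, or static pressure at
  bifurcations and anastomoses, solved by a damped Newton iteration. The
  system is nondimensionalised (areas by $A_0$, velocities by $c_0$, rows
  to order one) so that large stiffness contrasts between the attached
  vessels — as arise for a 70% stenosis — do not degrade conditioning.
  Zero-flow boundaries use mirror ghost cells, an exactly conservative full
  reflector that preserves the rest state to machine precision.

**Periodic convergence.** Cardiac cycles are repeated until the largest
cycle-to-cycle change of any vessel's midpoint pressure trace drops below a
threshold, measured as a time-normalised L2 (RMS) norm in mmHg
(`convergence_error()`); the RMS normalisation makes the conventional
3 mmHg threshold dimensionally meaningful, and a constant offset of
3 mmHg between cycles yields exactly 3. Traces are compared on a fixed
1 ms grid. The default cap is 50 cycles; a run that does not converge is
flagged, never returned silently. Reported results always refer to the
last simulated cycle. Windkessel capacitors start at a configurable
pressure (75 mmHg by default in the population tools) to shorten the
charging transient.

## Network representation and files

`arterial_network()` assembles vessels, junctions, boundaries, named
anatomical sites (e.g. `MCA`, `ICApp`, `brachial`) and a left/right
symmetry map; `validate_network()` enforces the structural invariants
(every end attached exactly once, junction degrees, connectivity, at most
one heart inlet, symmetry an involution). Networks round-trip through a
YAML schema (`load_network()` / `write_network()`), SI units throughout.
Positive flow runs proximal→distal; retrograde flow is negative signed
mean flow. Site labels live in the network file, not in code, so other
topologies can be used unchanged.

`split_vessel_at()` and `detach_junction_edge()` are the topology edits
underlying catheter insertion and balloon flow arrest; both preserve the
total diastolic volume $\sum A_0 L$.

## The synthetic cerebral network

No published parameter set is shipped: the packaged 34-vessel network
(`toy_cow_network()`, `inst/extdata/cow_network_synthetic.yaml`) is a
synthetic parameterisation of the standard upper-body plus circle-of-Willis
topology — ascending aorta inlet, brachial/thoracic outlets, carotid trees
with the ICA split into ICApp/ICApd/ICAd by the Ophthalmic and
posterior-communicating branch points, MCA/ACA/PCA territories, ACoA and
PCoA closing the circle, 13 impedance-matched windkessel outlets.

Its parameters were chosen once, on physiological grounds:

* geometry and wall mechanics give pulse-wave speeds of 5–12 m/s and
  baseline MCA velocity ≈ 0.32 m/s;
* outlet resistances split a 4 l/min mean inflow into ≈ 570 ml/min
  cerebral flow (MCA ≈ 130 ml/min per side) at a mean arterial pressure
  near 95 mmHg;
* outlets discharge at a common 35 mmHg outflow pressure (venous plus
  critical-closing pressure, a standard lumped-model choice) and carry
  ≈ 1.6 ml/mmHg total compliance, calibrated — in the spirit of the
  preliminary-population calibration that `calibrate_baseline()`
  automates — so that the baseline brachial pressure lands near the
  age-25 literature reference (124/75 mmHg; the shipped network produces
  ≈ 124/81) while compliance-reduced aged subjects keep physiological
  diastolic pressures.

The cardiac inflow is half a sinusoid of 350 ml/s peak and 0.3 s duration
in a 1.0 s cycle, zero in diastole.

What the synthetic network does **not** emulate: real anatomical
variability of the circle of Willis, vessel tortuosity and curvature,
wall viscoelasticity, leptomeningeal collaterals and autoregulation, and
any particular published baseline's numbers. Tests passing on it show that
the machinery (solver, scaling, filtering, scenario edits, post-processing)
behaves correctly and that the qualitative haemodynamics are right; they do
not certify quantitative agreement with any clinical population.
Quantitative work should transcribe a literature baseline into the YAML
schema.

## Virtual ageing populations

Ageing is modelled by scaling the baseline network with six dimensionless
factors — arterial radius, wall thickness, wall stiffness, peripheral
resistance, peripheral compliance, cardiac output — drawn independently per
subject from age-specific normal distributions (ages 25–75 in decade
steps) shipped in `inst/extdata/ageing_scaling_factors.csv`. Sampling
(`sample_scalings()`) redraws non-positive values, a negligible-probability
truncation at the shipped parameters. `apply_scalings()` multiplies every
$A_0$ by the squared radius factor ($A_0 = \pi r^2$), $h_0$ and $E$ by
their factors (recomputing $\beta$), windkessel $R_1$, $R_2$ by the
resistance factor and $C$ by the compliance factor, and the inlet amplitude
by the cardiac-output factor; the operation is homogeneous (two scaling
sets compose by componentwise product) and uniform scaling preserves
left/right symmetry. The cardiac-output factor scales amplitude only;
period and systole duration stay fixed at 1.0 s / 0.3 s.

Each subject is run to the periodic steady state (3 mmHg threshold);
systolic/diastolic brachial pressure is the max/min of the brachial
midpoint trace. The plausibility filter accepts a subject iff both
pressures lie within 2.575 standard deviations of the age-specific
reference means (`inst/extdata/brachial_pressure_reference.csv`) — a closed
rectangle, with a $10^{-9}$ relative tolerance so that boundary values
computed as mean $\pm 2.575\,$sd accept despite rounding.

`calibrate_baseline()` selects, from a preliminary population, the subject
whose (SBP, DBP) best matches the youngest reference means; the distance is
Euclidean in mmHg by default (configurable to Manhattan, since the exact
published criterion is not in the main text), ties break to the lowest
index.

## Thrombectomy scenarios

A scenario is derived from a subject's network by three commuting edits
(`scenario_network()`):

1. **Balloon guide catheter** (`apply_bgc()`): the ICA/ECA/CCA junction is
   disconnected and the ipsilateral ICApp proximal end receives a zero-flow
   boundary; CCA and ECA remain joined as a conjunction. Idempotent;
   contralateral and posterior circulations untouched.
2. **Aspiration catheter** (`insert_aspiration()`): the tip is a node on
   the host segment (created by `split_vessel_at()`, default mid-segment —
   the 5-cell discretisation floor makes mid-segment the robust default,
   and at 1D resolution the axial position within these short segments is
   immaterial; the fraction is configurable) joined to a 1 cm stub whose
   free end withdraws a constant 0.5, 5 or 10 ml/s. The stub has fixed
   catheter-like geometry independent of the host's current state, so the
   edit order cannot matter. Aspiration is active in all three phases.
3. **Clot** (`apply_clot()`): phase 1 (clot in the MCA) replaces the MCA
   outlet windkessel by a zero-flow boundary (complete occlusion); phase 2
   models the moving clot as a 70% reduction of the host vessel's lumen
   area over its whole length, $\beta$ recomputed from the reduced area
   (a stiffer effective tube; both the severity basis — area vs diameter —
   and the $\beta$ recomputation are configurable switches, since the
   published convention does not specify them); phase 3 restores the
   pre-intervention outlet exactly.

Twelve configurations arise from three aspiration sites (ICApp, ICApd,
ICAd) crossed with the clot positions between occlusion site and tip plus
the clot-removed state (`enumerate_configurations()`); a campaign runs
every subject × configuration × rate job (`run_campaign()`), flagging
non-converged jobs without aborting.

## Post-processing

Cycle-mean flow is the trapezoidal time average over one cycle, reported
signed in ml/min; direction is a sign test (exact zero reported antegrade
with a flag). Velocity for the pulsatility index
$PI = (V_{max}-V_{min})/V_{mean}$ is $u = Q/A$ at the vessel midpoint,
matching the convergence-check site. Population tables report median
(min, max) per aspiration site and rate; a subject's several phase-2
configurations are reduced by their mean before the population median
(`campaign_flow_table()`), the aggregation order being ambiguous in the
published layout — the per-subject reducer is configurable.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use deliberately small problem
sizes chosen for a laptop-scale run: verification fixtures of 200–400
cells, populations of 6–12 subjects per age, campaigns restricted to
representative configurations; sampling moments are checked at $10^5$
draws. The solver itself is deterministic; all sampling randomness flows
from a single master seed, from which per-stage seeds derive
(`pipeline_age_filter_treat()` writes them to its JSON manifest).
Simulation outputs are written as per-vessel CSV (`write_results()`).

## Known limitations

One-dimensional flow cannot represent vessel curvature or tortuosity, 3D
flow structures at junctions, or fluid–structure interaction beyond the
elastic tube law. Catheters are not represented geometrically (no annular
flow resistance in catheterised segments). Clot mechanics and
fragmentation are out of scope: the clot is a boundary condition or a
stenosis, never a mechanical body. Heart rate is fixed across ages.
Windkessel outlets are the only distal model; there is no autoregulation
and no leptomeningeal collateral network.
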