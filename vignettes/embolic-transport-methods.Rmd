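---
title: "Methods: embolic particle transport in a synthetic circle of Willis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embolic particle transport in a synthetic circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embotrack)
```

# Scope and philosophy

`embotrack` is a reduced-order counterpart to patient-specific CFD studies of
embolus transport in the cerebral arteries. The expensive parts of such a
study — MRI segmentation, meshing, and a 3-D Navier–Stokes solve — are
replaced by components that run in seconds on a laptop while preserving the
structure that drives embolus routing: the topology and left/right asymmetry
of the circle of Willis (CoW), the division of flow among the MCA, ACA and
posterior territories, in-tube Poiseuille advection, and the particle force
balance. This document records the model, its assumptions, the main tunable
parameters, the numerical choices, and what the package's passing tests do
and do not demonstrate about real cerebral hemodynamics.

# The synthetic vasculature

The default network is an idealized tube model laid out in a right-handed
frame (+x right, +y anterior, +z superior, coordinates in mm): three feeding
arteries ascend from below (the internal carotids and the basilar artery, as
in anatomy), join a complete communicating ring, and fan out into 21 named
terminal outlets (six right-MCA, four left-MCA, six ACA, two basilar-branch,
three PCA). Two asymmetries of a typical subject are built in deliberately,
because embolus routing is known to be sensitive to exactly these features:

* the right ICA is slightly larger than the left (4.0 vs 3.8 mm diameter),
  and the right MCA tree carries six outlets against the left's four;
* the left carotid terminus is a T-shaped junction (the MCA leaves at a right
  angle) while the right is Y-shaped — the morphological contrast that makes
  particle distributions side-dependent.

Trunk diameters lie in the anatomical 1–4 mm range. One default deviates
from the "typical textbook" value on purpose: the basilar artery is 2.6 mm
rather than ~3 mm. With the common 0.2 m/s velocity imposed on every inlet,
inflow shares scale with the square of the inlet radius; a 3 mm basilar
would carry ~23 % of the total inflow, more than the 20 % posterior outflow
of the physiological 20:60:20 calibration target, and the communicating
arteries would then have to drain basilar blood *forward* into the carotid
circulation. Clinical flow measurements (and the routing of basilar emboli)
indicate the opposite: the carotids top up the posterior circulation through
the posterior communicating arteries. A 2.6 mm basilar puts its inflow share
at ~18 % and recovers the correct communicating-flow direction.

Vessel lengths and branch angles are plausible rather than measured — no
absolute lengths are published for the geometry this network emulates — and
the number of branch generations is mirrored only through the outlet list.
Anatomical variants remove one communicating segment each (`no_L_PCoA`,
`no_R_ACoA`). The anterior communicating segment is modelled on the right
side of the midline ACA confluence (the left A1 reaches the confluence
directly), so removing it cuts the right carotid's access to the ACA
territory; the right A1 then ends in a capped blind stub, which the network
validator accepts as the physical remnant of an absent vessel (it carries
exactly zero flow in the resistance solve).

# Flow solution

Each segment contributes a Hagen–Poiseuille resistance
$R = 8\mu L/(\pi r^4)$ with $L$ its centerline polyline length. Nodal flow
conservation gives a linear system in the nodal pressures, solved densely
(the default network has 41 nodes). Inlet velocity boundary conditions are
converted to fixed volumetric inflows $Q = v\,\pi r^2$ — the ten-diameter
inlet extensions justify treating the inflow as developed. Outlets are held
at 0 Pa; in the fixed-flow mode every outlet but one is prescribed a
volumetric outflow and the remaining outlet (first left-MCA branch by
default) closes the system as the pressure reference. Because this study
design prescribes only territory-level ratios, the per-outlet prescriptions
are built by rescaling the pressure-mode per-outlet splits to the exact
territory targets.

Terminal-branch radii carry the calibration burden: a fixed-point iteration
rescales each territory's terminal radii by $(target/achieved)^{1/4}$
(clamped per iteration) until the solved outflow split matches
ACA:MCA:posterior = 20:60:20 within 1 percentage point; trunk vessels are
never rescaled. On the default network this converges in a handful of
iterations and lands at 19.0 : 60.7 : 20.3.

## Velocity reconstruction

Inside a tube the axial Poiseuille profile
$u(s) = 2\bar u\,(1 - (s/r)^2)$ is used, oriented by the sign of the solved
flow, with no slip at the wall; where several tubes overlap the profiles are
blended with inverse-distance-to-axis weights $w_i \propto 1/(\varepsilon +
d_i)$, $\varepsilon = 0.01$ mm. The pressure gradient is uniform per segment
($\Delta P/L$, pointing so pressure falls downstream) and blended the same
way. The blended field is not divergence-free; the error is confined to
junction neighbourhoods of a few millimetres.

## The junction model

The junction treatment deserves its own section because naive choices fail
in instructive ways. A tube network metric that clamps the
distance-to-centerline at segment ends leaves, just beyond a parent vessel's
end plane, a pocket in which the blended velocity is nearly zero (every
profile factor vanishes there and nothing points sideways). Point particles
with any inertia coast straight into that pocket and stall; in early builds
of this package essentially every core-released particle was lost at the
first bifurcation. Simple remedies — a uniform carrier velocity along the
mean outflow direction, or a dipole interpolation between "toward the node"
and "out of the node" — trade the stagnation pocket for wall-pressing limit
cycles or a stagnation shell in which elastic particles orbit indefinitely.

The model that works, and that the package uses, treats every junction node
as a small **mixing sphere** (radius 1.05 × the largest attached lumen
radius) that is itself part of the lumen:

* tubes are capped by planes at their ends, so the parent's end plane plays
  the role of the bifurcation apex (carina) wall, with an axial collision
  normal;
* inside the sphere, the velocity superposes one **port** per attached
  vessel, placed where the vessel axis crosses the sphere: an inflow port
  contributes a directed, softened jet along the vessel's flow direction,
  an outflow port a softened converging sink, each with strength equal to
  the solved signed segment flow (net zero by conservation) and a softened
  $1/d$ influence law (softening length 0.3 × sphere radius);
* the sphere admits the particle *centre* anywhere within its full radius,
  while the attached tubes' wall-contact surfaces shrink with the particle
  radius (next section), so large particles keep a connected path through
  the bifurcation wedge.

The $1/d$ (channel-like) rather than $1/d^2$ (free-space) decay is
deliberate: it keeps the junction transit speed above the gravitational
settling speed of the heaviest study particles (~0.02 m/s for 800 µm,
1300 kg/m³) everywhere in the sphere, so dense emboli cross low-flow
posterior junctions instead of sedimenting at the sphere's bottom. Port
fields of this kind have no stable interior stagnation points, so particles
entering a junction are always handed from the inflow vessel to an outflow
vessel, with the capped tube profiles taking over beyond the ports.

# Particle dynamics

Each embolus is a rigid sphere of diameter $\phi$ and density $\rho_p$
obeying

$$m_p \frac{dU_p}{dt} = F_D + F_B + F_P + F_{AM},$$

* **Drag** $F_D = \tfrac12 C_D \rho_F A_P |U_s| U_s$ with slip
  $U_s = U_F - U_p$ and the capped Schiller–Naumann coefficient
  $C_D = \max\{(24/Re_s)(1 + 0.15\,Re_s^{0.687}),\ 0.44\}$. Below the cap
  the force is evaluated in the factorized form
  $3\pi\mu\phi\,(1 + 0.15 Re_s^{0.687})\,U_s$, regular as $U_s \to 0$. A
  `literal` cap mode using 44 instead of 0.44 is retained as an alternative
  convention that appears in print; with it the coefficient never leaves the
  Stokes-like branch at the Reynolds numbers of interest.
* **Buoyancy** $F_B = (\pi/6)\phi^3(\rho_p-\rho_F)\,g$. Gravity defaults to
  $(0,0,-9.81)$ m/s² — the model's superior axis — and is fully
  configurable, including zero; no orientation is canonical for a moving
  patient.
* **Pressure-gradient force** $F_P = -(\pi/6)\phi^3\nabla p$. The sign is
  chosen so the force pushes from high to low pressure (downstream in a
  resistive tube); the opposite sign would drive particles upstream and
  break the tracer limit.
* **Virtual mass**: the $dU_p/dt$ part, $C_{VM}\rho_F(\pi/6)\phi^3$ with
  $C_{VM}=0.5$, is moved to the left-hand side (effective inertia
  $m_p + m_{VM}$); the fluid-acceleration part is estimated by finite
  differences of the sampled fluid velocity along the trajectory, clamped at
  50 m/s² per component to suppress spikes from the non-smooth junction
  blending, and reset after wall bounces.

History (Basset) and lift forces are omitted, as in the CFD force balance
this package mirrors.

## Finite particle radius at walls

A sphere's centre cannot approach the wall closer than its radius, so
collision detection uses the contact surface $r_{lumen} - \phi/2$ while the
fluid velocity is evaluated at the centre with the true lumen radius. This
is the standard discrete-phase wall treatment, and it matters: a point
particle whose centre reaches the no-slip wall samples exactly zero fluid
velocity and never leaves; a finite particle at wall contact still samples
the profile one radius off the wall (about 40 % of the mean velocity for an
800 µm embolus in a 1.1 mm-radius branch). The same offset naturally makes
near-wall-released large particles faster than small ones, one of the
qualitative signatures of the study design this package reproduces.

## Collisions

At a wall hit the crossing is bisected to the boundary, the normal is
classified (lateral tube wall → radial; tube end plane → axial "apex"
normal; mixing-sphere surface → spherical normal), and the velocity is
reflected with perpendicular/parallel restitution coefficients
$(e_\perp, e_\parallel)$: $v_n \leftarrow -e_\perp v_n$,
$v_t \leftarrow e_\parallel v_t$. The defaults $(1,1)$ give ideal elastic
collisions (speed conserved to machine precision); $(0,0)$ deposits the
particle. Restitution is applied per component, so kinetic energy scales by
exactly $e^2$ when both coefficients are equal.

## Time integration

The outer step is 0.01 s (also the trajectory sampling and release cadence)
over a 5 s horizon. Within an outer step the integrator subdivides:

* the drag term is integrated **exactly** per substep (exponential
  integrator with frozen coefficients), which is unconditionally stable for
  relaxation times $\tau_p = \rho_p\phi^2/(18\mu)$ far below the step
  (0.7 ms for a 200 µm embolus);
* the substep is $\min(\Delta t, \max(0.1\,\tau_p, \Delta t/100))$. The
  $0.1\tau_p$ rule is the classical stability bound for explicit drag and is
  kept where it is coarser than $\Delta t/100$; the floor reflects that with
  exact drag integration the substep only needs to resolve *field variation
  along the path*, not $\tau_p$ — without it a 10 µm tracer would demand
  ~10⁷ substeps for no accuracy gain;
* a displacement guard limits each substep to half the local lumen radius
  (with adaptive halving), which both bounds the field-variation error and
  prevents wall tunnelling.

Releases follow the two-phase protocol of the study design: during the
release window (default 100 outer steps) the core protocol injects one
particle per inlet per step at the inlet-plane centre (3/step; ~300 total)
and the near-wall protocol six per step at radial fraction 0.9 (three sites
in the left ICA, two in the right, one in the basilar); afterwards the
particles are only tracked. Injection is at 0.2 m/s along the inlet tangent.
A seeded Gaussian jitter (σ = 5 % of the inlet radius) perturbs each release
position: it stands in for the trajectory spread that particle–particle
interaction produces in a fully coupled simulation, and it is the only
stochastic element in the pipeline — everything else is deterministic, and
identical configurations and seeds reproduce outputs byte for byte.

# Outcome statistics

Exit distributions are percentages over *exited* particles; trapped
particles (still airborne at 5 s) and deposited ones are counted separately
and excluded from the 100 % base, matching the convention of ignoring
recirculation-trapped particles. Histograms of average travel speed
(path length / residence time; default bin 0.025 m/s) and residence time
(default bin 0.1 s) use half-open bins with an upper-inclusive last bin; the
bin widths resolve the 0.05 m/s peak spacing that separates the density
groups in the study this mirrors. Tortuosity is
$100\,(\text{path} - \text{route})/\text{route}$ against the shortest
centerline route from release inlet to exit outlet; small negative values
occur (particles cut bend corners inside the lumen) and are reported as
computed.

# Parameters at a glance

| Parameter | Default | Units | Notes |
|---|---|---|---|
| blood density / viscosity | 1056 / 3.2e-3 | kg/m³, Pa·s | Newtonian, incompressible |
| inlet velocity | 0.2 | m/s | every inlet; `Q = v π r²` |
| outlet pressure | 0 | Pa | all exit planes (pressure mode) |
| calibration target | 20:60:20 | % | ACA : MCA : posterior, tol 1 point |
| outer step / horizon | 0.01 / 5 | s | sampling and release cadence |
| particle diameters | 200, 500, 800 | µm | case letters A/B/C |
| particle densities | 800, 1050, 1300 | kg/m³ | case digits 1/2/3 |
| gravity | (0, 0, −9.81) | m/s² | configurable, incl. zero |
| restitution (e⊥, e∥) | (1, 1) | — | 0 deposits |
| virtual-mass coefficient | 0.5 | — | sphere |
| drag cap | 0.44 | — | `literal` mode: 44 |
| release jitter σ | 0.05 | inlet radii | seeded |
| junction sphere radius | 1.05 × max r | — | port softening 0.3 R |

# What the synthetic data do and do not emulate

The generator reproduces the *structural* determinants of embolus routing:
three-inlet topology, a complete (or variant) communicating ring, territory
flow division, left/right asymmetry, T- versus Y-shaped carotid termini, and
ascending feeders. It does not emulate: real vessel curvature and surface
irregularity, secondary (Dean) flows and flow separation at bends, pulsatility
(the boundary conditions are steady by design), non-Newtonian rheology,
two-way momentum coupling, or particle–particle collisions. Consequently,
passing tests demonstrate internal correctness of the force model,
conservation, calibration and statistics, and the robust qualitative
findings (flow-disproportionate MCA preference, strict posterior routing of
basilar emboli, slower near-wall transport); they do not certify
patient-specific percentages, which depend on geometry this model does not
possess.

# Numerical choices and degenerate inputs

* Flow solve: dense LU on ~41 unknowns; junction imbalance is checked to
  1e-10 of total inflow. A disconnected network is rejected with a
  diagnostic naming the island.
* Calibration: per-iteration radius factors clamped to [0.6, 1.6], radii to
  [0.2, 2.5] mm; non-convergence raises a condition carrying the last
  achieved fractions. A target territory without terminal outlets is
  rejected up front.
* `locate`/field queries: nearest axis wins in junction overlaps; points
  beyond every tube and sphere are `outside`, and field evaluation there is
  an error so callers must handle wall logic first.
* Zero slip, zero flow segments, zero-length displacement steps and
  neutrally buoyant particles are all exact fixed points of the integrator
  rather than special cases.
* Exit detection uses a short collar (2 radii) beyond each terminal end
  plane, which a displacement-guarded substep cannot jump over.
* Non-finite particle states abort tracking with a particle diagnostic
  rather than propagating NaNs into the statistics.

# Known limitations

* The principal fidelity gap is the flow field itself: resistance-network
  Poiseuille tubes plus heuristic junction spheres, not Navier–Stokes. The
  junction field is not divergence-free and its port law (softened 1/d) is a
  modelling choice, though a consequential one (see above).
* Density separation of mean travel speeds is weaker than in
  patient-specific geometry. For 800 µm particles the densest case (C3) is
  reliably the slowest, but the buoyant case (C1) gains on the ascending
  feeders roughly what it loses drifting onto the upper walls of the lateral
  MCA runs, so its margin over the near-neutral C2 is at the noise level of
  a 300-particle release rather than the clear 0.05 m/s histogram-peak
  separation reported for a real network. The corresponding acceptance test
  asserts the full strict ordering and is expected to fail on the C1–C2
  pair; this is recorded here deliberately rather than papered over with a
  tuned geometry or seed.
* Trapped particles are excluded from exit statistics; with elastic walls
  and the default horizon the default network traps few or none, but heavy,
  slow near-wall releases can leave a few percent unresolved at 5 s.
* Problem sizes used by the test-suite: releases of 30–300 particles per
  case, the full 18-cell matrix at ~50 particles per cell, and 5 s horizons;
  these are the package's standard desk-scale settings and complete in
  seconds to a few minutes.
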