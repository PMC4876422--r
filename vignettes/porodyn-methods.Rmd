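---
title: "porodyn: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porodyn: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porodyn)
```

## The physical model

During an electroporation pulse train, the measured current between two
needle electrodes in tissue is far from Ohmic: it jumps to a large
fraction of its final amplitude at the pulse rise, keeps rising within the
pulse, grows across successive pulses on two distinct time scales, relaxes
between widely spaced pulses, and shows capacitor-like charge/discharge
spikes at pulse edges. `porodyn` models this with a quasi-static
conduction problem whose conductivity carries memory.

At every instant the electric potential $u$ satisfies a charge
conservation equation with a capacitive source/sink term,

$$\nabla\cdot\big(\sigma\,\nabla u\big) \;=\; \nabla\cdot \mathbf{j}_C ,$$

with the applied voltage as a Dirichlet condition on one electrode
surface, $0$ V on the other, and zero normal current density on the outer
boundary. Time enters only through state variables: the quasi-static
assumption is that charge redistribution within the conductive tissue is
fast compared with every resolved time scale, while the slower membrane
charging is represented by the explicit capacitive term rather than a
transient PDE.

### Dynamic conductivity

Conductivity per element is a product of three factors driven by three
subsidiary variables,

$$\sigma = \big[\sigma_0 + (\sigma_{MAX}-\sigma_0)\,p\big]\,
  \big[1 + A_{pg}\,(1-e^{-d_p/\tau_{pg}})\big]\,
  \big[1 + A_{T}\,(1-e^{-d_T/\tau_{T}})\big],$$

* the **level of poration** $p \in [0,1]$ tracks the field-determined
  target $p_T = \mathrm{clamp}\!\big((E - E_{min})/(E_{max}-E_{min}),
  0, 1\big)$ *instantly* when the target rises (pore creation is fast
  relative to any resolved step) and relaxes exponentially toward it with
  $\tau_{relax}$ when the target falls (pore resealing). Field values
  exactly at $E_{min}$/$E_{max}$ map to 0/1 inclusively;
* the **poration damage** $d_p$ and **thermal damage** $d_T$ indicators
  grow as $\alpha\,E\,\Delta t$ while a pulse is applied and decay
  exponentially between pulses. They saturate the two enhancement factors,
  which reproduce, respectively, the current rise within the first pulse
  and the slower rising envelope across a pulse train (attributed to
  Joule heating). $d_p$ decays with $\tau_{relax}$ — the only
  poration-relaxation time in the parameter set — and $d_T$ with the
  thermal diffusion time $\tau_T$.

This composition guarantees $\sigma(0,0,0) = \sigma_0$, monotonicity in
each argument, and the upper bound
$\sigma_{MAX}(1+A_{pg})(1+A_{T})$. The displayed form is this package's
canonical transcription of the constitutive idea (linear poration part,
two saturating multiplicative enhancements); the damage indicators carry
units of seconds.

### Capacitive current density

Membrane and electrode-interface capacitance is lumped into a per-element
first-order RC filter on the local (element-mean) potential $u_e$ with
memory $m_e$:

$$f = e^{-\Delta t/RC},\qquad
  m_e' = u_e + (m_e - u_e)f,\qquad
  |\mathbf{j}_C| = \frac{A_C\,|u_e - m_e|\,f}{R},$$

directed along the local field with the sign of $u_e - m_e$. A potential
step $\Delta U$ therefore produces a spike of initial magnitude
$A_C\,\Delta U/R$ decaying with the time constant $RC = 1.8\ \mu s$, and
the density vanishes when the potential has been constant for
$t \gg RC$. Driving the filter with the local potential (rather than the
local field rate or an electrode-interface potential, neither of which is
uniquely determined by the lumped constants) is a design choice; it is
dimensionally consistent, since $A_C\,[\mathrm{m^{-2}}]\times V/\Omega =
\mathrm{A/m^2}$.

### Parameters

The defaults of `tissue_parameters()` are the fitted beef-liver values:

| symbol | meaning | default |
|---|---|---|
| $\sigma_0$ | virgin conductivity | 0.065 S/m |
| $\sigma_{MAX}$ | fully porated conductivity | 0.1483 (range 0.125–0.1675) S/m |
| $E_{min}$, $E_{max}$ | poration ramp limits | 20 000, 40 000 V/m |
| $\tau_{relax}$ | poration relaxation | 100 µs |
| $A_{pg}$, $\tau_{pg}$ | pore-growth amplitude / saturation | 0.35, 15 µs |
| $A_T$, $\tau_T$ | thermal amplitude / diffusion time | 0.125, 1.75 s |
| $\alpha_p$, $\alpha_T$ | damage accumulation rates | 0.0015, 25.0 m/V |
| $A_C$, $R$, $C$ | capacitive amplitude, resistance, capacitance | 0.0005 m⁻², 15 Ω, 0.12 µF |
| $\Delta t$ | adaptive step bounds | 2 µs – 0.99 s |

Two consequences of these magnitudes are worth noting rather than
"fixing". First, with $\alpha_T = 25$ m/V and $\tau_T = 1.75$ s the
thermal factor saturates essentially within the first pulse at
supra-poration fields ($d_T \approx 2.5\,\tau_T$ after a single 2 µs step
at 50 kV/m); the same holds for the pore-growth factor at plateau fields.
The printed constants are transcribed as-is and the saturating forms
retained, because the decay *between* pulses — which controls whether a
train's envelope rises or repeats — still operates on the stated time
scales. Second, with $A_C = 5\times10^{-4}\,\mathrm{m^{-2}}$ the
capacitive density is roughly five orders of magnitude smaller than the
conductive density at plateau fields, so edge spikes are present in the
capacitive channel (and verified there) but are invisible in the total
simulated current.

## Discretisation and solver

**Elements.** Linear (P1) tetrahedra, matching the element-wise constant
field, conductivity and state maps the model manipulates. The capacitive
source is assembled element-wise as
$f_i = \sum_e V_e\, \mathbf{j}_{C,e}\cdot\nabla\phi_i$.

**Newton iteration.** Each time step solves the nonlinear system with a
damped Newton method: analytic $d\sigma/dE$ through all three state
channels (the ramp's clamp points use one-sided zero derivatives),
rank-one element Jacobian blocks
$\big(K^0_e u_e\big)\big(\tfrac{d\sigma}{dE}\tfrac{1}{E}\,G_e^T G_e
u_e\big)^T$, and a backtracking line search (halving down to $1/64$),
which is needed because the clamped ramp and the steep pore-growth slope
can make the full step overshoot. Conductivity is re-evaluated from the
current-iterate field in *every* iteration; the subsidiary variables are
committed from the converged field without an outer loop of their own,
since their updates depend explicitly on $E$. Convergence is declared at
a relative residual of $10^{-9}$, measured against the norm of the
Dirichlet boundary load (a scale that stays meaningful when the applied
voltage is zero and only the capacitive source drives the system). The
linearised systems use a sparse direct factorisation.

**Capacitive term in the iteration.** The density's magnitude is
refreshed from the current-iterate element potential (Picard; its
Jacobian contribution is ~1e-5 of the conductive one), while its
*direction* is frozen at the previous committed step's total-current
direction. The direction freeze matters at pulse-fall steps, where the
in-iterate field is near zero and its direction would chatter while the
capacitive source is the dominant term at that scale.

**Adaptive time stepping.** The schedule hits every pulse rise/fall edge
exactly, keeps $\Delta t_{min} = 2\ \mu s$ steps inside a 10 µs window
after each edge (where the RC term varies), and grows steps geometrically
(factor 2) elsewhere, capped at $\Delta t_{max} = 0.99$ s and truncated to
land on the next edge; trailing slivers below $\Delta t_{min}$ are merged
into the preceding step. For the eight-pulse, 1 Hz, 1000 µs train
(7.001 s span) this yields 281 steps — the same order as the
~190-step reference schedule, and vastly fewer than the $3.5\times10^6$
constant-$\Delta t_{min}$ steps. The committed window/growth-factor
schedule is one concrete choice among many; the reference step count is
treated as an order-of-magnitude anchor, not a target.

**Electrode current.** The reported simulated current is the surface sum
$I_S = \sum_i A_i\,|\mathbf{j}_{tot,i}|$ over the tagged electrode
triangles, with the total density taken from the adjacent element. Two
further estimators are exposed: the signed outward normal flux, and the
Dirichlet-reaction current (the sum of the unconstrained-equation
residuals over the electrode's nodes), which is discretely conservative —
reactions over the two electrodes balance to solver precision and are used
for the conservation checks.

## Geometry and meshing

The built-in two-needle geometry is a 60 mm cube of tissue (the sample
dimensions are a configurable package choice; they are not part of the
reference description) with two parallel needles 10 mm apart, inserted
from the top face, insulated except over an exposed 10 mm segment ending
in a flat tip. Meshing uses a graded rectilinear grid split uniformly into
six tetrahedra per cell (a Kuhn split, conforming across faces), with
cells near the electrodes at the target edge length and geometric
coarsening outwards.

Needles are represented as *square-section* bores with side
$s = \pi d/4$ — perimeter-matched to the 1.2 mm cylinder — so the tagged
lateral electrode area equals the cylinder area $\pi d L$ exactly; the
flat exposed tip face is also bare metal and is included in the electrode
tag (+2.4 % area, within the 5 % area contract). The insulated shaft
above the exposed segment is tagged as outer (zero-flux) boundary.

Generic tetrahedral meshes are imported from Gmsh MSH files (ASCII 2.2
and 4.1) via the physical surface groups `electrode_a`, `electrode_b`,
`outer`; inverted elements are re-oriented on load, zero-volume elements
are an error naming the element index. Field snapshots export to legacy
VTK.

At the deliberately coarse resolutions used throughout the tests
(~3,000–4,000 tetrahedra, bore-adjacent cells ~1 mm against far-field
cells ~15 mm), the absolute needle current is mesh-limited: successive
refinements still change it by more than a few percent because of the
field concentration at the bore edges. The refinement harness
(`mesh_convergence_study()`) demonstrates convergence exactly on the
plate geometry, where the uniform field is representable at any
resolution; quantitative needle-current studies should use finer meshes
than the test defaults.

## Verification strategy

The finite-element path is checked against an independent 1-D oracle
(`plate_oracle()`): a parallel-plate configuration in which the field is
known in closed form ($E = U/\mathrm{gap}$) and only the constitutive
updates are exercised. On box meshes the P1 solution reproduces the
uniform field exactly, so FEM and oracle agree to solver precision; the
closed forms $\sigma_0 E A$ (virgin) and $\sigma_{MAX} E A$ (saturated
poration, damage terms off) anchor the absolute scale. Model-level
invariants — $p$ confined to $[0,1]$ under arbitrary histories,
conductivity bounds and monotonicity, return to the virgin state within
$10^{-3}$ after a field-free rest of ten times the longest time constant,
and the RC decay constant of the capacitive step response — are tested by
property-style loops under fixed seeds.

## Trace processing and calibration

Measured (or synthetic) voltage/current traces are down-sampled by
averaging consecutive groups of 1000 samples — in both time and value,
with a trailing partial group averaged as well — and the five replicates
of a sequence are aligned by linear interpolation onto the first
replicate's grid restricted to the common span, then averaged pointwise
(the pointwise standard deviation is kept alongside). Interpolation
alignment and group-mean timestamps are package choices where the
acquisition description is silent.

Calibration reproduces the two-run protocol: **Run1** fits
$\sigma_{MAX}$ per sequence by bounded scalar minimisation
(`stats::optimize`, Brent-type, tolerance $10^{-4}$ S/m — a deliberate
one-parameter method choice, as the objective is smooth and unimodal in
practice) of the mean absolute deviation between measured and simulated
current at all simulated time points; **Run2** re-evaluates every
sequence with the single shared value (the Run1 mean) and no
optimisation. "Average difference" is implemented as the mean *absolute*
difference: a signed mean would vanish under oscillating error and could
not serve as a fit-quality measure. The normalising $I_{MAX}$ is the
maximum *measured* current over the compared span.

## The synthetic-data generator

`generate_experiment()` stands in for the oscilloscope acquisitions: per
replicate, a trapezoidal voltage train (2 µs linear ramps — equal to the
minimum time step; an idealised instantaneous edge would produce an
excessive capacitive response) scaled by a seeded plateau-amplitude
factor (0.5 % spread, keeping applied voltages within ~1 % of one
another), a current response simulated with ground-truth parameters on
the chosen mesh, dense resampling at the oscilloscope interval (default:
span/5×10⁵, so group-of-1000 down-sampling is meaningful), and i.i.d.
additive Gaussian noise of 1 % of the maximum current per sample.
Optional per-replicate perturbation of $\sigma_0$ (off by default)
emulates tissue heterogeneity. Identical seeds regenerate identical
traces.

What passing recovery tests show — and what they do not: the generator
produces data from the *same* model family that the calibration fits, so
parameter recovery demonstrates the correctness and conditioning of the
inverse machinery, not the model's adequacy for real tissue. Real
measurements add structured disturbances (electrode placement variation,
tissue heterogeneity, probe bandwidth, non-Gaussian artefacts) that the
generator deliberately omits.

## Problem sizes used in the tests

The shipped test-suite and acceptance script use a ~3,300-tetrahedron
two-needle mesh, 48–384-element box meshes for oracle equivalence and
calibration studies, single-pulse drives for recovery (five seeds, five
replicates, 1 % noise), and 50,000-sample synthetic acquisitions. These
sizes are the package's chosen desk-scale defaults; all of them are
parameters the user can raise.

## Known limitations

* The constitutive law is empirical: its terms mirror observed current
  features and carry no mechanistic pore-scale model; transfer to other
  tissues or electrode geometries requires recalibration.
* Thermal effects enter only through the indicator variable $d_T$; no
  bioheat/temperature equation is solved.
* Conductivity is scalar (isotropic); anisotropic tissues are out of
  scope.
* The electrode–electrolyte double layer is not modelled separately; it
  is absorbed into the single lumped RC term.
* With the default capacitive amplitude, edge spikes are negligible in
  the total current (see above); studies of the spikes themselves should
  examine the capacitive channel directly.
* Coarse default meshes under-resolve the bore-edge field concentration;
  absolute currents at the test resolutions are mesh-limited.
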