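---
title: "Modelling a magnetofluidic capacitive sweat sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a magnetofluidic capacitive sweat sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`magsense` is a desk-scale, semi-analytical model of a wearable microfluidic
immunosensor: planar spiral microcoils pull antibody-functionalized magnetic
nanoparticles (MNPs) out of a sweat stream, and a parallel-plate capacitor
reads out how much of the detection zone the trapped particles occupy.  This
vignette explains the three physical stages, the assumptions behind each
reduction, the numerical choices, and what the model can and cannot say.

## 1. Coil magnetostatics

Every material in the device — copper, PDMS, sweat, and a dilute MNP
suspension — has relative permeability ≈ 1, so the magnetic source problem
decouples from the particles (one-way coupling) and Maxwell's equations
reduce to magnetostatics in free space.  Each spiral turn is modelled as a
concentric circular filament; the field of a circular loop has an exact
solution in complete elliptic integrals, and the coil field is the linear
superposition over filaments.  `B = μ0 H` everywhere outside the wires.

Geometry convention: `z = 0` on the top surface of the wires (so filament
centerlines sit at `z = −h/2`), the channel floor at `z = K_coil`, the flow
axis along `x` over the coil center, `y` lateral.  SI units everywhere
internally; config files use µm / mA / µL·min⁻¹ for readability.

Four reference layouts (R500–R2000, outer radii 500–2000 µm) share
10 × 10 µm copper wires at 10 µm spacing (20 µm pitch).  Only the largest
coil's turn count is part of the published design (97); the other counts
follow from fixing the innermost filament radius at 75 µm — the value the
97-turn layout implies — and filling outward: 22, 47, 72 turns.  This is a
declared convention, not a recovered fact.

Two refinements matter near the wires:

* **Cross-section quadrature.**  A single centerline filament per turn is
  accurate beyond a few pitches but cannot resolve the near-field *ripple*
  (the flux-density oscillation at the wire pitch).  With
  `quadrature = TRUE` each wire is represented by a 3 × 3 midpoint grid of
  sub-filaments carrying `I/9` each.  The ripple metric is the peak-to-peak
  amplitude of the profile about a one-pitch moving-average baseline,
  relative to the mean; it decays monotonically with height, which is the
  physical reason a ~30 µm coil–channel separation is a good working point.
* **Gradient of `|H|²`.**  The magnetophoretic force needs `∇|H|²`.  It is
  computed by central differences with a 1 µm step (and checked against a
  finer/coarser Richardson pair in the tests) rather than by symbolic
  differentiation — simple, and verified against the elliptic-integral
  oracle to better than one part in 10³.

The coil figure of merit is `Mp = Bmax / P` with `P = I²R` and
`R = Σ 2πr_k/(σwh)`.  `Bmax` is evaluated on the channel-floor plane
`z = K_coil`, because that is the field actually available to the fluidic
domain; with `B ∝ I` and `P ∝ I²`, `Mp ∝ 1/I` exactly in this model, so
small coils and low currents win on efficiency while large coils win on
absolute field strength.

## 2. Channel flow

At the device scale (hydraulic diameter 50 µm, mean velocity 6.7 mm/s,
Re ≈ 0.33) the Navier–Stokes equations reduce to steady, fully developed,
unidirectional Poiseuille flow.  The velocity field is the classical
Fourier-series solution of the rectangular-duct Poisson problem, truncated
at 51 odd terms (truncation error ~ `1/n³`; the series is evaluated with an
overflow-safe `cosh` ratio) and scaled so the integrated flux equals the
prescribed flow rate exactly.  The magnetic body force on the (non-magnetic)
fluid and the particle back-reaction are both zero in this one-way-coupled
model.  Tests verify no-slip walls, flux conservation to 0.1%, the
square-duct peak-to-mean ratio 2.096, and agreement with an independent
201 × 201 finite-difference Poisson solve to < 0.5%.

## 3. Particle transport

An MNP of diameter `D` in field gradient `∇|H|²` feels the dipole
(magnetophoretic) force

```
Fmap = ¼ π μr μ0 D³ · (μr,p − μr)/(μr,p + 2 μr) · ∇|H|²
```

and Stokes drag `FD = 6πηr (u − vp)`.  The Clausius–Mossotti contrast
factor saturates near 1 for magnetite (`μr,p ≈ 5000`).  The momentum
relaxation time `m/(6πηr) ≈ 7 × 10⁻¹⁰ s` is ten orders below the transport
timescales (Stokes number ≪ 1), so the inertial equation is reduced to its
overdamped limit `vp = u + Fmap/(6πηr)` — the magnetophoretic slip scales
as `D²` (force `D³` over drag `D`).  A full inertial integrator (via
`deSolve`) is retained solely as a cross-check oracle; the test suite shows
the two trajectories agree to well under one particle diameter.

**Ensemble simulation.**  Particles are injected continuously over the
first 10 s, inlet positions sampled flux-weighted across the cross-section
(matching steady perfusion and making "steady state" well defined), and
advected by an adaptive Cash–Karp Runge–Kutta integrator with a ~1 µm
displacement cap per step.  For speed, the integrator samples a
precomputed field table — `|H|²` and its central-difference gradient on a
1 µm `(ρ, z)` grid (the spiral field is axisymmetric), and the duct
velocity on a 1 µm `(y, z)` grid — with bilinear interpolation; the tests
show the tabulated gradient matches direct evaluation to < 10⁻³.  A
particle is **trapped** when it comes within one radius of the channel
floor or a side wall while the wall-normal magnetophoretic component
points into the wall and its advection speed is below 1% of the mean flow;
trapped particles are frozen (no dipolar interactions, no back-reaction).
A particle leaving the domain (`|x| > 1.2 ×` outer radius) has
**escaped**.  Runs are bit-reproducible given `(config, n, seed)`.

Brownian motion is deliberately omitted: the force model contains no
stochastic term, and adding one silently would change the trapping physics.
For 50 nm particles at room temperature diffusion is in reality
non-negligible (D_B ≈ 10 µm²/s), so this is a known physical limitation,
not an oversight.

**Outcome statistics.**  Trapping efficiency is `100 · trapped/injected`
at a given time (mean ± sd across seeds).  The steady-state time is the
earliest 1 s bin after which the resolved-trapping fraction
(trapped among trapped + escaped) stays within ±2 percentage points of its
final value; these definitions are declared here because no standard ones
exist, and they are oracle-tested against analytically constructed fixture
results.

**What the model predicts at the nominal operating point.**  At 400 mA the
field over the channel floor is tens of mT, but `|H|² ≈ 10⁹ A²/m²` varying
over tens of µm gives `∇|H|² ≈ 10¹³ A²/m³`, hence a magnetophoretic slip
of only a few µm/s for a 50 nm particle — three orders below the 6.7 mm/s
mean flow.  Under these conditions the simulated 60 s trapping efficiency
is below 1%: only particles entering within ~1 µm of the floor are
captured.  This is a direct consequence of the force law above; published
finite-element studies of comparable devices report efficiencies of
60–80% at the same nominal parameters, which under this force model would
require an effective susceptibility roughly `(μr,p − 1)/3 ≈ 1.7 × 10³`
times larger (i.e. dropping the Clausius–Mossotti denominator), or
equivalently much larger/more numerous particle aggregates.  The package
reports what the stated equations give; the low-flow regime
(≲ 0.05 µL/min), larger diameters, or smaller separations show the
expected qualitative trends (efficiency increasing in `D`, decreasing in
`K_coil` beyond 30 µm, decreasing in channel width) and are used by the
test suite to exercise the trapping machinery.

## 4. Capacitive readout

The detection zone is a parallel-plate capacitor whose dielectric is a
PDMS wall / fluid channel / PDMS wall series stack:

```
Ceq = ε0 A · εw εch / (εw dch + 2 εch dw)
```

with `dch` the fluid gap (= channel width) and `dw` each wall.  The wall
thickness is not part of the published geometry; the package default is
`dw = 5 µm`, a typical thin spin-coated PDMS membrane, exposed in the
config and documented as an assumption.  With the reference geometry
(50 × 500 µm electrodes, `εch = 80`, `εw = 2.7`) the baseline is 51.1 fF.

Trapped MNPs (iron-oxide `εr` 10–40, below sweat's 80) lower the effective
permittivity.  The default occupancy geometry is the **parallel-column**
plug: the MNP-rich phase spans the full gap over a length fraction `φ` of
the electrodes, so `C(φ)` is the length-weighted parallel combination of
two stacks and is exactly affine in `φ`.  A homogeneous linear mixture and
a Maxwell–Garnett mixing rule are selectable alternatives for sensitivity
analysis.  Sensitivity is defined as `100·(C(0) − C(φ))/C(0)` — the only
definition of "relative capacitance change" consistent with the stack
model; at `εp = 10` it gives 42.7% at `φ = 0.85` and 25.1% at `φ = 0.50`,
near-linear in `φ` as the parallel-column model requires.  Electrode
material enters only as metadata: under ideal electrostatics the
conductor's identity cannot change the capacitance.

The **dynamic trace** couples the stages: trapped counts are converted to
occupancy by volume bookkeeping (each simulated particle represents
`c·Q·T_inject/n` physical MNPs at inlet concentration `c`, default
10¹⁸ m⁻³ ≈ 10¹² particles/mL, a typical assay loading; trapped MNP volume
over a 1% plug packing fraction gives the plug volume).  On coil-off the
plug is released; because a released particle sitting in the zero-velocity
wall layer would unphysically linger without Brownian re-entrainment,
washout is modelled at the occupancy level as an advective exponential
decay with time constant `zone length / mean velocity`, which returns the
trace to baseline within a few tenths of a second at nominal flow.

## 5. Scenario generation and testing strategy

The scenario module makes every stage testable without external data:
seeded flux-weighted or uniform inlet ensembles; uniformly sampled valid
device configurations inside the design ranges (current 100–700 mA,
diameter 10–60 nm, separation 5–100 µm, width 50–1000 µm); and
analytically constructed trap results (constant-rate, step, none-trapped)
whose efficiency and steady-state time are known exactly.  Generators use
R's default Mersenne-Twister stream under an explicit seed and restore the
caller's RNG state.

What the synthetic scenarios do **not** emulate: Brownian diffusion,
particle–particle dipolar chaining and aggregation, biomarker binding
kinetics, channel-entrance effects, AC/double-layer electrode physics, and
fabrication non-idealities.  Passing tests therefore demonstrate the
internal consistency of the stated model, not agreement with a physical
device.

## 6. Numerical choices and problem sizes

* Field tables and gradients: 1 µm spacing (equal to the stated
  central-difference step); ensembles interpolate bilinearly.
* Particle integrator: Cash–Karp 4(5) with relative tolerance 10⁻⁶,
  1 nm absolute displacement tolerance, steps bounded by [10⁻⁷, 0.05] s
  and a 1 µm displacement cap; trapped/escaped decided after each accepted
  step.
* Duct series: 51 odd terms; inlet rejection sampling against `u/umax`.
* Reference ensembles: 500 particles × 3 seeds per design point, 60 s
  horizon — chosen so across-seed standard errors are well below the
  percentage-point scale of the reported efficiencies; the quick
  reproduction path uses 80 × 1 for smoke testing.
* Ripple profiles: 3 × 3 sub-filament quadrature, 0.85–1 µm sampling,
  one-pitch moving-average baseline.

## 7. Known limitations

1. The trapping stage inherits the full weakness of the dipole force law
   for nanometre particles (Section 3): nominal-flow efficiencies are
   sub-1%, so quantitative trapping claims at 1 µL/min should be read as
   model outputs, not device predictions.
2. No Brownian motion, hence no diffusive capture or re-entrainment.
3. The occupancy→capacitance link depends on two calibration-like
   parameters (inlet concentration, plug packing fraction) that only the
   dynamic-trace demo uses.
4. Feed-line segments are available for field-asymmetry studies but are
   not part of the transport model (which assumes axisymmetry).
5. Electrode conductivity, fringing fields, and electrode polarization are
   outside the electrostatic model.
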