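---
title: "retortsim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retortsim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
physical model and its assumptions, the tunable parameters and their
defaults, the numerical scheme, the synthetic-data (probe) generator, and
the choices made where the design was genuinely open.

## Physical model

### Geometry and assumptions

A filled tin can is modelled as a finite cylinder, two-dimensional
axisymmetric in `(r, z)` with the axis at `r = 0` and the can bottom at
`z = 0`. The default geometry (`can_geometry()`) is a #9121 can: inner
radius 49.45 mm, inner height 121 mm, 0.2 mm wall, 5 mm vapor headspace.
The model assumes:

1. **Thermally thin wall.** The 0.2 mm metal is not meshed; the inner
   surface takes the boundary temperature directly. A Robin option
   (`wall_bc = "robin"`, `film_coefficient` in W/(m² K)) exposes an external
   film resistance for sensitivity studies; the default is Dirichlet.
2. **Stagnant headspace.** The vapor gap is a conductive layer with fixed
   properties (`headspace_vapor()`: k = 0.03 W/(m K), ρ = 0.8 kg/m³,
   C_p = 2000 J/(kg K)). Vapor motion and condensation during cooling are not
   modelled; the headspace acts purely as a thermal buffer over the product
   surface, which is treated as a rigid, no-slip lid for the liquid.
3. **Uniform initial state.** Product and headspace start at the fill
   temperature (default 341.15 K = 68 °C) at rest.
4. **Axisymmetric, single can.** The retort environment is uniform around
   the can; probe fixtures do not perturb the flow.

The mesh (`build_mesh()`) is a uniform structured grid with exact
cylindrical-shell cell volumes `π (r_{i+1}² − r_i²) Δz`; the headspace
boundary snaps to the nearest cell edge and the realized height is reported.
The default resolution is 24 × 48 (the headspace then spans two cell rows).

### Thermophysical properties

`chestnut_puree()` carries polynomial correlations **in kelvin** for density
(quadratic), apparent viscosity (quintic) and conductivity (quadratic), plus
constant specific heat 3860 J/(kg K). Kelvin is the correct argument unit: it
yields ρ ≈ 1.05–1.08 × 10³ kg/m³, k ≈ 0.57–0.61 W/(m K) and μ ≈ 30–80 Pa·s
over process temperatures, whereas evaluating the same polynomials in Celsius
gives unphysical values (a unit test pins this down). The correlations were
measured over 30–95 °C; the validity range is `[303.15, 400.15]` K with
policy `"extrapolate"` (warn), `"clamp"` and `"error"` available. Two
numerical caveats, both tested: the viscosity quintic has a shallow minimum
near 391.5 K (≈31.51 Pa·s), so it is strictly decreasing only up to
≈390 K and essentially flat above; and the same quintic cancels terms of
order 10⁶ down to ~35, so independent evaluation orders agree to ~10⁻⁹
relative, not machine precision.

The puree is treated as a **temperature-dependent Newtonian** fluid. This is
the package's most consequential simplification — see *Limitations*.

### Retort schedules

`parse_schedule()` reads the canning notation
`"d1-d2-…-dn/T1-…-T(n−2)"`: come-up of `d1` min ramping to `T1`, holds at
`T1 … T(n−2)` °C, cooling over `dn` min. Open choices, made once:

* **Come-up** is a linear ramp starting at the fill temperature (341.15 K by
  default, configurable) — retort logs rarely ship with the notation, and a
  linear ramp to the set point over the stated come-up time is the standard
  idealization. A measured log can replace the whole profile
  (`schedule_from_log()`).
* **Cooling** is a linear ramp from the last hold to the cooling-water
  temperature, default 298.15 K (25 °C).
* **Stacked holds** step at the phase boundary, smoothed over
  `transition_width` (default 1 s — one time step) to keep the boundary
  condition continuous.

### Governing equations

Energy: `ρ(T) C_p ∂T/∂t + ρ₀ C_p u·∇T = ∇·(k(T) ∇T)` over puree and
headspace (conjugate conduction; advection only in the puree). Momentum
(puree only): incompressible Stokes flow with temperature-dependent
viscosity and Boussinesq-type buoyancy — full ρ(T) in the gravity source,
constant reference density ρ₀ = ρ(T₀) in the inertia and advective mass
fluxes — together with ∇·u = 0.

Two deliberate choices:

* **Momentum self-advection is dropped.** At process conditions the Reynolds
  number is O(10⁻²) (u ~ 10⁻⁴ m/s, L ~ 0.05 m, ν ~ 0.03 m²/s): fluid inertia
  in the advective sense is two orders below the viscous term and far below
  discretization error. Energy advection — the term that matters, as the
  thermal Péclet number is O(10) — is retained with first-order upwinding.
* **The buoyancy source is the deviation of ρ(T) from its instantaneous
  puree-volume mean.** In a closed container the mean body force is
  hydrostatically balanced by pressure and drives no flow; subtracting it
  changes nothing dynamically but makes a uniform-temperature state an exact
  fixed point of the discrete update (asserted as a test) and keeps the
  pressure field free of a large hydrostatic component.

## Numerical scheme

A staggered (MAC) finite-volume grid: temperature and pressure at cell
centers, `u_r` on radial faces, `u_z` on axial faces. Each time step
(default `dt = 1` s):

1. **Momentum predictor**, implicit in the viscous terms (μ ~ 30–80 Pa·s
   makes any explicit viscous step useless: the viscous CFL number is ~10⁴).
   Variable viscosity is face/corner averaged; the axis gets zero radial
   velocity and zero shear, walls and the headspace interface are no-slip.
   Buoyancy enters the `u_z` equation explicitly.
2. **Pressure projection.** The Poisson operator over the puree block is
   assembled once, pinned at one reference cell, and factored by sparse
   Cholesky; each step costs one back-solve. The projection is exact to
   round-off — the volume-weighted RMS divergence after correction is
   ~10⁻¹⁶ s⁻¹ against a 10⁻⁶ s⁻¹ contract, checked every step.
3. **Energy**, implicit in both conduction and upwind advection, with
   harmonic-mean conductivities across faces (conjugate puree/headspace
   coupling) and half-cell conductances to the Dirichlet boundary. The
   resulting matrix is an M-matrix, so the update obeys a discrete maximum
   principle; the solver verifies the bounds (±0.5 K tolerance) after every
   step and halves `dt` for that step (recursively, up to six levels) if
   they are violated, erroring with advice if that fails.

In `mode = "conduction"` stages 1–2 are skipped and `u ≡ 0`. When every
property polynomial is constant, the conduction matrix is time-invariant and
its Cholesky factor is cached, which makes fine-grid benchmarks cheap.

Lethality is co-accumulated every step: `F += (L(Tⁿ) + L(Tⁿ⁺¹))/2 · dt/60`
per cell (minutes), with `L(T) = 10^((T−RT)/Z)`, RT = 121.1 °C, Z = 10 °C.
The cold point is the minimum-F puree cell, ties broken toward the smallest
`z` then the smallest `r` (deterministic). The overheated fraction divides
the F > 25 min cell volume by the **puree** volume — the headspace holds no
product, so it does not belong in a quality denominator. The default
commercial-sterility target (`target_F = 4.5` min) is a conventional
low-acid-food choice and is configurable.

There is no randomness anywhere in the solver; the only RNG use in the
package is the probe noise generator, which takes an explicit seed.

## Verification

* **Analytic conduction benchmark.** `analytic_cylinder_temperature()`
  implements the separable Fourier–Bessel series (J₀ radial × odd-sine
  axial product solution) for a finite cylinder with a step change of wall
  temperature. The suite requires the conduction mode on a 48 × 96 grid to
  match it within 1 % of the initial temperature difference at Fourier
  number 0.1; observed agreement is well inside that.
* **Conservation.** With all boundaries insulated and constant properties,
  the implicit finite-volume update conserves volume-integrated thermal
  energy exactly (fluxes cancel in antisymmetric pairs); the test asserts
  drift below 0.1 % over 1000 steps and in practice sees round-off.
* **Structure of the flow.** Zero gravity yields identically zero velocity;
  heating drives an up-the-wall / down-the-core circulation whose strength
  decays through the hold and reverses within minutes of cooling onset; the
  accumulated cold point sits low on the axis in convection mode and above
  the convection position in conduction mode (the insulating headspace puts
  the pure-conduction cold point just under the product surface). All are
  asserted as tests.
* **Convergence.** Conduction-mode lethality metrics change by about 1 % when
  the mesh and step are refined 2× on the full single-stage process (the test
  asserts < 5 %). Convection-mode fields converge more slowly — first-order
  upwinding trades accuracy for boundedness at Péclet ≈ 20 — so
  convection-mode lethality at the default resolution should be read as
  having roughly ten-percent-level numerical uncertainty.

## The synthetic probe generator

`synthesize_probe()` emulates a thermal-penetration validation test: a
thermocouple at a stated `(r, z)` (canonically the axis at `z = 18.8` mm,
the predicted slowest-heating height) reads the local temperature through a
first-order sensor lag `dT_m/dt = (T_true − T_m)/τ` (exact exponential
update per sampling interval, treating the truth as piecewise linear) plus
i.i.d. Gaussian noise `N(0, σ²)`. Defaults: `τ = 5` s (a sheathed
thermocouple in a viscous product), `σ = 0.25` K (consistent with a ±0.5 °C
fill-temperature reading tolerance), explicit integer seed.

What it does **not** emulate: probe-fixture flow disturbance, retort
temperature nonuniformity, drift, or condensation effects at cooling. A
passing simulate → synthesize → compare round trip therefore demonstrates
the internal consistency of the solver plus the stated sensor model — not
fidelity to any particular physical retort. `general_method_F()` applies the
classical general method (trapezoidal integration of the lethal rate) to any
probe record, and `compare_probes()` scores predicted against measured
curves (RMSE, maximum deviation, both F values) after linear resampling onto
the predicted time grid.

## Schedule evaluation and search

`evaluate_schedule()` runs the full simulation and reports
`F_min`/`F_max`, cold point, overheated fraction and feasibility against the
target. `compare_schedules()` computes the overheated-volume reduction and
flags lethality equivalence when `|ΔF_min|` is within ±10 % of the baseline
`F_min` (the equivalence band is a package choice; no standard exists).
`grid_search_schedules()` enumerates one- or two-stage candidates
exhaustively (two-stage pairs a hotter first hold with a cooler second) and
ranks feasible ones by overheated fraction, then total time, with stable
ties — exhaustive enumeration over a bounded candidate grid is preferred to
gradient or surrogate methods because single runs are cheap at coarse
resolution and reproducibility matters more than search speed here.

## Problem sizes

Default production resolution is 24 × 48 cells at `dt = 1` s — a full
two-hour process takes a few minutes on one core, with the cost dominated by
one sparse LU per implicit stage per step. The test suite uses 6–16 radial
cells and `dt` of 2–5 s for schedule sweeps and property checks, and the
48 × 96 constant-property grid (cached factorization) for the analytic
benchmark.

## Limitations

* **Rheology.** Purees are shear-thinning pastes; the model uses the
  temperature-only apparent viscosity measured in a viscometer. At in-can
  natural-convection shear rates (≪ 1 s⁻¹) the true apparent viscosity of
  such a paste is typically far higher, which would suppress convection
  toward the conduction limit. The two bracket the physics: conduction mode
  gives the slow-transport extreme, convection mode with the measured μ(T)
  the fast-transport extreme, and real cans fall between. Cold-point
  lethality and overheated volume are sensitive to this because the can
  approaches thermal saturation during a long hold; both modes are
  first-class and reported side by side where it matters.
* Headspace condensation and vapor motion at cooling are not modelled; the
  cooling-phase temperature near the lid is therefore approximate.
* First-order upwinding adds numerical diffusion of order `|u| Δx / 2`,
  a few tens of percent of the molecular diffusivity near the wall plumes at
  the default grid.
* Dirichlet wall coupling assumes a condensing-steam-grade external film;
  for water-immersion or air retorts use the Robin option.
* Single can, axisymmetric, no rotation, no particulates.
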