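---
title: "Methods: continuum modelling of exosome transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum modelling of exosome transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(exotran)
```

## The model

Exosomes are 50–150 nm extracellular vesicles. At that size, their
collective movement through interstitial fluid can be treated as a
continuum scalar field rather than as discrete particles: a
concentration $c_k(\mathbf{x},t)$ per exosome species $k$ obeying the
advection–diffusion transport equation

$$\frac{\partial c_k}{\partial t} + \frac{\partial (u_i c_k)}{\partial x_i}
  = \frac{\partial}{\partial x_i}\left(\Gamma_k
  \frac{\partial c_k}{\partial x_i}\right) + S_{c_k},
  \qquad k = 1,\dots,N,$$

where $u_i$ is the interstitial fluid velocity, $\Gamma_k$ the diffusion
coefficient and $S_{c_k}$ the source term representing release by tumor
cells. Uptake (a sink term) is deliberately not modelled, and the
concentration does not feed back on the flow: the coupling is one-way
(staggered). The velocity field is obtained first, from the
incompressible laminar momentum equations; transport is then integrated
on the frozen field.

Interstitial flow sits at Reynolds numbers around
$\rho U L/\mu \sim 10^{-5}$–$10^{-3}$ (`reynoldsNumber(fluidProps(),
0.75e-6, 1e-4)` gives $7.5\times10^{-5}$), so the package solves the
Stokes limit by default and retains the convective term behind the
`inertia` flag of `solveFlow()`, verified in the tests to be negligible
at these Reynolds numbers. Turbulence and heat transport are out of
scope; the flow is steady, incompressible and laminar.

## Discretization

**Grids.** Uniform cell-centered Cartesian grids (optionally
axisymmetric $r$–$z$ for bodies of revolution), with per-face areas and
per-cell volumes carried explicitly so both coordinate systems share one
finite-volume core. 2-D Cartesian runs carry an explicit out-of-plane
depth (default 1 m) so concentrations integrate to absolute exosome
counts; every output header records this convention.

**Geometry.** Cell obstacles (tumor, immune cells) are rasterized by a
cell-center point-in-shape test onto a solid mask (blocked-cell method;
no cut cells). Release surfaces are the faces separating fluid cells
from tumor cells; the prescribed total release rate is distributed over
those faces area-weighted and therefore sums to the prescribed rate
exactly, regardless of rasterization error. Rasterized areas converge to
shape areas at first order in the cell size, which the test suite
checks; a body-fitted mesh would converge faster but is not needed for
the directional claims made at this scale.

**Flow.** Staggered (MAC) variable arrangement: face-normal velocities,
cell-centered pressures — the standard cure for checkerboard pressure
modes. Because the Stokes system is linear, no SIMPLE-style relaxation
is used: the saddle-point system is solved exactly by conjugate
gradients on the pressure Schur complement (Uzawa), with the momentum
Laplacians Cholesky-factored once and a scaled mass-matrix
preconditioner, which keeps the iteration count mesh-independent (tens
of iterations). The inlet is a uniform velocity on the left boundary;
the outlet is a flux-matched uniform outflow profile on the right with
pressure reported relative to the outlet mean — pressure is in any case
only defined up to that reference. Lateral boundaries default to
free-slip symmetry (the physical condition is unknown at the tissue
margins; no-slip is selectable). Solid surfaces are no-slip, imposed by
mirror ghost values across the solid interface. The discrete divergence
of converged solutions is at round-off level (the acceptance suite
requires a normalized divergence below $10^{-8}$; in practice it is
$\sim10^{-15}$), and plane-Poiseuille channel flow reproduces the
centerline-to-mean ratio of 3/2 within 1 % at 64 transverse cells.

**Transport.** Conservative finite volumes. Advective face values are
reconstructed by one of four upwind-biased schemes — first-order upwind,
second-order linear upwind, QUICK (quadratic weights $3/8$ downstream,
$6/8$ upstream, $-1/8$ far-upstream) and MUSCL with a minmod-limited
slope (van Leer selectable). Minmod is the default limiter as the most
dissipative (safest) choice. Diffusive fluxes are central. Two time
integrators are available:

* `euler` (default for scenarios): explicit advection + backward-Euler
  implicit diffusion. First-order in time, unconditionally stable in
  the diffusion term — essential for the transwell case, where
  $\Gamma = 2\times10^{-3}\ \mathrm{m^2\,s^{-1}}$ over centimetres and
  72 h makes explicit diffusion hopeless (stability would demand
  $\Delta t \sim 10^{-5}$ s).
* `heun` (used by the verification benchmark): Strang splitting with
  Crank–Nicolson diffusion half-steps around a Heun (RK2) advection
  step, second-order in time so the spatial order of the face schemes is
  observable under grid refinement.

Time steps honour an advective CFL limit (default 0.5; the solver
refuses CFL > 1). Scenario runs take at least 200 steps regardless of
CFL so monitor series are well resolved. Boundary conditions per side:
`wall` (zero flux), `dirichlet` (prescribed value, applied to inflow
face values and to diffusive fluxes across the half cell), `outflow`
(zero gradient). Solid cells carry zero concentration and exchange no
flux. With implicit diffusion solved by a direct sparse factorization,
closed-domain mass conservation holds to near round-off
($\lesssim10^{-12}$ relative after hundreds of steps; the acceptance
bound is $10^{-8}$), and because the semi-discretization is linear with
zero initial condition, solutions scale exactly linearly in the source
rate — a property the scenarios exploit and the tests pin at $10^{-12}$.

## Verification benchmark

An instantaneous Gaussian source of strength $M$ released at the origin
of an unbounded planar shear flow $u = (U + \lambda y,\,0)$ has the
closed-form solution

$$c(x,y,t) = \frac{M}{4\pi D t\sqrt{1+(\lambda t)^2/12}}
 \exp\!\left\{-\frac{1}{4Dt}\Big[y^2 +
 \frac{(x-\bar x(y,t))^2}{1+(\lambda t)^2/12}\Big]\right\},
 \qquad \bar x = \Big(U + \tfrac{1}{2}\lambda y\Big)t .$$

The benchmark uses $U = 5\times10^{-6}$ m/s,
$\lambda = 5\times10^{-4}$ s$^{-1}$, $M = 1$, $D = 10^{-8}$ m²/s on a
100 × 100 mm square with the origin at the center. To keep the field
finite the solver is initialized from the exact solution at $t = 60$ s
and integrated for a further 45 min with the shear velocity imposed
analytically (it is discretely divergence-free, so the velocity
discretization contributes no error) and Dirichlet boundary values from
the exact solution — the plume is effectively zero at the walls, and
this removes boundary ambiguity from the error norms. The default grid
is 200 × 200 (0.5 mm cells), on which the plume spans well over 15
cells.

**Sign variant.** One published form of this solution centers the plume
at $\bar x = (U - \tfrac12\lambda y)t$. Only the $+$ form satisfies the
PDE $\partial_t c + (U+\lambda y)\partial_x c = D\nabla^2 c$:
`auditSignVariant()` initializes from each variant's field, evolves the
PDE numerically, and compares against the same variant at the end time.
The $+$ ("standard") variant shows the small discretization error
(L2 error ≈ 700× smaller at 200²); the $-$ variant an $O(1)$ mismatch.
The package default is pinned to the audit's winner by a test; the
printed variant remains available as `variant = "as_printed"`.

**Observed behaviour.** With the second-order integrator, L2 errors
refine at observed orders ≈ 0.92 (first-order upwind) and 1.97–2.01
(second-order upwind, QUICK, MUSCL) over 100 → 200 → 400 grids, and the
higher-order schemes keep the peak-normalized L∞ error well under 1 %
at 200² — first-order upwind, by contrast, loses ~5 % of the peak.
These are the quantities `scripts/acceptance.R` recomputes.

## Transwell scenario

A two-chamber culture well: cells seeded at the bottom release exosomes
at a measured per-cell rate; the medium is stagnant, so the velocity is
identically zero and transport is pure diffusion; the quantity of
interest is the number of exosomes that have reached the insert's porous
membrane over 72 h. Measured inputs: $3.6\times10^{6}$ seeded cells;
release rates 515.3 (no force, NF) and 986.3 (oscillatory force, OF)
exosomes per hour per $10^5$ cells; $\Gamma = 2\times10^{-3}$ m²/s. The
stated diffusion coefficient is enormous for 100 nm vesicles
(Stokes–Einstein gives $\sim4\times10^{-12}$ m²/s); it is taken as the
scenario default anyway, not silently corrected — its main consequence
is that the chamber is nearly well-mixed throughout, which the
fast-diffusion limit test exploits.

Choices the physical description leaves open, fixed as package
defaults:

* **Geometry** (not part of the measured inputs): axisymmetric $(r,z)$
  — the transwell is a body of revolution — with well radius 17.4 mm,
  insert radius 12 mm, insert wall 0.6 mm, membrane plane 1 mm above
  the bottom, 5 mm media height, on a 58 × 50 grid. Absolute membrane
  counts depend on these dimensions and are therefore reported as
  qualitative; ratios between conditions are geometry-independent.
* **Counting.** "Number of exosomes at the membrane" is implemented two
  ways: `cumulative_flux` (default) integrates the diffusive flux
  through the membrane plane over time; `region_content` integrates the
  concentration over the membrane-adjacent cell layer. The membrane
  itself is transparent (0.4 μm pores pass 50–150 nm vesicles).

Two numerical choices keep this scenario well conditioned. First,
implicit diffusion updates are applied in flux-divergence form (solve
for the new state, then update each cell with explicitly computed face
fluxes, which cancel pairwise), with an iterative-refinement pass on
the direct solve when the operator is diffusion-dominated: global
conservation then holds to round-off even though the implicit operator
has condition number ~$10^7$ here. Second, because the closed chamber
fills uniformly, the solver integrates the *deviation* from the
uniformly rising mean ($c = St/V + \delta$, with $\delta$ driven by the
zero-mean part of the source): with the scenario's huge $\Gamma$ the
physical gradients are ~$10^{-9}$ of the mean — far below double
precision on the raw field — but order one on $\delta$. Counts, means
and condition ratios are reconstructed from both parts, and the
bottom-vs-top comparison is formed at the deviation level where it is
fully resolved.

Because the problem is linear with zero initial condition, the OF/NF
membrane-count ratio equals the release-rate ratio
$986.3/515.3 = 1.9139$ exactly, at every time point and in both counting
modes — the idealized form of near-proportionality. Simulations on the
experiment-matched 3-D geometry (whose dimensions are unpublished)
have reported absolute counts whose ratio is about 1.81; the package
reproduces the exact linear value and documents the difference as
geometry- and counting-definition-dependent rather than tuning to it. The concentration field stays bottom-heavy at all
pre-equilibrium times, and the domain content equals the released total
$S\,t$ to solver precision.

## TME scenario

A 2-D tumor microenvironment: interstitial fluid enters from the left at
0.75 μm/s, flows around the tumor and immune cells, and carries exosomes
released from the tumor boundary at 2.5 (early stage) or 7.5 (late
stage) exosomes/s; concentrations are reported after 45 min. The
original study's drawn geometries are unpublished, so
`generateTmeLayout()` provides a synthetic stand-in: one central
circular tumor (radius 40 μm early, ×1.8 late, i.e. 3.24× the area)
plus non-overlapping immune cells (6 μm radius; 6 macrophages + 8
T cells by default) placed uniformly at random in a 400 × 400 μm
domain, reproducibly from a seed. Late-stage layouts keep the same
immune-cell draw so the stage comparison isolates tumor growth.
$\Gamma = 10^{-12}$ m²/s (Stokes–Einstein scale). The grid is 256².

What the synthetic layouts do and do not emulate: they reproduce the
structural features that drive the claims — a dominant central obstacle
that grows between stages, scattered small obstacles, left-to-right
interstitial drift — but not ECM heterogeneity, porous-medium effects,
cell motility or any particular drawn figure. Passing tests therefore
support the *directional* statements (larger tumor ⇒ higher interstitial
pressure; higher release ⇒ proportionally higher concentration), not
absolute concentrations in real tissue.

Transport boundary conditions: Dirichlet $c = 0$ at the inlet (clean
fluid enters) and at the outlet (exosomes leave with the flow; the
zero-Dirichlet outlet also absorbs the small diffusive flux), closed
lateral walls. The discrete release/outflow/accumulation balance closes
to $\sim10^{-13}$ relative. The stage comparison with the shipped
layouts gives a mean-concentration ratio above the 3.0× source ratio
(the larger tumor reduces the dilution volume and blocks advection),
matching the direction of the reported ≈3.5×, and a higher maximum
interstitial pressure at the late stage.

## Problem sizes and runtimes

Defaults were chosen so the full verification suite runs on a laptop
core: the 200² benchmark integrates ~320 steps per scheme; the
convergence study spans 100²–400²; the 256² TME runs take ~8000 steps
over the 45 min window. The complete acceptance recomputation
(`scripts/acceptance.R`) takes roughly 10–15 minutes on one CPU.

## Known limitations

* Blocked-cell (staircase) geometry: obstacle boundaries are first-order
  accurate; pressure drops around obstacles are qualitative.
* The interstitium is modelled as free fluid around explicit cell
  obstacles; no Darcy/Brinkman porous-medium term.
* First-order time integration in scenario runs (the benchmark uses the
  second-order integrator); monotone advection only with first-order
  upwind — the higher-order schemes can undershoot near sharp fronts
  (MUSCL limits this).
* No uptake/sink term, no mechanobiological feedback of pressure on
  release rate, no cell migration or growth dynamics: release rates are
  measured inputs and geometry is static.
* The transwell is axisymmetric; azimuthal asymmetries (e.g. tilted
  inserts) are out of scope.
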