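---
title: "Morphoelastic simulation of skin graft contraction: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic simulation of skin graft contraction: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphograft)
```

## The biological problem

After a deep burn is excised, the wound bed is usually covered with a skin
graft.  Many grafts nevertheless contract substantially over the following
months, and when part of that shrinkage becomes permanent the patient is left
with a contracture: a lasting, often disabling deformation of the grafted
area.  The cellular picture behind this is reasonably well established:
signalling molecules (TGF-β is the canonical example) present in the wound
drive the differentiation of fibroblasts into contractile myofibroblasts,
myofibroblasts pull on the collagen-rich extracellular matrix, and matrix
remodelling under sustained load converts part of the elastic deformation
into permanent shape change.  `morphograft` implements a continuum
mechano-chemical model of this process on a two-dimensional slice of dermis
and exposes the full pipeline — parameters, geometry, kinetics, mechanics,
and a positivity-preserving moving-grid finite-element engine — as testable R
functions.

## Model structure

The dermal layer is modelled as a heterogeneous, isotropic, **morphoelastic**
solid.  Morphoelasticity decomposes the deformation gradient into an elastic
part and a growth/remodelling part; permanent deformation enters through the
evolution of the *infinitesimal effective strain* ε, a local measure of the
gap between the current and the mechanically relaxed configuration
(ε = I − A⁻¹ with A the elastic part).  Four constituents are primary
variables: fibroblasts N, myofibroblasts M, a generic signalling molecule c,
and collagen ρ.  The governing system on the moving tissue is

* mass balance for each constituent z:
  Dz/Dt + z ∇·v = −∇·J_z + R_z,
* momentum balance:
  D(ρ_t v)/Dt + ρ_t v ∇·v = ∇·σ + ∇·ψ,
* effective-strain evolution (Jaumann/corotational rate):
  𝒟ε/𝒟t + [tr(ε) − 1] sym(∇v) = −G,

with v = Du/Dt the displacement velocity.

**Kinetics.**  Fibroblast division is signal-enhanced and crowding-limited
(`r_F [1 + r_F_max c/(a_c_I + c)][1 − κ_F F] N^{1+q}`, F = N + M), with
differentiation `k_F c N` into myofibroblasts and apoptosis.  Myofibroblast
division requires signal.  The signal is secreted autocrinely with a Hill
saturation and degraded proteolytically by matrix metalloproteinases (MMPs).
MMPs are not a state variable: their level is the derived quantity
`g = (N + η_II M) ρ / (1 + a_c_III c)`, secreted by (myo)fibroblasts in
proportion to the collagen present and inhibited by the signal.  Collagen is
secreted at a signal-enhanced rate and degraded by MMPs; it is immobile
(`J_ρ = 0`).  Cells disperse with density-dependent motility `−D_F F ∇z` plus
chemotaxis `χ_F z ∇c`; the signal diffuses Fickianly.

**Mechanics.**  The visco-elastic Cauchy stress is
`σ = μ₁ sym(L) + μ₂ tr(sym L) I + E(ρ)/(1+ν) [ε + ν/(1−2ν) tr(ε) I]` with
L = ∇v and a collagen-dependent stiffness `E(ρ) = E_I √ρ`.  Myofibroblasts
exert the isotropic traction `ψ = ξ M ρ/(R² + ρ²) I`, entering the momentum
balance as the body force ∇·ψ; the collagen dependence peaks at ρ = R.  The
growth tensor is `G = ζ (N + η_II M) c/(1 + a_c_III c) ε`: active strain
conversion requires signal, scales with the MMP level, and acts along the
current strain.  With ζ = 0 there is no conversion and any contraction is
ultimately reversible; with ζ > 0 strain is consumed while the graft is under
load, which is exactly what leaves a permanent contracture behind.

**Slice reduction.**  Contraction happens essentially parallel to the skin
surface, so all computations are done on an infinitely thin (Y,Z) slice:
out-of-plane displacement, velocity and the ε₁₁/ε₁₂/ε₁₃ components vanish
identically, in-plane fields have no out-of-plane derivative.  Plane
symmetric tensors are stored as (t22, t23, t33) and tr(ε) = ε₂₂ + ε₃₃.  The
computational domain is the square [−10, 10]² cm.

**Graft geometry, initial and boundary conditions.**  The graft is a square
of half-side `s1` (default 2.5 cm) rotated by `theta_r` (default π/4), with a
smooth sinusoidal blend of half-width `s2` (default 0.10 cm) between grafted
(w = 0) and unwounded (w = 1) dermis: `w = 1 − B(Y_r) B(Z_r)` with
`B(r) = [1 − I(r, s1, s2)] I(r, −s1, s2)` built from the ramp `I`.  Initially
N = {I_w + (1 − I_w) w} N̄, M = M̄, c = (1 − w) c_w, ρ = ρ̄ and
u = v = ε = 0.  On the outer boundary N, M, c are held at their unwounded
equilibrium values and v = 0 (the far field is intact dermis that does not
move).  The graft surface area is tracked through material tracer points
placed on the w = ½ level set; the shoelace area of their displaced polygon,
divided by its reference area, is the *relative surface area* readout.

## Parameters and defaults

All quantities are dimensional in cm / day / g / cells;
`default_parameters()` returns the full set and `load_parameters()` reads a
flat YAML file with the same keys.  Points worth calling out:

* **Reference scenario.**  `zeta = 9e2` cm⁶/(cells g day) and
  `a_c_III = 2e8` cm³/g are the published reference values for this scenario
  family and are the package defaults.
* **Equilibrium consistency.**  The unwounded state (N̄, M̄, c̄, ρ̄) must be a
  fixed point of the reaction system, so a few rate constants are
  consequences of the others.  `derive_equilibrium_parameters()` solves the
  steady-state equations for a caller-chosen set of up to three unknowns.
  With the default M̄ = c̄ = 0 (no myofibroblasts or free signal in intact
  dermis) the myofibroblast and signal balances vanish identically — every
  term carries a factor M or c — leaving two active constraints with the
  closed forms `delta_N = r_F (1 − κ_F N̄) N̄^q` and
  `k_rho = delta_rho ρ̄²`; those two are the default unknowns.
* **Traction calibration.**  The traction coefficient ξ is the one
  mechanical constant with no directly transferable literature value in our
  unit convention.  It was calibrated once so that the default scenario
  reproduces the clinically reported contraction magnitude of unmeshed
  grafts (minimum relative area around 0.7–0.85 within the first few
  months): ξ = 1e-2 gives a minimum near 0.72 and a permanent end-of-year
  area near 0.82 at the package's desk-scale settings.  It was not adjusted
  afterwards.
* **Tissue density.**  ρ_t = 1.02 g/cm³ (typical soft tissue).  At these
  viscosities and velocities the inertial terms are negligible; a
  `quasi_static` switch drops the advective momentum term for comparison and
  the two modes agree to solver precision.
* ν = 0.49 makes the volumetric elastic response stiff
  (near-incompressible), which is why the momentum solve treats the
  linearised elastic increment implicitly (below).

```{r}
p <- default_parameters()
max(abs(unlist(reaction_residuals(p))))  # fixed-point residual of the defaults
```

## Numerics

The engine is a pure-Lagrangian moving-grid P1 finite-element method: mesh
nodes travel with the material velocity, so the discrete advection term
vanishes and the mesh itself records the tissue deformation
(`cur = ref + u`).

* **Momentum.**  Semi-implicit: the viscous stiffness and the linearised
  elastic increment `dt (1 − tr ε) K_E(ρ)` are in the system matrix, the
  accumulated elastic stress and the traction ψ enter explicitly through
  their weak-form divergence (integration by parts; the boundary term is
  dropped where v is Dirichlet-pinned).  This keeps the near-incompressible
  elastic response stable at day-scale steps.
* **Strain.**  Nodal update of ε with the corotational evolution law; ∇v is
  obtained per element and projected to nodes with the lumped mass.
* **Dilution.**  The geometric identity Dz/Dt = −z ∇·v is realised exactly
  by rescaling nodal values with the ratio of old to new lumped masses after
  the mesh moves — discretely conservative and positivity-preserving by
  construction.
* **Transport and reactions.**  For each constituent the high-order operator
  (nonlinear diffusion plus chemotactic drift in divergence form) is made
  low-order by adding symmetric algebraic diffusion `d_ij = max(0, K_ij,
  K_ji)` that cancels every positive off-diagonal entry; with Patankar
  source splitting (production explicit, linearised loss implicit) the
  low-order update is an M-matrix solve and therefore non-negative.  The
  removed antidiffusion is then returned edge by edge through a
  Zalesak-type flux-corrected-transport limiter bounded by the local
  low-order extrema, so the corrected field is conservative and can never
  undershoot zero.  Dirichlet rows implement boundary values exactly;
  limiter fluxes touching constrained nodes are suppressed.
* **Time stepping.**  Step-doubling control: one full step is compared with
  two half steps in a scaled maximum norm over all fields; accepted steps
  take the Richardson combination 2·half − full (clipped at zero for the
  constituents, and discarded in favour of the plain half-step result if it
  would fold the moved grid), which cancels the leading first-order
  splitting error.  Rejected steps halve dt; accepted steps grow it by at
  most 1.5× up to `dt_max` (default 5 days).  The velocity is excluded from
  the error norm — it is an auxiliary of the viscous-dominated balance and
  is controlled through u and ε.
* **Mesh adaptation.**  `refine_recoarsen()` bisects flagged elements on
  their longest reference edge with Rivara compatibility propagation (no
  hanging nodes, deterministic tie-breaks by edge length then node index)
  and merges sibling pairs back to their parents when the indicator falls
  below a quarter of the refinement threshold and the midpoint node is no
  longer needed.  Midpoint values are edge means, so refinement reproduces
  the P1 field exactly and conserves every lumped-mass integral.  The
  scenario driver keeps adaptation off by default: the uniform structured
  grid is invariant under the point reflection (Y,Z) → (−Y,−Z), so the
  discrete solution inherits the symmetry of the rotated-square graft
  exactly, which longest-edge tie-breaking under refinement does not
  guarantee.  Set `refine_every` in `simulate_graft()` to switch it on.
* **Degenerate inputs.**  Saturating fractions use the continuous extension
  0/0 → 0; N^{1+q} clips FP-negative states to zero before powering
  (q may be non-integer); inverted elements abort assembly with the
  offending element id; a NaN anywhere rejects the step.

## Verification strategy

The test suite checks the engine against routes that share no code with it:

* a **stiff-ODE oracle** (`integrate_homogeneous`, built on `deSolve`)
  integrates the spatially homogeneous reduction at tolerance 1e-10; with
  uniform fields and released boundaries the engine must track it to better
  than 1e-3 in relative maximum deviation (`compare_fem_to_ode`, which uses
  a tight step tolerance of 5e-5 because the split scheme's global bias
  scales roughly linearly with the local tolerance);
* frozen-kinetics strain decay has the closed form e(t) = e₀ exp(−ζkt) with
  k = (N + η_II M) c/(1 + a_c_III c), matched to 1e-8;
* the flux limiter is compared with a brute-force search over admissible
  flux fractions on a hand-built three-node fixture;
* refinement round-trips, conservation, positivity, equilibrium
  preservation, point symmetry and determinism are asserted as invariants.

## What the scenarios emulate — and what they do not

The built-in scenario is an idealised square unmeshed graft on a homogeneous
dermal slice.  It reproduces the qualitative healing arc: myofibroblasts and
signal rise inside the graft and are then cleared, collagen overshoots its
equilibrium before relaxing, the graft contracts fast early, partially
retracts as the myofibroblasts apoptose, and — with ζ > 0 — retains a
permanent area deficit with a residual strain field.  One nuance: chemical
activity ends well before the year is out (signal and myofibroblasts are
cleared by around day 180 at the defaults), and the *area* is stationary
from then on, but the strain field itself keeps settling visco-elastically
toward its self-equilibrated residual state with a tail of a few months set
by the viscosity-to-stiffness ratio, so late strain snapshots still differ
by several percent in Frobenius norm.  With ζ = 0 the area returns to
its initial value.  Increasing either ζ or a_c_III deepens the permanent
contracture, ζ by far the more strongly.

Real grafts are meshed or fenestrated, anisotropic (collagen bundle
orientation matters), attached to subcutis in 3-D, and subject to external
splinting; none of that is modelled here.  The a_c_III trend also holds only
while the signal is cleared within the simulated horizon: for values far
above the reference (say 1e9 cm³/g) MMP secretion is suppressed so strongly
that the signal outlives the one-year window and end-time readouts are no
longer quasi-steady.  Passing tests therefore demonstrate internal
consistency of the model and solver on this idealised configuration, not
clinical predictive power.

## Problem sizes

Scenario-level tests and the acceptance script run on a 2.5 cm grid
(81 nodes, 128 triangles) to a one-year horizon with step tolerance 2e-3 —
chosen as the coarsest resolution at which the contraction/retraction arc
and all monotone trends are cleanly resolved; operator- and fixture-level
tests use single triangles or 3-node fixtures where exact values are known.
Halving the grid spacing changes the day-50 relative area of the default
scenario by less than 2% (asserted in the suite), and the ODE-oracle
comparison is grid-independent by construction (uniform fields).

## Known limitations

* Infinitesimal effective strain only; the finite-strain variant of the
  evolution law and hyperelastic constitutive relations are out of scope.
* Isotropic collagen; no fibre-orientation tensor.
* The equilibrium-consistency solver assumes the steady state is supplied;
  it does not search for multiple equilibria.
* The default unknowns of the completion step cover the M̄ = c̄ = 0 case;
  non-zero signal equilibria activate all four constraints and may need a
  third unknown.
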