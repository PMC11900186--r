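---
title: "Methods: constrained Helfrich mechanics of tubular junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained Helfrich mechanics of tubular junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`junctionmech` studies fluid membrane tubules and three-way tubular
junctions of the kind formed by retraction fibers of migrating cells and by
membrane tethers pulled from vesicles.  The membrane is a Helfrich sheet
with bending energy

$$F_B = \frac{\kappa}{2}\int J^2\, dA,$$

where $J$ is the total curvature (the sum of the two principal curvatures)
and $\kappa$ the bending modulus.  Spontaneous curvature is zero and the
Gaussian-curvature term is dropped: local bulging does not change the
topological genus, so by Gauss–Bonnet that term is an additive constant.

The system exchanges area, volume and length with a reservoir characterized
by a tension $\gamma$, a transmembrane pressure $P$ and pulling forces $f$
on the arm ends.  The three conjugate pairs $(L, f)$, $(A, \gamma)$ and
$(V, P)$ define a thermodynamic ensemble by clamping one member of each
pair; the minimized functional is

$$\bar F = F_B + \gamma A - P V - f \textstyle\sum_k L_k,$$

with each work term present only when the corresponding intensive variable
is clamped, and the clamped geometric quantities enforced as constraints.
The retrieved Lagrange multipliers of the area and volume constraints *are*
the (virtual-reservoir) tension and pressure of the altered state.

Two derived quantities organize everything: the relaxation length
$\lambda = \sqrt{\kappa/\gamma}$ and the dimensionless stress parameter
$p = P\sqrt{\kappa/\gamma^{3}}$.  For a cylinder the shape equation
$P - \gamma J + \tfrac{\kappa}{2}J^{3} = 0$ nondimensionalizes to
$p = j - j^{3}/2$ with $j = J\lambda$; its maximum
$p^{*}_{\rm cyl} = (2/3)^{3/2} \approx 0.544$ bounds the existence of
cylindrical equilibria.  The junction loses stability earlier, at
$p^{*} \approx 0.4$, which is the quantitative reason bulges nucleate
preferentially at branch points.

Internally the package works in units $\kappa = \gamma_0 = \lambda_0 = 1$;
all results are reported in these dimensionless units and can be scaled to
physical units through `material_params()`.

## Discretization

The surface is an oriented triangle mesh (`surface_mesh`).  The area is the
sum of triangle areas; the enclosed volume uses the divergence theorem with
each open boundary ring closed by a flat fan to its centroid — consistent
with the flat-ended reference cylinders used for the excess-volume
bookkeeping, and translation invariant.

The bending energy uses the star discretization of finite-element surface
evolution.  The gradient of total area with respect to a vertex equals the
integrated mean-curvature vector, so

$$J_i = \frac{|\nabla_i A|}{a_i}, \qquad
  F_B = \sum_i \frac{\kappa}{2} J_i^2\, a_i,$$

with $a_i$ the barycentric vertex area.  Its gradient is fully analytic
(per-triangle area gradients and 9×9 area Hessians) and is verified against
central finite differences in the test suite to $10^{-8}$.  The reporting
operator `mean_curvature()` uses the cotangent mean-curvature normal with
mixed Voronoi areas (falling back to barycentric areas for one-rings
dominated by obtuse triangles), which is more accurate pointwise; both
converge to the same limit under refinement.  A normal-projected variant of
the star energy is implemented in the kernel as well, but the default is
the magnitude form: combined with the boundary treatment below it
reproduces the tether relations to a fraction of a percent at the
resolutions used here.

### Boundary conditions

The tubular arms end on circular boundary rings of shared radius $R$ in
planes perpendicular to the arm axes, with the membrane tangent to the axis
there.  Both conditions are built into the parameterization rather than
penalized:

* boundary-ring vertices sit at
  $\mathbf{c}_k + d_k\,\hat{\mathbf{e}}_k + R(\cos\theta\,\hat{\mathbf u} +
  \sin\theta\,\hat{\mathbf v})$ with fixed angular positions; $R$ is a
  single shared scalar degree of freedom and $d_k$ (the arm length) is free
  exactly when the force is clamped;
* the adjacent "collar" ring is constrained to the same radius $R$ at a
  fixed axial offset behind the boundary plane, so the terminal band is a
  genuine cylinder segment (parametric tangency); collar vertices retain a
  free angular coordinate.

The curvature stars of boundary vertices are completed by *mirror ghosts*:
the band between the boundary and collar is reflected across the boundary
plane, the reflected faces enter the curvature stars (not the area or
volume), and each boundary vertex's energy is weighted by the real-membrane
share of its star area.  This is the discrete Neumann condition for
tangency.  Without it, the terminal rows pay area but no bending and the
tube ends flare or neck by several percent, which corrupts the boundary
force; with it, a clamped-tension cylinder at edge length $\lambda/4$
reproduces $R = \sqrt{\kappa/2\gamma}$ to better than $0.1\%$ and the
tether force $f = 2\pi\sqrt{2\kappa\gamma}$ to about $0.5\%$.

## Constrained minimization

`minimize_state()` minimizes $\bar F$ over the free vertex coordinates,
the collar angles, $R$ and (when free) the arm lengths, using L-BFGS-B
inner solves inside an augmented-Lagrangian outer loop on the relative
area/volume residuals.  Two ingredients matter in practice:

* **Newton projection onto the constraint manifold.**  After every inner
  solve the state is projected back onto $\{A = A_t, V = V_t\}$ by a small
  Newton iteration along the span of the constraint gradients.  This keeps
  residuals at $10^{-10}$ without driving the penalty weight (and the
  conditioning) up; penalties stay moderate and the multiplier updates
  $\mu \leftarrow \mu + \rho c$ use the pre-projection drift.
* **Multiplier initialization.**  A cold start at $\mu = 0$ lets the first
  inner solve drain area (the bending energy alone prefers less membrane),
  so multipliers are seeded from a least-squares stationarity estimate in
  the reduced coordinate space — which includes the boundary-radius
  equation, without which $(\gamma, P)$ are not identifiable on a
  near-uniform tube because the per-vertex area and volume gradients are
  parallel — or, for tubes, from the tether relation
  $\gamma \approx \kappa/2R^2$.  Continuation drivers warm-start both the
  shape and the multipliers from the previous step, with the sweep's first
  step seeded by the known initial-state values $(\gamma_0, 0)$.

Retrieved multipliers are reported from the augmented-Lagrangian estimates,
optionally refreshed by the least-squares solve when that system is
well-conditioned; `estimate_multipliers()` remains available as an
independent cross-check.
The per-arm pulling force is the axial boundary reaction
$\sum \hat{\mathbf e}\cdot\nabla(F_B + \gamma A - PV)$ over the ring
vertices.  The tube-force identity used for cross-checks is
$f = 2\pi R\gamma + \pi\kappa/R - \pi R^2 P$, whose bending term
$\pi\kappa/R$ is required for consistency with the tether force
$2\pi\sqrt{2\kappa\gamma}$ at $P = 0$ (a force expression omitting it
appears in parts of the literature; the two differ by a factor of two at
the tether point).

### Degenerate and pathological cases

Ensembles clamping both $\gamma$ and $P \ne 0$ have no bounded bulged
equilibria (shapes inflate without limit) and are refused unless
explicitly overridden.  Clamped $(A, V)$ targets violating the
isoperimetric bound raise an error before any solve.  Divergence (radial
extent exceeding ten times its initial value, or non-finite energy) raises
a no-equilibrium condition — the expected outcome for a cylinder pushed
beyond $p^{*}_{\rm cyl}$.  On a sphere with clamped $(A, V)$ the pair
$(\gamma, P)$ is structurally degenerate (scale invariance of $F_B$ leaves
only the Laplace relation $P = \gamma J$); the least-squares retrieval
reports its condition number and the tests assert only the determined
combination.

The discrete star energy has a well-documented weakness: it rewards vertex
pairing, so local minimizations slowly drive isolated faces toward zero
area, where the energy landscape becomes effectively discontinuous and the
optimizer can stall against the resulting wall with a large residual
gradient.  The package counters this with deterministic grooming —
surgical collapse of sliver faces, Delaunay equiangulation flips and
tangential smoothing with all ring vertices protected — applied between
continuation steps (`remesh_every`), plus the full isotropic remesher
(`remesh()`) with fixed edge target used when preparing initial states.
Residual step-to-step retrieval noise of a few percent remains; sweep
analyses therefore read critical points off robust local-regression fits
of $p$ and $\gamma$ against the control parameter rather than off a single
sample, and steps whose shape did not move at all (stuck against a
discrete barrier) are excluded from the fits.

## Initial states and sweeps

The initial state is the equilibrium with a real reservoir: clamped
$(\gamma_0, P = 0, L_0)$ with free area, volume and boundary radius.  The
junction seed is the boundary surface of the union of three tubes around
the 120° ray skeleton (a pair-of-pants surface with creases that relax
away); one isotropic remeshing pass between two relaxations yields an
isotropic equilibrium mesh.  The arms settle onto the tether radius and
force, and the junction core width is of order $\lambda$.

Two alterations mirror the experiments:

* `volume_sweep()` — osmotic swelling: clamped $(A_0, L_0)$, stepped
  $V = V_0(1 + \Delta V/V_0)$, warm-started continuation;
* `force_sweep()` — tension jump: clamped $(A_0, V_0)$, stepped
  $f = (f/f_0) f_0$ with free lengths and boundary radius.

The pearling onset is the interior maximum of $p$ along the sweep
(the contour-convexity change of the junction silhouette is recorded as
corroboration, not as the estimator).  The volume sweeps use a stiffer
penalty scale than the force sweeps (`rho0` 1000 versus 100): the volume
targets change every step and need firm tracking, whereas the force steps
keep the same geometric targets and a stiff penalty freezes the
warm-started shape against the constraint walls.

Default study conditions follow the two systems analyzed in the sweeps:
the biomimetic scale (per-arm $L = 5.3\lambda_0$, total volume
$\approx 27\lambda_0^3$ relaxed, mesh edge $\lambda/3$) and the
retraction-fiber scale (per-arm $L_0 = 23.3\lambda_0$, $V_0 \approx
111\lambda_0^3$, coarse edge $\lambda/2$ with twenty sweep steps so a full
sweep stays in the minutes range on one core; the mesh-refinement trend of
the onset is checked rather than chased).

## Universality machinery

For any converged state the conformation-for-comparison is the set of
smooth cylinders sharing its boundary radius and arm lengths (three for a
junction); the excess volume and area
$V_{exc} = (V - V_C)/\lambda^3$, $A_{exc} = (A - A_C)/\lambda^2$ use the
state's *own* retrieved tension in $\lambda$ — the initial-state
$\lambda_0$ would not close the recovery equations.  States computed under
different ensembles and alterations collapse onto master curves
$(V_{exc}) \mapsto (p, A_{exc}, R/\lambda)$; `assemble_master_curves()`
tabulates and interpolates them with monotone splines and reports a
leave-one-out cross-validation error.  `recover_parameters()` inverts the
closed system of the conservation conditions plus the three master-curve
relations by a one-dimensional root search in $V_{exc}$ (all in-range roots
are reported), with the arm terms tripled for junctions.

## Numerical choices at a glance

| choice | default | why |
|---|---|---|
| internal units | $\kappa=\gamma_0=1$ | everything reported in $\lambda$ units |
| edge target | $\lambda/3$ (biomimetic), $\lambda/2$ (long arms) | resolves the core; keeps sweeps in minutes |
| constraint tolerance | $10^{-6}$ relative | convergence criterion of the state |
| penalty $\rho_0$ | $10^3$ (volume), $10^2$ (force) | see sweeps section |
| symmetry-breaking seed | $10^{-3}\lambda$ axial cosine, mode 1 | selects the single-central-bulge cylinder branch deterministically |
| onset estimator | robust loess over the sweep | multiplier noise is a few percent per step |
| grooming cadence | every 5 (volume) / 3 (force) steps | sliver control without branch disturbance |

## What the generator emulates — and what it does not

The synthetic systems are ideal Helfrich membranes: uniform bending
modulus, zero spontaneous curvature, no thermal fluctuations, no
hydrodynamics, no adhesion, exact three-fold symmetry of the junction.
Real retraction fibers carry proteins, substrate attachments and a
cytoskeleton; the biomimetic vesicle system adds measurement noise and
finite reservoir effects.  Passing tests therefore validate the mechanics
of the idealized model — the energy landscape, the constraint handling and
the critical criteria — not the biological completeness of the
description.  The universal description itself is valid only when the arms
are long compared with the junction core ($L \gtrsim 5\lambda$); the
package warns below that range.

## Known limitations

* The onset values at coarse mesh carry a systematic bias of order ten
  percent in $p^{*}$ (the junction core stiffens when the rings have few
  vertices); the bias shrinks with the edge target.
* Post-onset continuation tracks the constrained equilibrium branch, but
  the deeply bulged regime needs grooming and occasionally re-seeds; the
  junction silhouette can linger in the transitional class longer than the
  visual impression of the bulge would suggest.
* The cylinder's bulged branch under clamped $(A, V, L)$ starts at a
  symmetric saddle; the deterministic cosine perturbation selects the
  single-bulge branch, and multi-bulge states are out of scope.
* Timescales (how fast a bulge develops or relaxes) are outside the
  quasi-static energy minimization altogether.
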