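---
title: "Growing dental-implant healing chambers by strain-adaptive remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing dental-implant healing chambers by strain-adaptive remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A healing chamber is a void deliberately left between the threads of a
dental implant — often a circumferential trough — that fills with blood
clot and then woven bone after placement. A well-shaped chamber speeds
osseointegration and increases the final bone-implant contact (BIC) area,
but its ideal geometry depends on the local load transfer, which varies
along the implant. Additive manufacturing can build arbitrarily complex
chamber walls; what is missing is a systematic way to *design* them for a
given loading.

`chambergrow` grows the chamber geometry computationally. The trough is
voxelized into 50 µm cubic elements and starts entirely filled with
cancellous bone. A finite-element solve gives every element's strain
state; a Mechanostat-style remodeling law then decides, element by element
along the bone-implant interface, whether bone there would be resorbed
(the voxel becomes implant — keeping the future implant surface in contact
with bone) or deposited (an adjacent implant voxel becomes bone). Each
iteration's geometry is a *candidate* implant; candidates are ranked by
the volume fraction of surrounding bone in the healthy strain range, and
the best one is exported for manufacture.

## The remodeling law

The stimulus is the scalar equivalent strain at the element centroid,

$$\varepsilon_{eqv} \;=\; \frac{1}{1+\nu'}\;\frac{1}{\sqrt 2}
\sqrt{(\varepsilon_1-\varepsilon_2)^2+(\varepsilon_2-\varepsilon_3)^2+
(\varepsilon_3-\varepsilon_1)^2},$$

a von-Mises-type invariant of the principal strains. Four thresholds
partition strain into windows: below `eps_du` (disuse) resorption is
certain, `f* = -1`; at or above `eps_ol` (overuse) formation is certain,
`f* = +1`; inside the physiological window `[eps_pl, eps_pu)` the outcome
`f* = f(Gamma)` is governed by the *nonuniformity* of the local stress
field; the two flanking ranges interpolate linearly. `Gamma` is the
relative deviation of an element's von Mises stress from the
inverse-distance-weighted mean of the bone stresses within a sensing
radius (self excluded), and `f(Gamma) = clamp(Gamma / Gamma_u, -1, 1)`.
An element more stressed than its surroundings attracts bone; a shielded
one loses it. This drives the tissue toward a uniform stress state — and,
inside a load-shielded chamber, inexorably toward a fully implant-filled
trough, which is why intermediate iterations, not the last one, hold the
interesting designs.

A decision is drawn per interface element with probability `|f*|`
(`decision_mode = "stochastic"`; the `"deterministic"` variant acts iff
`|f*| >= 0.5`). Removals within a sweep are applied before additions, an
addition converts the lowest-linear-index eligible neighbour, and implant
voxels created by a removal in the same sweep are not eligible targets —
fixed tie-breaks that make a run bit-reproducible from its seed. The
activation count `n_act` repeats the decision sweep against the frozen
solution to mimic a higher remodeling activation frequency.

### Parameter defaults and their provenance

| parameter | default | meaning |
|---|---|---|
| `eps_du` | 100 µε | disuse threshold |
| `eps_pl`, `eps_pu` | 400, 1500 µε | physiological window |
| `eps_ol` | 3000 µε | overuse threshold |
| `sensing_radius` | 150 µm (3 voxels) | stress-sensing neighbourhood |
| `gamma_scale` | 1.0 | `f(Gamma)` saturation scale |
| `n_act` | 1 | sweeps per FE solve |

The element-swap literature this law follows does not print a unique
numeric set; these defaults place the physiological window exactly on the
400-1500 µε healthy-bone range and the disuse threshold at the classical
100 µε Mechanostat resorption boundary. They are deliberate substitutes,
exposed as mandatory configuration so a user can match any specific
source. Two conventions are ambiguous in the tradition and are exposed as
options: the effective Poisson ratio in the equivalent strain (`nu_prime
= "material"`, alternative `"half"`) and the choice of von Mises stress
(not strain energy density) as the nonuniformity field.

`n_act = 1` is the default so that one iteration corresponds to exactly
one interface sweep; under zero load this makes the chamber fill one
exhaustively-verifiable shell per iteration, which the test suite exploits.

## The finite-element model

The lattice is meshed with 8-node trilinear hexahedra (one per voxel),
fully integrated (2×2×2 Gauss). Because every element is the same cube,
the element stiffness is computed once per material and assembly is a
scatter-add, done in compiled code directly into compressed sparse
columns. Bone and implant share nodes on the conformal mesh, which
reproduces a bonded (linear, no-separation) interface exactly; there are
no contact elements. Strains are evaluated once at the element centroid —
for the regular trilinear element this equals the Gauss-point average for
linear fields.

Materials (isotropic linear elasticity): cancellous bone E = 0.69 GPa
(type IV posterior-maxilla bone), cortical bone E = 13.7 GPa (both
ν = 0.3), Ti6Al4V E = 110 GPa, ν = 0.35.

Numerical choices:

* Dirichlet constraints are applied by reduction to the free DOFs.
* Systems below 30 000 DOFs use CHOLMOD's supernodal Cholesky; larger
  systems use Jacobi-preconditioned conjugate gradients in compiled code
  to a relative residual of 1e-9 (the default model has ~425 000 DOFs; a
  direct factorization of that system exceeds an 8 GiB budget, while PCG
  converges in a few hundred iterations). Design-loop solves warm-start
  from the previous iteration's displacement.
* The solver refuses to return if the final relative residual exceeds
  1e-6, which catches under-constrained (rigid-body) systems.
* Loads are split over the loaded nodes uniformly by default — the
  documented simplification for "uniformly applied" abutment loads. For
  analytic verification against a uniform surface pressure, the
  lattice-consistent weights (¼ corner, ½ edge, 1 interior) can be passed
  explicitly.

## The synthetic model, and what it does not emulate

Commercial implant CAD geometry and anatomical jaw models are proprietary
/ unavailable, so the generator builds a parameterized stand-in: a
rectangular bone block (cortical crest over cancellous body), an
axisymmetric implant core with annular thread rings (a ring per pitch —
the helix is not resolved), an abutment protruding above the crest, and
rectangular circumferential troughs between adjacent rings, trough depth
defaulting to half the thread pitch. The troughs are the design region;
everything else is immutable. A cylindrical ROI shell (default: implant
radius + 10 voxels, spanning the embedded length) defines where the
healthy fraction is measured; ROI bounds are configuration because the
source tradition shows the region only graphically.

The default model is a *miniature*: 48 × 48 × 72 voxels at 50 µm
(2.4 × 2.4 × 3.6 mm), so that a full design run fits in minutes on one
CPU. The default 3 N axial load is the miniature equivalent of a ~100 N
bite force on a full-size implant: it was fixed a priori so that the
nominal far-field cancellous strain, F / (A_block · E) ≈ 755 µε, sits
mid-physiological-window — the same regime the full-scale model reaches
under 100 N. Mesial and distal (±y) bone faces are fully constrained.

A green test on this model establishes that the algorithm behaves as
specified — conservation, determinism, window law, candidate ranking —
and that the qualitative design trajectory (progressive chamber filling,
rising-then-saturating healthy fraction, contact-area peak at an
intermediate iteration) emerges. It does *not* reproduce the absolute
healthy-bone percentages or contact areas of any commercial implant in an
anatomical jaw: those depend on the unavailable geometry. One known
small-scale artifact matters when interpreting results: with constrained
faces only ~1 mm from the implant, stiffening the chamber *raises*
strains in the under-strained surrounding bone, so the healthy fraction
can keep creeping up to the fully-filled final candidate instead of
peaking strictly inside the run as it does at anatomical scale, where the
far field is compliant. The candidate-ranking machinery is indifferent to
which iteration wins; the tie-break (earliest iteration, then larger
contact area) prefers open-chamber designs when fractions tie.

## Candidate evaluation

* `healthy_fraction()`: share of ROI bone voxels with equivalent strain in
  [400, 1500] µε (inclusive at both ends — the boundary has measure zero
  for continuous solves, but inclusivity must be fixed for
  reproducibility). The denominator is bone-in-ROI by default; total ROI
  volume is available because the source tradition is ambiguous about it.
* `contact_area()`: shared bone-implant faces (6-connectivity) ×
  (50 µm)². At anatomical scale this is the BIC area that correlates with
  osseointegration.
* `select_best()`: maximal healthy fraction; ties broken by earliest
  iteration, then larger contact area.
* Every candidate is evaluated with a fresh solve on its own geometry
  (whether the source tradition re-solves before evaluating is unstated;
  re-solving is the physically consistent choice).

## A run, end to end

```{r}
library(chambergrow)

grid <- build_synthetic_model(implant_params())
history <- run_design(grid, default_bc(grid),
                      remodeling_params(seed = 1), max_iter = 20)
tidy(history)      # per-candidate metrics
glance(history)    # best candidate vs initial design
autoplot(history)  # fraction and contact area per iteration

best <- select_best(history)
export_stl(attr(best, "grid"), "best-implant.stl")   # for the printer
```

Or from a shell, via the installed `exec/chambergrow` script:

```sh
chambergrow build  --config config.yaml --out model.vgz --vtk model.vtk
chambergrow run    --config config.yaml --out rundir --seed 1
chambergrow export --out rundir --iteration 4 --stl implant_iv.stl
```

## Degenerate inputs and edge cases

* Zero thread/trough depth builds a plain cylinder with an empty design
  region; `run_design` then records only the initial candidate.
* Zero load solves trivially (all strains 0, disuse window everywhere):
  the chamber fills monotonically, one interface shell per iteration.
* An element whose sensing neighbourhood has zero mean stress would make
  `Gamma` undefined; inside the loop this can only happen where `f*` is
  ±1 anyway (the `f(Gamma)` weight is zero outside (`eps_du`, `eps_ol`)),
  so `Gamma` is set to 0 there; the standalone `nonuniformity()` errors.
* `max_iter = 0` evaluates the initial design only.

## Known limitations

* Annular thread rings, not a resolved helix; voxel (staircase) surfaces.
* Linear elasticity with a rigidly bonded interface — no friction,
  nonlinear contact, plasticity, or time-resolved healing.
* Discrete element swapping, not continuum density adaptation; no
  woven/lamellar distinction.
* The miniature default model reproduces mechanisms and trends, not
  absolute clinical metrics (see above).
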