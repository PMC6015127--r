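---
title: "Inextensible thread dynamics: model, solver and scene design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inextensible thread dynamics: model, solver and scene design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(threadsim)
```

## The model

`threadsim` simulates surgical thread as a *discrete Cosserat rod*: a
chain of particles (positions, velocities, inverse masses) whose
consecutive pairs form rod elements, each element carrying a unit
quaternion material frame (orientation, angular velocity, scalar inverse
inertia). A Cosserat rod tracks not only where the centerline is but how
the material cross-section is oriented along it, which is what couples
twisting to bending — the effect that makes a twisted thread suddenly
throw a loop, and a knot bind.

Two constraint families express the elasticity:

* **Shear–stretch** (one per element):
  $C_s(p_1, p_2, q) = \tfrac{1}{l}(p_2 - p_1) - R(q)\,e_3$.
  Zero exactly when the segment has rest length $l$ and lies along the
  frame's third director. It both resists stretch and keeps the frame
  glued to the centerline.
* **Bend–twist** (one per adjacent element pair):
  $C_b(q, u) = \Im(\bar q u - \bar q^0 u^0)$,
  the imaginary part of the relative frame rotation minus its rest value
  (the discrete Darboux vector mismatch). Its first two components
  measure bending, the third twist; the per-iteration corrections are
  scaled by the stiffnesses $K_b$ (bend rows) and $K_t$ (twist row).

Projection follows the standard position-based dynamics recipe: for each
constraint, $\lambda = -(\nabla C\, W\, \nabla C^{\mathsf T})^{-1} C$ (a
dense solve of size at most 3), then $\Delta p = W \nabla C^{\mathsf T}
\lambda$. Quaternions are treated as 4 raw components during projection
and renormalized after every correction. Gauss–Seidel sweeps reuse
updated state; a fixed iteration count per time step bounds the cost.

**Inextensibility** is enforced separately and directly. The chained
distance constraints $C_i = |p_i - p_{i+1}| - d$ have a Gram matrix
$\nabla C\, W\, \nabla C^{\mathsf T}$ that is *exactly tridiagonal*:
diagonal $w_i + w_{i+1}$, off-diagonal $-w\,(n_i \cdot n_{i+1})$ with
$n_i$ the unit segment directions. One Thomas-algorithm solve per
iteration therefore enforces all segment lengths simultaneously in
$O(k)$ — this is what a fixed Gauss–Seidel budget cannot do, and it is
the difference between thread that sags correctly and thread that
stretches like elastic. A held particle ($w = 0$) zeroes every coupling
through it, so a thread gripped mid-span by an instrument splits into
independently solved sub-chains without special casing.

Collision handling is continuous: the thread is a chain of spheres of
radius $r$ spaced one diameter apart ($d = 2r$ by default, so the spheres
are closely arranged and sphere–sphere time of impact — a single
quadratic — is the only narrow-phase test). Swept AABBs are hashed into a
uniform grid for culling; same-rod neighbors within two chain positions
are excluded (they overlap permanently by construction). Each detected
contact contributes an inequality constraint
$(p_1 - p_2)\cdot n \ge d$ with the normal frozen at the time of impact,
and a friction constraint $k\,|\widehat{p_1 - p_2} \times n| \to 0$ that
resists tangential motion at the contact while the pair is touching.
Static rigid colliders (plane, sphere, cylinder) produce the same
constraint types against a fixed anchor point on their surface.

Damping is time-step independent: $v \leftarrow (1-d_v)^{\Delta t} v$ and
$\omega \leftarrow (1-d_a)^{\Delta t} \omega$, i.e. the factors are the
fraction of velocity removed per second. $d_v$ models dissipation in
stretching/compression, $d_a$ in bending/twisting.

## Parameters

| parameter | units | default | notes |
|---|---|---|---|
| `dt` | s | 1/60 | interactive rendering rate; the contact scenes use 1/300–1/600 (below) |
| `iterations` | – | 10 | Gauss–Seidel sweeps per step; 5–40 is the studied range |
| `d` (element length) | m | thread thickness `2r` | set by the centerline discretization |
| `radius` | m | `d/2` | collision sphere radius |
| `K_b`, `K_t` | (0, 1] | 0.05, 0.25 | per-iteration correction scale of bend / twist rows |
| `d_v`, `d_a` | [0, 1] | 0 | fraction of linear / angular velocity removed per second |
| `mass` | kg | 1 | uniform per particle; only ratios matter in projection |
| `inv_inertia` | 1/(kg·m²) | `1/(m d²)` | isotropic scalar; the scale of a rod element's moment of inertia |
| `frame_coupling` | (0, 1] | 0.05 | see "Numerical choices" |
| `friction_k` | [0, 1] | 0.5 | 0 frictionless, 1 blocks tangential contact motion |
| `cell_size` | m | 2 × sphere diameter | spatial hash cell edge |

Stiffnesses are solver parameters, not physical moduli: the mapping from
$K_b, K_t$ to bending/twisting modulus depends on discretization, time
step and iteration count, and no closed form exists. They are chosen per
scene for behavior, which is the accepted practice for this family of
methods.

## Numerical choices

These choices are where the implementation earns its stability; each was
adopted after the naive variant failed reproducibly, and each is guarded
by tests.

**Quaternion convention.** Scalar-first $(w, x, y, z)$, Hamilton
product; rotation is $q (0,v) \bar q$. Rest frames are the shortest-arc
rotation from $e_3$ onto each segment (twist-free), with the antiparallel
case resolved by a 180° rotation about a fixed orthogonal axis.

**Inverse inertia and frame coupling.** The shear–stretch constraint
weighs its position block as $1/l^2$; with millimeter elements this is
$\sim 10^6$, so the frame's effective weight decides who moves when frame
and segment disagree. Two failure modes bracket the choice: frames much
heavier than positions lag rigid rotations and drag the falling thread
sideways (divergence); frames balanced with positions get enslaved to the
segments at the Gauss–Seidel fixed point, and bending stress can no
longer move the centerline at all (a bent rod then creeps instead of
springing back). The resolution is to keep the physical inertia scale
$1/(m d^2)$ but scale the frame's inverse inertia by `frame_coupling`
(default 0.05) *inside the shear–stretch projection only*: frames track
the centerline over a few steps, yet remain governed by the bend–twist
constraints, which restores usable bending elasticity at fine
discretizations.

**Frame re-attachment.** After the projection loop, each frame is
rotated onto its segment by the minimal (twist-preserving) rotation.
The frames' angular velocities then measure actual material rotation, so
the per-second angular damping $d_a$ dissipates bending motion — without
this, the within-step iteration converges the frames to a fixed point,
the measured $\omega$ is nearly zero, and $d_a$ has no observable effect.

**Direct solver robustness.** The tridiagonal solve is a Gauss–Newton
step: exact for near-collinear chains, but a *full* step overshoots
violently when the length violation spans many segments on a curved chain
(the directions it linearized around rotate away; a dense reference
solver shows the same behavior). Three layers address this: a
backtracking line search on the maximum length violation inside each
solve; on the final iteration of each step, the solve is repeated to
convergence, alternating with a sequential distance pass that is
nonlinearly exact per constraint; and if the residual still exceeds
$10^{-6} d$, a follow-the-leader sweep anchored at held particles
(the discrete taut-chain limit) restores exact lengths. The fallback is
not mass-weighted, so it is last-resort only and never fires in gentle
scenes.

**Friction projection.** Projecting the raw scalar $C_f = k\,|\hat u
\times n|$ is scale-invariant in $k$ (both the value and the gradient
norm carry it), which would make any $k > 0$ equally sticky; $k$ is
therefore also applied as the PBD stiffness of the correction. The
correction is clamped to a quarter of the pair distance per projection
(the constraint is non-convex and full Gauss–Seidel steps can explode),
and a contact counts as "touching" for friction when its gap is within
2% of the separation target (the contact solve parks pairs at a gap of
$0^+$, where an exact-zero activation test would leave friction
permanently inactive).

**Without the direct solver** (`use_ddc = FALSE`), one sequential
Gauss–Seidel pass over the chained distance constraints runs per
iteration — the iterative distance handling that the direct solve
replaces. This is the ablation baseline: its elongation is large at low
iteration counts and decreases as iterations grow.

**Degenerate inputs.** Coincident consecutive particles are a
degenerate-geometry error (the distance gradient is undefined); a
segment with both ends held yields a zero pivot and is skipped, not
fatal; an all-held chain is a no-op; singular local systems in the
generic projector skip the constraint and continue.

## The scenes: what they emulate, and what they do not

All experiment inputs are generated programmatically; a "frame" is one
solver step at `dt` (there is no separate render clock). Scene
parameters the underlying protocol leaves open were fixed once, on
physical grounds, and are listed here.

* **Hanging spiral** (`hanging_spiral_experiment`): 120 elements, 15 cm,
  helical rest shape, one end pinned, gravity; 10 s at `dt = 1/60`. The
  helix uses radius 5 mm and pitch 2 cm — about four turns; a 1 cm-radius
  coil of six turns is geometrically impossible for a 15 cm thread, so
  this is the nearest realistic coil. Measured: percent elongation per
  frame. With the direct solver the bound of a few percent holds at
  every iteration count in {5, 10, 20, 40}.
* **Compression–release** (`compression_release_experiment`): 49
  elements, 2 cm, no gravity or friction. The left end is clamped
  (position and frame — a position-only pin leaves the recovered shape
  direction-indeterminate and the settle metric meaningless), the right
  end gripped and pushed 1 cm inward quasi-statically over 2 s under
  heavy damping, then released with `d_v = 0` and the tested `d_a`. The
  straight centerline carries a sub-radius multi-harmonic transverse
  imperfection so the inextensible compression buckles deterministically
  into a mix of modes; a single-mode buckle would swing coherently
  through the rest state and make the settle metric dip to zero even
  undamped. Scene stiffness `K_b = K_t = 0.5`. Measured: the summed
  particle distance to the pre-compression state for 500 frames.
* **Twist winding** (`twist_winding_experiment`): 40 elements, 15 cm,
  ends clamped 12 cm apart with a sag and a 1 mm out-of-plane seed; the
  right end frame ramps through $10\pi$ radians about the world x axis
  over 6 s, then settles 4 s. Gravity is off: hanging tension suppresses
  the twist-to-writhe instability at these stiffness scales. Measured:
  maximum out-of-plane deflection and a winding count (sign changes of
  the out-of-plane deflection along the centerline).
* **Knot tightening** (`knot_experiment`): 100 elements, 15 cm, laid out
  as an open trefoil (a loose overhand knot); both ends pulled apart
  4 cm over 4 s by a shipped waypoint script, `dt = 1/300`. Measured:
  minimum center distance between non-neighboring spheres (the
  no-tunneling contract) and final elongation.
* **Cylinder binding** (`cylinder_wrap_experiment`): a single throw —
  2.5 turns draped around a 5 mm rigid cylinder with both tails hanging,
  their weight tensioning the wrap (a capstan). Gravity is tilted 15°
  toward the cylinder axis so an axial force constantly drives the wrap;
  `dt = 1/600` with a 2 s settle before the 5 s measurement. At
  `dt = 1/60` a single resting-particle gravity step moves farther than
  the thread radius, which no position-level friction constraint can
  survive — the finer step is a property of contact resolution at
  millimeter scale, not of this scene. Measured: mean axial drift.

What passing these scenes does *not* show: the thread has no physical
elastic moduli (stiffnesses are solver-scale), contacts are
sphere-on-sphere rather than capsule-based (grazing contacts between
nearly parallel threads resolve at sphere resolution), masses are
uniform, and the scenes use scripted boundary motion rather than
interactive instruments. Timing claims (ms per frame) are out of scope.

## Problem sizes

The shipped experiments use the scene sizes above (40–120 elements,
500–3000 steps); the full test suite, including the experiment sweeps,
runs in well under two minutes on one CPU. Larger rods and longer
horizons scale linearly in elements × iterations × steps, with an
$O(n^2)$ term only in the optional minimum-separation diagnostic.

## Known limitations

* Bending/twisting stiffness saturates with the iteration budget and
  falls with refinement (a Gauss–Seidel property); matching a measured
  flexural rigidity is out of reach by construction.
* Friction is not Coulomb: its strength does not scale with normal
  force, and stick–slip transitions are resolution-dependent.
* The direct solver's follow-the-leader fallback transfers momentum
  toward the free end of a chain; it only engages when the
  mass-consistent paths stall (violations of many segment lengths on
  strongly curved chains).
* Rod topology is a single open chain per rod; branched or closed
  threads are not supported.
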