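# threadsim

Real-time simulation of inextensible surgical thread as a discrete
Cosserat rod inside a position-based dynamics (PBD) solver, in R.

Surgical thread is thin, nearly inextensible, and spends most of a
suturing task in contact with itself and with instruments. Simulators for
surgical training need thread that neither stretches visibly nor tunnels
through itself when a knot is cinched, at interactive time steps. This
package implements such a simulator and ships the validation scenes —
hanging-spiral inextensibility sweeps, compression–release dissipation,
twist winding, overhand-knot tightening, and thread-on-cylinder friction
binding — as reproducible, scripted experiments. It is aimed at
researchers in computational biomechanics and physically based simulation
who want an inspectable reference implementation with a test suite, rather
than a game-engine plugin.

## The model

The thread centerline is a chain of particles `x_1 .. x_j` with inverse
masses `w_i`; each consecutive pair forms a rod element carrying a unit
quaternion `q_k` (a material frame, with scalar inverse inertia). Every
step the solver

1. predicts positions and orientations by symplectic explicit Euler,
2. detects collisions continuously (sphere–sphere time of impact, swept
   AABBs, spatial hashing) between the current and predicted states,
3. projects constraints Gauss–Seidel style for a fixed iteration count,
   each constraint solving `λ = −(∇C W ∇Cᵀ)⁻¹ C` and applying the
   mass-weighted correction `Δp = W ∇Cᵀ λ`,
4. updates velocities from the corrected state and applies time-step
   independent damping `v ← (1−d_v)^Δt v`, `ω ← (1−d_a)^Δt ω`.

The constraints are the discrete Cosserat pair

* shear–stretch: `C_s(p1, p2, q) = (p2 − p1)/l − R(q) e₃`, tying each
  segment to its frame's tangent director at rest length `l`, and
* bend–twist: `C_b(q, u) = Im(q̄u − q̄⁰u⁰)`, the discrete Darboux-vector
  mismatch between adjacent frames (first two components bend, third
  twist, scaled by stiffnesses `K_b`, `K_t`),

plus position-level contact (`(p1−p2)·n ≥ d`) and friction
(`k·|unit(p1−p2) × n| → 0`) constraints from the collision pass.

What makes the thread inextensible is the **direct distance constraint**:
all chained segment-length constraints `C_i = |p_i − p_{i+1}| − d` are
solved *simultaneously* each iteration. Their Gram matrix `∇C W ∇Cᵀ` is
exactly tridiagonal (row `i` couples only `λ_{i−1}, λ_i, λ_{i+1}`, with
diagonal `w_i + w_{i+1}` and off-diagonals `−w (n_i · n_{i+1})`), so one
Thomas-algorithm solve per iteration enforces length in O(k). A held
particle (`w = 0`, an instrument grip) zeroes the couplings through it and
splits the chain into independently solved sub-chains.

## Worked example

Build the reference thread (120 elements, 15 cm, helical rest shape), pin
one end, and let it drop under gravity for ten simulated seconds:

```r
library(threadsim)

rod <- build_rod(make_spiral_centerline(0.15, 120))
print(rod)
#> <thread_rod>
#>   120 elements (121 particles), rest length d = 0.00125 m, radius = 0.000625 m
#>   total length 0.15 m; K_b = 0.05, K_t = 0.25, d_v = 0, d_a = 0

res <- hanging_spiral_experiment(iterations = 10, use_ddc = TRUE,
                                 duration = 10)
print(res)
#> <thread_result: hanging_spiral>
#>   600 recorded frames
#>   max_elongation_pct: 4.34306e-09
#>   final_elongation_pct: 3.70074e-14
#>   iterations: 10
#>   use_ddc: TRUE
```

`max_elongation_pct` is the largest relative excess of the centerline's
polyline length over its 15 cm rest length across all 600 frames: with
the direct distance constraint the thread stays inextensible to numerical
precision. The full iteration sweep shows the ablation:

```r
elongation_sweep(duration = 10)
#>   iterations use_ddc max_elongation_pct final_elongation_pct
#> 1          5    TRUE          5.702e-09            0.000e+00
#> 2         10    TRUE          4.343e-09            3.701e-14
#> 3         20    TRUE          5.525e-09            3.701e-14
#> 4         40    TRUE          4.312e-06            7.401e-14
#> 5          5   FALSE          2.692e+03            1.324e+03
#> 6         10   FALSE          1.355e+03            8.032e+02
#> 7         20   FALSE          6.814e+02            3.868e+02
#> 8         40   FALSE          3.437e+02            1.776e+02
```

Without the direct solver, Gauss–Seidel distance handling leaves large
elongation that shrinks as the iteration count grows — the qualitative
signature the direct solver removes.

A command-line driver wraps the same scenes
(`inst/exec/threadsim`): `threadsim run scene.yaml`,
`threadsim sweep-elongation`, `threadsim sweep-damping`,
`threadsim demo-knot`, with `--seed`, `--iterations`, `--no-ddc`,
`--duration` and `--out` flags. Scene files are YAML (see
`inst/extdata/minimal_scene.yaml`); trajectories and metrics are written
as CSV, centerlines as Wavefront OBJ polylines.

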