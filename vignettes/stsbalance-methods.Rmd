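---
title: "Methods: sit-to-stand balance feasibility maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sit-to-stand balance feasibility maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its model, the numerical choices
behind it, and what the synthetic-data experiments do and do not show.

## The models

Both models describe the body after seat-off as a point mass (the
whole-body centre of mass, CM) rotating about the ankle of a motionless
support foot, in the sagittal plane. The state is the CM angle `θ`
(measured from the anterior horizontal axis, so `θ = π/2` with the CM over
the ankle and `θ > π/2` posterior) and its rate `ω`.

The **simple inverted pendulum** keeps the rotational radius `l` constant:

```
τ − m g l cos θ = m l² θ̈.
```

The **inertia-variable (telescopic) pendulum** lets the radius vary with
the angle, `l(θ) = a₀θ³ + a₁θ² + a₃θ + a₄` (the coefficient naming skips
`a₂` deliberately, following the convention of the cubic radius fit), so
`I(θ) = m l(θ)²` and

```
τ − m g l(θ) cos θ = (dI/dθ) θ̇² + I(θ) θ̈,    dI/dθ = 2 m l l′.
```

This is exact for a point mass whose radial motion is produced by internal
(muscular) coordination: internal forces and the ankle reaction exert no
torque about the ankle, so the angular momentum about the ankle is
`m l² θ̇` and its rate equals the ankle torque plus the gravity torque. The
assumption doing the real work is that the joints move in a stereotyped,
synchronized way, so that `l` is a function of `θ` alone — that is what
reduces a multi-joint movement to one degree of freedom. With
`a₀ = a₁ = a₃ = 0` every quantity in the package reduces exactly to the
simple model; this reduction is asserted by tests to below 1e-6 in
normalised units (in practice it is exact, because the constant profile
makes the extra terms identically zero).

## The admissible torque set

The foot must not move. With CM acceleration obtained by differentiating
`u = l(θ) cos θ`, `h = l(θ) sin θ` twice along the motion, the ground
reaction on the body is `Fx = m ü`, `Fz = m (ḧ + g)`, and four constraint
families apply:

1. ground contact: `Fz > 0`;
2. no slip: `|Fx| ≤ μ Fz`;
3. no tip: the centre of pressure stays within the foot,
   `−d_heel ≤ u_p ≤ d_toe`, with `u_p Fz + h_ankle Fx = τ` from the moment
   balance of a massless foot (positive torque is counterclockwise on the
   body, i.e. the plantarflexion side, with anterior = +x and the
   ground reaction applied at the CoP on the sole);
4. physiology: `−τ_df,max ≤ τ ≤ τ_pf,max`.

Since `θ̈` is affine in `τ`, so are `Fx`, `Fz` and every constraint: the
admissible set at a state is an interval, computed in closed form. An empty
interval means the state is uncontrollable without moving the foot; the
failure is labelled by which constraint family, when relaxed alone,
restores feasibility (slip / tip / torque-limit). The foot is treated as
massless in the CoP balance — no foot inertial parameters enter the model —
and the sign conventions above are fixed by the requirement that a static
hold place the CoP directly under the CM.

## Map construction

Map coordinates are `x = (d_toe − u)/foot_length` (posterior distance from
the toe, 0 = toe, 1 = heel) and `v = u̇ / height` (anterior CM velocity in
heights/s).

Each boundary is the trajectory field's extremal envelope, obtained by
backward integration:

- **Upper (forward-fall) boundary**: apply, at every instant, the largest
  admissible torque (maximal braking). Its terminal state is the most
  anterior statically holdable CM position — the toe, provided
  `τ_pf,max ≥ m g d_toe` (true for the package defaults) — at zero
  velocity.
- **Lower (backward-fall) boundary**: mirror image — maximal admissible
  dorsiflexion, ending just over the heel.
- **Zero-torque curve**: the `τ = 0` dynamics, ending at the upright
  equilibrium (CM over the ankle).

Each terminal state is a saddle of the corresponding dynamics: the CoP
constraint caps the holding torque exactly at the value that balances
gravity there, so the extremal field has a semi-stable equilibrium and the
boundary is its stable manifold. Integration therefore starts from a small
offset `ε` along the stable eigendirection of the numerically linearised
dynamics (central differences, step 1e-6 rad), on both sides of the saddle
(the anterior branch carries the negative-velocity part of each curve).
Backward integration is self-correcting: transverse perturbations decay,
so the computed curve is insensitive to `ε` (halving it moves the curve by
less than 1e-8 heights/s, which the tests assert through a smooth
interpolant of the raw samples).

In fast, crouched postures the admissible interval can pinch shut for
*every* torque — the no-slip cone and the vertical-reaction requirement
collapse under large centripetal acceleration. Where the extremal braking
trajectory runs into this **feasibility frontier**, the forward-fall
boundary continues along the frontier (located by bisection in `v` at each
grid abscissa) until it meets the backward-fall boundary and the stable
region closes. States beyond the closure are classified unstable, not
errors; queries outside the map's x extent are errors (no extrapolation).

Classification is strict: a state, together with its whole horizontal error
bar `[x − Δx, x + Δx]`, must lie strictly between the boundaries to be
called stable, so an on-boundary point is unstable.

### Numerical choices

- Fixed-step classical RK4, default `dt = 5e-4 s` for boundary curves
  (energy-conservation error of the `τ = 0` dynamics is at machine level;
  the closed-form zero-torque oracle agrees to ~1e-10 heights/s). A
  fixed-step scheme was chosen over an adaptive library integrator because
  the extremal field is only piecewise smooth (constraint switching) and
  the integration needs per-step admissible-range evaluation and custom
  termination.
- Saddle offset `ε = 1e-6 rad`; backward time capped at 20 s per branch.
- Map grid default `x ∈ [−0.2, 3.0]` foot lengths, 400 samples (seat-off
  distances in demanding sit-to-stands reach ~2.5 foot lengths); curves are
  resampled onto the grid by monotone piecewise-linear interpolation, with
  non-monotone sweeps reduced to the conservative (innermost) envelope.
- Inverting boundaries for the position control tolerance `W(v) =
  x_lower(v) − x_upper(v)` uses the rising limb of each curve (terminal to
  velocity maximum): the tolerance is measured between the anterior-most
  crossings.
- Similarity between a candidate map `a` and the reference map `b` is
  `1 − |W_a(v) − W_b(v)| / W_b(v)`; the exact functional form of such a
  comparison is a convention, so it is defined once here and used
  consistently. The validity velocity is the largest grid velocity below
  which similarity stays above the threshold (default 0.85).

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `foot_length` | 0.152·height | m | standard anthropometric scaling |
| `d_toe` / `d_heel` | 0.75 / 0.25 of foot length | m | ankle ~25% of foot length from the heel |
| `ankle_height` | 0.039·height | m | standard scaling |
| `mu` | 0.8 | – | shod foot on dry indoor floor |
| `tau_pf_max` | 2.2·mass | N·m | healthy-adult plantarflexion maximum; ≥ m·g·d_toe so the toe-hold terminal exists |
| `tau_df_max` | 0.7·mass | N·m | upper range of healthy dorsiflexion; ≥ m·g·d_heel so the heel-hold terminal exists |
| segment fractions | head .090, trunk .552, thigh .222, shank .103, foot .032 | – | standard table, arms excluded, renormalised |
| fraction SDs | .012/.042/.030/.014/.006 | – | between-subject mass-distribution spread; propagates to a CM error bar of roughly ±1–1.5 cm in sitting postures |
| velocity smoothing | 2nd-order Butterworth, 6 Hz, zero-phase | Hz | typical kinematic low-pass; the filter is a configurable choice, not part of the model |
| energy-strategy band `δ` | 0.01 | heights/s | "on the zero-torque curve" tolerance; no principled value exists, declared once |
| condition threshold | 2.48 | foot lengths | an empirical cohort value, configurable — not a constant of the method |

CM estimation assumes uniform segment density (segment CM at the
marker midpoint), bilateral symmetry (left/right markers averaged into one
sagittal segment), and a motionless ankle, whose marker position is
time-averaged so that reference noise does not leak into every CM sample.
First-order propagation of the fraction SDs gives
`sd(u_cm) = sqrt(Σ σᵢ² (uᵢ − u_cm)²)` per posture (worst case over the
trial); a Monte-Carlo oracle with renormalised perturbed fractions agrees
within 5%.

A profile fitted from natural trials only covers the observed angle range,
which never includes the toe-hold terminal; computing a map from it
requires extrapolating the cubic, which `extend_profile()` does explicitly
(re-validating positivity) rather than silently.

## The synthetic generator

The generator stands in for a motion-capture cohort. A synthetic subject
draws anthropometry uniformly from configurable ranges (defaults 1.65–1.85
m, 60–85 kg). Its inertia profile is the cubic
`l(θ) = l_up (1 − A (d² + 0.3 d³))`, `d = θ − π/2`, with `l_up =
0.48·height`: the radius is longest near upright and shortens toward
seated, crouched postures, emulating the multi-joint radius change of a
sit-to-stand; `l_up` sits below the erect CM height because the body is
still partially flexed when the CM passes the ankle. The default variation
`A = 0.15` gives a ~12% radius change over the movement; profiles must keep
`l > 0` and the CM horizontal position monotone in `θ` (otherwise map
coordinates would be ill-defined), and the generator damps `A` until both
hold.

Marker trials forward-simulate the pendulum from a seat-off state under a
velocity-tracking policy that follows a braking target profile above the
minimum-energy requirement — emulating the observation that natural
sit-to-stands carry extra kinetic energy relative to the zero-torque
trajectory, trading energy for backward-fall margin — and emit 15-marker
frames at 120 Hz from a 5-segment kinematic chain. The thigh and trunk
angles are solved per frame (damped Newton, residual < 1e-10 m) so that the
chain's whole-body CM coincides with the pendulum CM exactly; noiseless
round-trips through the CM estimator and the cubic fit are therefore exact
to solver tolerance, which is what makes "recovered within 1e-9 m" a
meaningful test of the analysis code rather than of the generator.

The labelling oracle searches piecewise-constant torque sequences (depth 8,
5 levels spanning the admissible interval at each segment start, 0.15 s
segments, nominal torque clamped to the instantaneous admissible range) for
a control that parks the CM over the BOS. Clamping keeps the extremal
policies inside the searched family; two exact prunes (CM posterior of the
heel with non-anterior velocity, or anterior of the toe with non-posterior
velocity, is unrecoverable) keep the search fast. Because the control grid
is finite, the oracle is slightly conservative within about one grid cell
of the forward-fall boundary — which is why boundary-adjacent disagreements
are tolerated in the grid-agreement check, and why oracle-labelled cohorts
exclude states within one cohort cell of a boundary.

What the synthetic experiments show: that the analysis pipeline is
internally correct (exact round-trips, oracle agreement, reduction,
monotonicity) and that the *direction* of the model comparison holds — the
inertia-variable map classifies an oracle-labelled cohort perfectly while
the simple model overpredicts stability for fast, far-posterior seat-offs,
and the two agree at low velocities. What they do not show: agreement with
any particular human cohort's numbers. Real sit-to-stands have soft-tissue
artifact, non-stereotyped coordination (so `l` is not exactly a function of
`θ`), arm motion, measurement noise structure beyond i.i.d. Gaussian, and
foot compliance, none of which the generator emulates.

## Problem sizes

The shipped tests and the acceptance script use one subject per scenario, a
400-point map grid, a 15×15 oracle grid, cohorts of ~140 grid states, 20
noise seeds for the fit-recovery study, and 3 levels per constraint
parameter for the monotonicity study; these sizes make every boundary and
every label recomputable from scratch in a few minutes on one core while
leaving the statistics (coefficient SEs, agreement percentages) stable.

## Known limitations

- One degree of freedom: stepping, grasping, or any base-of-support change
  is outside the model, as is frontal-plane balance.
- The CoP balance treats the foot as massless; a heavy-footed subject's
  boundaries would shift slightly.
- The admissible-torque treatment assumes torque can switch instantaneously
  (no rate limits, no activation dynamics), so the maps are outer bounds of
  what a physiological controller can do.
- Boundary construction assumes the extremal-field argument (greedy
  extremal torque is optimal for reaching the terminal hold); the
  exhaustive-control oracle cross-checks this on coarse grids but is not a
  proof.
- Fitted cubics are extrapolated beyond the observed angle range for
  mapping; strongly varying profiles can become non-invertible there, which
  the code rejects rather than repairs.
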