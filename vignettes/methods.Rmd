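---
title: "Models and methods: muscle-driven stair and ramp ascent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: muscle-driven stair and ramp ascent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairgait)
```

`stairgait` teaches a physics-based muscle-driven human model to ascend
stairs and ramps with reinforcement learning, and evaluates the
resulting gait. This vignette is the package's account of the models it
implements, the parameters that matter, and the numerical and design
choices behind them.

## The musculoskeletal model

The simulated model is a sagittal-plane seven-body chain: a lumped
pelvis+trunk+head segment on a 3-DOF planar joint (horizontal and
vertical translation plus tilt) and, per leg, a thigh, shank and lumped
foot connected by hip, knee and ankle pin joints — 9 DOF in total. The
full 3D topology (14 DOF, six-DOF pelvis, hip ab/adduction, 18 muscles)
exists as a configuration preset (`full_model_spec()`) for state-layout
accounting and serialization, but forward simulation is restricted to
the planar variant: the planar chain captures the sagittal mechanics of
stair and ramp ascent that the reward observes, at a cost that allows
desk-scale training.

Each leg carries 7 Hill-type muscles (gluteus maximus, iliopsoas,
vasti, biceps femoris short head, gastrocnemius, soleus, tibialis
anterior) — the sagittal subset of the 9-per-leg set of the full model,
dropping the two biarticular hip-knee muscles (hamstrings, rectus
femoris) whose main planar actions are covered by gluteus maximus and
vasti. Muscle force is

  F = f_max (a fL(l) fV(v) + fP(l)) cos(penn)

with a Gaussian active force-length curve (width 0.45 on normalized
length), a hyperbolic force-velocity curve reaching zero at the maximum
shortening velocity and saturating at 1.8 under lengthening, and an
exponential passive curve that is zero at or below the optimal length
and reaches 1 at 60% passive strain. These are the standard curve
shapes of the platform family the model descends from, chosen because
the source material names the Hill formulation without printing curves.
Activation follows excitation through first-order dynamics with
`tau_act` = 10 ms and `tau_deact` = 40 ms (configurable; the
literature-standard values, since no values are printed for this
model), advanced by the exact exponential update so activations can
never leave [0, 1].

The tendon is rigid: fiber length is the muscle path length minus the
tendon slack length, projected by a constant pennation angle. This
removes an inner root-solve per muscle per step and is adequate at this
scale; it is a deliberate deviation from elastic-tendon Hill models.
Muscle paths are straight origin-insertion lines with optional via
points; moment arms are the path-length Jacobian, realized by applying
the tension at every path point.

Maximum isometric forces and optimal fiber lengths are approximate
values for the simplified lower-limb model family (e.g., soleus 3549 N,
vasti 5000 N); they are defaults, not claims. Tendon slack lengths are
calibrated at model-build time so that the standing posture puts every
fiber exactly at its optimal length — the one self-consistent choice
given that the simplified muscle paths differ from any published
geometry. Two task presets exist: `"stairs"` fixes the trunk-pelvis
angle at -15 degrees and scales every `f_max` by 1.8 (the strength
compensation used for stair ascent), `"ramp"` uses -5 degrees and
unscaled strength.

## Terrain and contact

The stairs (3 steps of 0.2 m rise by 0.25 m tread, 2 m wide, 0.6 m
total rise) and the ramp (3.25 m run, 0.45 m rise, gradient 7.883
degrees, surface length 3.28 m) are built as watertight minimal
triangulations: the solid profile polygon is extruded across the width,
end caps fan-triangulated, side walls split into triangle pairs. The
builders target minimal valid watertight meshes; their vertex/face
counts are construction properties (16/28 for the three-step stairs,
6/8 for the wedge), verified instead through exact signed-volume
closed forms (width x depth x height x n(n+1)/2 for stairs, half run x
rise x width for the ramp) and through the full `validate_mesh()`
report: edge-manifold watertightness, consistent outward winding via
directed-edge uniqueness and positive signed volume, no duplicate
vertices, no degenerate faces. All meshes round-trip bit-identically
through the package's triangle-only OBJ reader/writer.

Each foot carries three contact spheres — a 50 mm heel at (30, 20, 0)
mm in the hindfoot frame and two 25 mm toes at (20, -5, +/-26) mm in
the forefoot frame, mirrored in Z on the left — triangulated as UV
spheres with 15 longitudinal segments and 8 latitudinal rings: 107
vertices and 210 faces. In the lumped planar foot the hindfoot and
forefoot frame origins are placed so that heel and toe sphere bottoms
are level, making flat-foot standing well-posed; the resulting standing
ankle height is 47 mm.

Contact is an elastic foundation discretized at the sphere vertices:
each vertex owns a tributary area (sphere surface area / 107) and
presses on the terrain with pressure k x (1 + c xdot), stiffness
k = 50 MPa/m and dissipation c = 5 s/m, clamped at zero. "MPa/m" is
read as pressure per meter of penetration (5e7 Pa/m). Penetration
depth is measured along the local terrain face normal, with the terrain
treated as a triangulated height field (only upward-facing faces carry
load; risers and side walls do not). Friction blends a static peak
(mu_s = 0.9) into the dynamic coefficient (mu_d = 0.9) across the
transition velocity 0.1 m/s, with a viscous term mu_v = 0.9 scaled by
normalized slip speed; the blend is zero at zero slip, so there is no
force discontinuity at rest. Whether the tabulated dissipation acts
multiplicatively or additively is unstated in the source; the
multiplicative (Hunt-Crossley-style) factor is used, matching the
platform convention. Only sphere-terrain pairs collide.

## Integration and numerical choices

The equations of motion of the planar chain are assembled analytically
(point Jacobians, composite mass matrix, velocity-product bias forces)
and integrated with a semi-implicit Euler scheme: speeds first, then
coordinates with the new speeds. Two numerical choices matter:

- **Implicit treatment of velocity-dependent forces.** With the
  tabulated contact coefficients, the damping slopes are enormous
  relative to the foot-pitch inertia (~0.007 kg m^2 against a 0.15 m
  toe lever): the contact dissipation slope c k x A, the low-slip
  friction slope mu N / v_t, and the muscle force-velocity slope all
  violate the explicit stability bound by an order of magnitude at any
  practical step size, and a fully explicit step diverges within tens
  of milliseconds. All such slopes are therefore linearized per step
  and treated backward-Euler through a damping matrix D, solving
  (M + dt D) u' = M u + dt (Q - Q_bias) + dt D_muscle u. Elastic terms
  stay explicit. High-slip friction (beyond 1.5 transition velocities)
  is a bounded explicit Coulomb+viscous force, so the stiff
  linearization only ever acts near sticking.
- **Step sizes.** The physics step defaults to 2 ms with the control
  (excitation hold) interval at 10 ms. Trajectories at 1 ms and 2 ms
  agree to plotting accuracy and neither diverges under random binary
  excitations; 2 ms is the cheapest stable choice given the explicit
  elastic contact stiffness.

Soft joint limits (300 N m/rad outside the range, 2 N m s/rad damping)
and a small passive pin-joint damping (0.1 N m s/rad) complete the
passive dynamics. Episodes terminate on a fall (pelvis below 60% of its
initial 0.94 m height — the source describes falls ending the
simulation without printing a threshold), on leaving the terrain
footprint, on a non-finite solve (flagged as divergence, never silent
NaN propagation), or at the end of the reference.

## Reference motions

Imitation targets are uniform-grid joint trajectories. Velocities are
backward differences divided by the sampling interval with the initial
sample copied from the first computable one; the printed divisor "t" in
the source's velocity definition is read as the sampling interval,
since dividing by absolute time is dimensionally inconsistent with the
stated boundary treatment. Readers exist for a plain CSV dialect
(SI units) and a TRC-like tab-separated dialect (header with
DataRate/NumFrames; translations in declared units, rotations in
degrees, normalized on read), with malformed rows and rate mismatches
rejected by row number.

Because the original motion-capture source (and the marker
inverse-kinematics pipeline) is out of scope, a synthetic gait
generator supplies the references. It emulates: stand-still initiation
(0.4 s) with the left leg taking the first swing, a pelvis that gains
one step depth and one step height per cycle on stairs (or one stride
projected on the slope for the ramp), and per-joint two-harmonic
templates with left/right half-cycle phase offset shaped to stair
kinematics — deep knee flexion at weight acceptance, extension through
pull-up, swing flexion for clearance, ankle plantarflexion at push-off.
Cycle duration defaults to 1.4 s with 2 cycles, the range healthy
adults use on stairs of this rise. Gaussian noise is available, seeded
and reproducible, but defaults to zero (inverse-kinematics output is
smooth at this scale). What the generator does **not** emulate: marker
soft-tissue artifact, inter-subject variability, kinetic consistency
(the templates are kinematic shapes, not solutions of the dynamics), or
foot-terrain clearance guarantees. Tests passing against these
references therefore demonstrate the machinery — tracking, reward,
learning — on stair-like motions, not fidelity to any recorded subject.

## Reward

The per-step reward is

  J_t = 0.1 Jgoal + 0.9 Jimitation,
  Jgoal = exp(-8 p_vel_pelvis),
  Jimitation = 0.9 exp(-4 p_pos) + 0.1 exp(-0.1 p_vel),

where p_pos and p_vel are sums of squared deviations from the reference
over the tracked DOFs (all nine planar coordinates: pelvis pose, hips,
knees, ankles — pelvis orientation and translation are both included,
configurable) and p_vel_pelvis is the squared pelvis translational
velocity deviation. The sums inside the exponentials are within-step
sums over tracked DOFs, not cumulative sums over time — a cumulative
exponent would drive every reward to zero and contradicts the per-step
framing — and the goal term uses the pelvis velocity only. The reward
lies in (0, 1], equals 1 exactly on the reference, and is strictly
decreasing in each penalty.

## Learning

The policy is a multilayer perceptron with tanh hidden layers; the
output layer is a sigmoid head producing independent per-muscle
Bernoulli probabilities from which the binary excitation vector is
sampled. A tanh output cannot represent probabilities, so the sigmoid
head is a recorded deviation from the stated all-tanh output; hidden
layers keep tanh. The full-scale configuration (input 214 for the 3D
state layout, hidden 312/312, output 18) is available as
`policy_spec()` defaults; desk-scale training uses the planar
113-dimensional observation and 64/64 hidden layers. Observations are
rescaled by fixed characteristic scales (10 m/s, 100 m/s^2, 2 kN,
100 N m) so every policy input is of order one.

Training is proximal policy optimization with the clipped surrogate
objective, a same-architecture value network (implied but never
described in the source; added here), generalized advantage estimation,
per-batch advantage normalization (configurable off), an entropy bonus,
and Adam. Hyperparameters are unprinted in the source ("taken from our
previous work"); the package defaults are the standard PPO values
(clip 0.2, gamma 0.99, lambda 0.95, learning rate 3e-4, 4 epochs,
minibatch 256, rollout 2048). Everything is driven by a single seed;
two runs with the same seed produce bit-identical learning curves.
Metrics are flushed every 5 iterations and the best policy by
normalized return is checkpointed; a non-finite loss aborts with the
last checkpoint retained.

At evaluation time excitation probabilities can be thresholded at 0.5
(deterministic) or sampled. Binary muscle policies produce intermediate
mean activations by stochastic dithering, which thresholding removes;
learning-curve and trained-vs-random comparisons therefore use sampled
actions, while the threshold mode is kept for deterministic replay.

**Scaled-down study conditions.** The learning check trains on the
planar stair task against the synthetic reference with rollouts of 512
control steps, 60 iterations, 64/64 hidden layers, learning rate 3e-3,
entropy coefficient 0.003 and minibatch 128 — desk-scale sizes that
train in minutes on a single CPU; the learning rate is raised from the
full-scale default because a 60-iteration schedule leaves no room for
a slow warm-up. Two summary statistics describe the run: the mean
horizon-normalized episode return (episode return divided by the
reference horizon, so episodes cut short by a fall score the missing
steps as zero) of the final policy against the random (p = 0.5)
baseline, and the Spearman rank correlation of the learning curve with
the iteration index over the first half of training. Normalized return
is used rather than the per-achieved-step mean because the episode
starts exactly on the reference: a random policy collects near-maximal
rewards for the few steps before it falls, so a per-step mean barely
distinguishes falling immediately from climbing, while the normalized
return rewards both surviving and tracking. The `reward_fraction()`
metric of the analysis module keeps the per-achieved-step-mean
definition (a mean reward of 0.716 is "71.6% of total reward").

## Gait evaluation

`joint_correlation()` computes Pearson correlations between simulated
and reference joint series, excluding the final 0.5 s (the part of a
rollout where the model falls because the object ends); constant series
yield a flagged NA rather than NaN, and the correlation is invariant to
positive affine rescaling. `muscle_summary()` reports mean and peak
fiber force against the (scaled) isometric maximum. `grf_report()`
summarizes the vertical ground reaction per foot: peak, mean over
contact samples only (zeros excluded), and contact episodes as maximal
runs of nonzero force; the simulation reports upward-positive forces
and the report preserves a signed (negative-up) series for
comparability with force-plate-style figures. The ground reaction
resultant acts at the center of pressure — the normal-force-weighted
mean contact position, about which the net normal-force moment
vanishes.

## Known limitations

- Planar dynamics only: no ab/adduction, no out-of-plane balance; the
  3D topology is configuration, not simulation.
- Rigid tendons and straight-line paths make muscle geometry
  approximate; fiber-force magnitudes should be read as order-of-
  magnitude, not clinical.
- The synthetic references are kinematically plausible but not
  dynamically consistent, which caps the achievable imitation reward
  below 1 even for an ideal tracker.
- Desk-scale training budgets demonstrate learning trends, not
  converged gaits; reproducing multi-day training outcomes is out of
  scope by design.
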