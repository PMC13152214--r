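---
title: "Delayed feedback, minimum-time feedforward, and body size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed feedback, minimum-time feedforward, and body size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the numerical
decisions behind them: what is simulated, which quantities are optimized
under which constraints, where the defaults come from, and what the test
suite does and does not establish.

## The two plants

Both tasks are single-degree-of-freedom pendulums driven by a muscle torque
and gravity.

**Swing.** The forelimb is a distributed-mass pendulum about the shoulder,
angle zero hanging vertically down, counterclockwise positive:

$$I_{limb}\,\ddot\theta = \tau_{act} - M_{limb}\,g\,L_{COM}\sin\theta .$$

Gravity is restoring. The task is a 30° repositioning from rest at −15° to
rest at +15°, the stumble-correction movement after a trip. The default
movement size is the one for which sensorimotor and inertial delays match
in a 1 kg animal; `task_config(movement_deg =)` changes it.

**Posture.** The whole body is a point mass on a rigid leg-length lever,
angle zero vertically up:

$$I\,\ddot\theta = \tau_{act} + M\,g\,L\sin\theta, \qquad I = M L^2 .$$

Gravity is destabilizing. The perturbation is an impulsive push that sets
an initial angular velocity but leaves the position at vertical. To give
animals of all sizes dynamically similar pushes, the linear velocity is
Froude-scaled: $v = 0.21\sqrt{gL}$, so $\omega_0 = 0.21\sqrt{g/L}$. The
phrase "dimensionless velocity 0.21" admits a second reading,
$v=\sqrt{0.21\,gL}$; we use the first (the standard definition of
dimensionless speed) and expose it as the `froude` argument so the other
convention is one call away.

## Controllers

**Delayed PD feedback.** The desired torque is zero during an initial
deadtime equal to the sensorimotor delay $t_{SM}$ (sensing, conduction,
synaptic, neuromuscular and force-generation latencies lumped into one
deadtime), and afterwards acts on state information that is $t_{SM}$ old:

$$\tau_{des}(t) = K_p\,[\theta_r - \theta(t-t_{SM})] +
K_d\,[-\dot\theta(t-t_{SM})] + \tau_{ss},$$

clamped to $[-\tau_{iso}, +\tau_{iso}]$. The steady-state torque
$\tau_{ss}$ is not a free parameter: it is fixed analytically to the torque
that balances gravity at the target, $M_{limb}\,g\,L_{COM}\sin\theta_r$ for
swing and zero for posture (vertical target). Fixing it analytically
removes one optimization dimension and matches its defining role.

**Minimum-time feedforward.** The open-loop benchmark: zero torque during
the deadtime, then $+\tau_{iso}$ toward the target until a switch time,
then $-\tau_{iso}$ until the plant comes to rest. For the posture task the
first phase opposes the perturbation velocity (minimum-time control always
brakes toward the target first in this geometry). The single free
parameter is the switch time.

## Numerical engine

The closed loop is a delay differential equation. It is integrated by the
method of steps with a fixed-step classical Runge–Kutta scheme implemented
in C++: the step is $h = t_{SM}/n$ (default $n = 200$), so every
discontinuity that propagates from the deadtime switch lands exactly on a
grid node and no RK step straddles it. The delayed state at stage midpoints
is reconstructed by cubic Hermite interpolation from stored states and
derivatives, which is $O(h^4)$ and consistent with the integrator's order.
A fixed, delay-aligned step was chosen over an adaptive integrator because
the optimizers call the engine tens of thousands of times; at $n = 200$ the
settling time is converged to well below 0.1% (doubling $n$ is a standing
test), and the tests cross-check whole trajectories against `deSolve`'s
independent adaptive DDE solver to $10^{-4}$.

The feedforward runs are ordinary ODEs integrated the same way, segment by
segment (torque is constant within a segment). The "comes to rest" event
is the first zero-crossing of $\omega$ after the switch, located on the
Hermite interpolant by bisection; a run with no crossing inside the safety
horizon ($50\,t_{SM}$) is flagged `no_rest` rather than raising.

State blow-ups (non-finite or absurdly large values) set a `diverged` flag,
and non-settling runs return an `Inf` settling time, so optimizers can
penalize both without exception handling.

## Response metrics

*Response time* is the 2% settling time measured from perturbation onset:
the **last** time the monitored signal exits the band (the standard
control-theory definition; first-entry would be shorter whenever the
response rings). For swing the band is $\theta_r \pm 0.02\,|\theta_r -
\theta_0|$ on the angle; for posture it is $\pm 0.02\,|\omega_0|$ on the
angular velocity — the band normalizer is the perturbation magnitude, the
natural scale of a velocity perturbation. Band crossings are refined by
linear interpolation between stored samples.

*Overshoot* is the excursion of the angle past the target in the direction
of motion (swing) or past vertical on the side opposite the push (posture),
and is constrained to zero in all optimizations, matching a critically
damped response.

## Gain optimization

`optimize_gains` minimizes settling time over $(K_p, K_d)$ subject to the
zero-overshoot constraint. Numerical choices that matter:

- **Overshoot tolerance.** Literal zero is unattainable in floating point.
  The tolerance is $10^{-6}$ of the movement (swing) or $10^{-6}$ rad
  (posture). This is deliberately much tighter than a "small" tolerance
  like $10^{-4}$: the optimum sits on the constraint boundary and trades
  overshoot for settling time at a steep rate, so at $10^{-4}$ the
  recovered optimum is visibly biased (on the dimensionless system,
  settling 6.94 instead of 7.07 and $\bar K_p$ 0.1642 instead of 0.1628).
  Between $10^{-6}$ and $10^{-8}$ the optimum moves by under 0.05%, so
  $10^{-6}$ is converged.
- **Search.** Gains live in log space (they are positive and scale over
  ten orders across the size grid). The landscape is jagged: the last-exit
  settling time jumps whenever a ring peak crosses the 2% band, and the
  global optimum is a narrow notch. The global phase therefore scans a
  13×13 log-spaced grid (half-width 0.5 decades) around a
  dimensional-analysis center — the dimensionless optimum rescaled by
  $I/t_{SM}^2$ and $I/t_{SM}$, shifted by the local gravitational
  stiffness $\mp M g L \cos\theta_r$ — and the three best grid points seed
  Nelder–Mead refinement with restarts. Scattered multi-start simplex
  alone misses the notch at some sizes (e.g. the 10 kg posture optimum,
  where it lands 45% high).
- **Penalty.** Constraint violations add an exact penalty proportional to
  the excess overshoot; non-settling runs score horizon-plus-delay, keeping
  the objective finite and ordered so the simplex can escape.
- **Task completion (posture).** Velocity-band settling plus zero
  angle-overshoot is also satisfied by a *non-stabilizing* controller with
  $K_p < MgL$ whose divergence is slower than the 20 $t_{SM}$ horizon: it
  "rests while leaning", with the velocity inside the band and the angle
  never returning. Such gains would be preferred by the raw objective
  (they settle the velocity faster) but do not perform the task, which is
  to return to rest *at vertical*. A run therefore counts as settled only
  if its final angular deviation is below 10% of its peak deviation;
  stabilized responses end near 0.1% of peak and drifting ones at 100%, so
  the threshold is uncritical across two orders of magnitude.

`optimize_switch_time` exploits the monotonicity of the rest position in
the switch time: a scan over $(t_{SM}, 50\,t_{SM}]$ brackets the root of
$\theta(t_{end}) - \theta_r$ and Brent's method polishes it to $10^{-9}$ s.
Runaway runs (switching before the posture apex, so the post-switch torque
feeds the fall) are assigned a large signed residual on the side the angle
escaped to, which keeps the scan's sign pattern monotone.

Everything is deterministic — grid starts, simplex, bisection — so
identical seeds trivially reproduce identical results; the seed is recorded
in every result object for provenance.

## The dimensionless model and the capacity sweep

Dividing the gravity-free feedback system by $I\theta_r/t_{SM}^2$ leaves
unit delay, unit inertia and unit reference; the only free parameter is
$\bar\tau_{iso} = \tau_{iso} t_{SM}^2 / (I\theta_r)$. The package optimizes
this system per capacity value on a descending sweep, warm-starting each
point at its neighbour's optimum (the middle and low regions have many
near-degenerate local minima; warm starts keep the gain curves smooth). A
warm start that fails re-runs with the full-width grid before the point is
recorded infeasible. Saturation is detected when a peak torque reaches
$(1-10^{-6})\,\bar\tau_{iso}$, and the three regimes are read off the
saturation flags: high (no saturation — delay-limited), middle (positive
torque clips), low (both clip). Near $\bar\tau_{iso} \approx 0.01$ the
optimal settling time approaches the 20-delay horizon, which is where the
feasible range bottoms out; the package reports that floor empirically
rather than asserting a value.

The posture variant of the normalized model (unit velocity push, velocity
normalization) is provided for completeness but is exploratory: the main
analyses use the swing variant, and no published benchmark pins the
posture normalization constant.

## Parameter laws and the size grid

All inputs are allometric power laws $a\,M^b$, shipped as a plain CSV
(task, parameter, coefficient, exponent, units) and converted to strict SI
at ingestion — milliseconds become seconds the moment a law is
materialized, so the DDE engine never sees mixed units. The posture
maximum torque coefficient (3.41 N·m at 1 kg) is taken as already including
the four-legged plantarflexor factor and is not re-multiplied. The size
grid is the study's: eight logarithmic decades from 1 g to 10 t plus 5 g
and 5 t, ten sizes, all of which enter the output regressions. Power-law
fits are ordinary least squares on $\log_{10}$ mass vs $\log_{10}$ output
(the log base is immaterial to the fit), with $r^2$ reported on the log
scale.

Available movement times close the loop on "fast enough": the swing-task
budget is the swing duration at maximum sprint speed, used as printed
(147.9 $M^{0.17}$ ms — its derivation lives in the locomotion literature,
not here), while the posture budget is derived in closed form as the
free-fall time through the leg length, $\sqrt{2L/g}$, which reproduces the
printed 182 $M^{0.19}$ ms law to within rounding (the exact exponent is
$b_L/2 = 0.185$).

## What the tests show, and what they do not

The synthetic inputs *are* the study conditions — parameter laws, the
ten-size grid, the 30° movement, the 0.21 push — not a calibration dial;
none of them were adjusted to any output. The suite establishes: agreement
of the engine with an independent adaptive DDE solver; exact closed-form
behaviour of the bang-bang controller on the double integrator; exact
power-law recovery; equivalence of the dimensional and dimensionless
optima under the analytic rescaling; movement-size invariance of linear
feedback settling; and end-to-end reproduction of the study's headline
numbers (dimensionless optimum, capacity-region boundary, both tasks'
response-time scaling laws, delay multiples and strategy ratios).

What passing does **not** show: anything about real muscle (no Hill-type
dynamics, force-velocity limits, pennation, or tendon compliance — force
rise is folded into the deadtime), multi-joint or multi-muscle limbs,
sensor noise, continuous or repeated perturbations, spinal rhythm
generators or preflexes. The models bound what *any* monosynaptic
reflex-latency controller could do; they do not describe what a particular
animal's nervous system does.

Two reproduction caveats are worth recording. First, at the published 1 kg
posture gains this engine's last-exit settling time is ~377 ms rather than
the published 239 ms — tiny late ripples re-exit the 2% velocity band;
the *re-optimized* gains avoid the ripples and land within ~1% of the
published gains and response time, so optimization, not gain transcription,
is the comparable operation. Second, all "fastest" claims are to the
optimizer's resolution; the landscape's flat near-degenerate minima mean
gains can differ by a few percent between equally fast solutions (visible
as scatter in the middle/low sweep regions).

## Problem sizes

The shipped analyses use the study's own sizes throughout: ten body
masses, a 0.005-step coarse capacity sweep over [0.005, 0.25] with
0.001-step refinement near the detected boundary, 200 integration steps
per delay, and 20-delay horizons. One task pipeline is ~30 s on one CPU;
the full analysis set is a few minutes.
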