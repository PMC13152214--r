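# neuroscale

Neuromechanical models of fast perturbation responses in terrestrial
mammals, from 1 g to 10 t. The package asks a simple question with two
well-defined controllers: when an animal must reposition a limb after a
trip, or catch itself after a push, is its response speed limited by its
sensorimotor delays or by the strength of its muscles — and how does the
answer change with body size?

It is aimed at computational neuromechanics and comparative biomechanics
work: everything is a small pendulum model with published allometric
parameter laws, so every result is reproducible from scratch on a laptop.

## Models

Two tasks, one plant equation each:

- **Swing task** — a distributed-mass pendulum (the forelimb about the
  shoulder): `I_limb θ̈ = τ_act − M_limb g L_COM sin θ`, repositioned from
  −15° to +15°.
- **Posture task** — a point-mass inverted pendulum (the body on a
  leg-length lever): `I θ̈ = τ_act + M g L sin θ`, pushed with a
  Froude-scaled impulsive velocity (dimensionless velocity 0.21) and
  returned to rest at vertical.

Two controllers bound the strategy space:

- **Delayed PD feedback**:
  `τ_des(t) = Kp [θ_r − θ(t−t_SM)] + Kd [−θ̇(t−t_SM)] + τ_ss` after an
  initial deadtime `t_SM` (the sensorimotor delay), saturated at the
  maximum isometric torque `±τ_iso`. Gains are optimized for the fastest
  2% settling time with zero overshoot.
- **Minimum-time feedforward**: open-loop bang-bang torque, `+τ_iso` then
  `−τ_iso` after an optimized switch time, the theoretical upper bound on
  response speed.

Dropping gravity and rescaling by the delay, the inertia and the movement
size collapses the feedback system to a single free parameter, the
dimensionless force capacity `τ̄_iso = τ_iso t_SM² / (I θ_r)`, which cleanly
separates a delay-limited regime from a force-limited one.

All physical parameters come from allometric power laws `a · M^b`
(sensorimotor delay, limb inertia and geometry, maximum torque), shipped as
a plain CSV in `inst/extdata/`, and the closed-loop system is integrated by
a method-of-steps Runge–Kutta scheme (in C++) whose step divides the delay
exactly, so the torque discontinuities always fall on grid nodes.

## Worked example

The dimensionless benchmark — the fastest stable response a delayed
feedback loop can produce with unlimited muscle:

```r
library(neuroscale)
opt <- optimize_normalized_gains()
opt
#> feedback optimum: kp = 0.16283, kd = 0.63713 (converged: TRUE)
#> response time 7.0656 s, overshoot 1e-06 rad, peak torque [-0.0962, 0.163] N.m, torque fraction 0
```

Even with no force limit at all, the optimal zero-overshoot response needs
about seven delay periods to settle, and never asks for more than ~0.16
units of dimensionless torque — the delay, not the actuator, is the
binding constraint. The peak accelerating torque equals `K̄p` exactly (the
first post-deadtime torque sample is `K̄p · [1 − θ̄(0)]`).

A scaled animal, same machinery:

```r
params <- animal_parameters("swing", 1)   # a 1 kg animal's forelimb
cfg    <- task_config(params)             # -15 deg -> +15 deg after a trip
fb     <- optimize_gains(params, cfg)
ff     <- optimize_switch_time(params, cfg)
round(1000 * c(feedback = fb$metrics$response_time,
               feedforward = ff$metrics$response_time))
#> feedback feedforward
#>      200          61
```

The feedback response (200 ms, ~6.4 delays) is over three times slower than
the minimum-time benchmark and uses only ~3% of the available muscle
torque. `run_task_scaling("swing")` repeats this across ten body masses and
fits the output power laws; `analysis/01_...R` through `05_...R` walk
through the whole study (normalized optimum, force-capacity sweep, both
task pipelines, strategy comparison) and write their tables under
`results/`.

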