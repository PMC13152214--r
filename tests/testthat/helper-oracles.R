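# Shared fixtures and independent oracles, built in code at test time.

# a minimal parameter set for the unit plant (delay 1, inertia 1)
unit_params <- function(tau_iso = Inf, t_sm = 1, inertia = 1,
                        task = "swing") {
  structure(list(task = task, body_mass = 1, t_sm = t_sm, inertia = inertia,
                 limb_mass = 0, l_com = 1, tau_iso = tau_iso, g = 9.81),
            class = "animal_params")
}

# hand-built task configurations (bypassing task_config for synthetic cases)
step_cfg <- function(theta0 = 0, theta_ref = 1, omega0 = 0) {
  structure(list(task = "swing", theta0 = theta0, omega0 = omega0,
                 theta_ref = theta_ref,
                 movement = abs(theta_ref - theta0),
                 angle_convention = "synthetic"),
            class = "task_config")
}
push_cfg <- function(omega0 = 1) {
  structure(list(task = "posture", theta0 = 0, omega0 = omega0,
                 theta_ref = 0, movement = abs(omega0),
                 angle_convention = "synthetic"),
            class = "task_config")
}

# wrap plain vectors as a trajectory object for the metric functions
make_traj <- function(t, theta, omega = rep(0, length(t)),
                      tau_act = rep(0, length(t)), task = "swing",
                      tau_iso = Inf, t_sm = 1, control = "feedback") {
  structure(list(t = t, theta = theta, omega = omega, tau_act = tau_act,
                 tau_gravity = rep(0, length(t)), diverged = FALSE,
                 task = task, t_sm = t_sm, tau_iso = tau_iso,
                 horizon = if (length(t)) max(t) else 0, control = control),
            class = "neuroscale_trajectory")
}

# Independent oracle for the closed-loop delayed-PD system: deSolve's
# adaptive delay-differential solver with its own history interpolation.
# Returns theta sampled at `times`.
dede_feedback_oracle <- function(params, gains, cfg, horizon,
                                 tau_iso = Inf, grav_coef = 0,
                                 n_out = 2000) {
  t_sm <- params$t_sm
  deriv <- function(t, y, parms) {
    if (t < t_sm) {
      tau <- 0
    } else {
      tl <- t - t_sm
      lag <- if (tl <= 1e-12) {
        c(cfg$theta0, cfg$omega0)
      } else {
        deSolve::lagvalue(tl)
      }
      tau_des <- gains$kp * (cfg$theta_ref - lag[1]) - gains$kd * lag[2] +
        gains$tau_steadystate
      tau <- min(max(tau_des, -tau_iso), tau_iso)
    }
    list(c(y[2], (tau + grav_coef * sin(y[1])) / params$inertia))
  }
  times <- seq(0, horizon, length.out = n_out + 1)
  # give the solver the deadtime breakpoint by splitting at multiples of t_sm
  times <- sort(unique(c(times, seq(0, horizon, by = t_sm))))
  out <- deSolve::dede(c(cfg$theta0, cfg$omega0), times, deriv, parms = NULL,
                       rtol = 1e-10, atol = 1e-12)
  list(t = out[, 1], theta = out[, 2], omega = out[, 3])
}

# linear interpolation lookup of a trajectory's angle at arbitrary times
traj_theta_at <- function(traj, times) {
  stats::approx(traj$t, traj$theta, xout = times, rule = 2)$y
}
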