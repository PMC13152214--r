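#' Simulate the closed-loop delayed feedback response
#'
#' Integrates the plant under saturated, delayed PD control by the method of
#' steps: a fixed-step classical Runge-Kutta scheme whose step divides the
#' sensorimotor delay exactly, so every discontinuity propagating from the
#' end of the deadtime lands on a grid node. The history for \code{t < 0} is
#' the constant initial state; during the deadtime the controller applies no
#' torque and the plant moves under gravity alone.
#'
#' @param params \code{\link{animal_parameters}} (or any list with
#'   \code{task}, \code{t_sm}, \code{inertia}, \code{tau_iso} and the
#'   gravity fields).
#' @param gains \code{\link{feedback_gains}}.
#' @param cfg \code{\link{task_config}}.
#' @param horizon Simulation horizon, s; default \code{20 * t_sm} (rounded
#'   up internally to a whole number of delay intervals).
#' @param include_gravity Set \code{FALSE} to drop the gravitational torque
#'   (used by the dimensionless model and linearity checks).
#' @param tau_iso Force-capacity limit override, N m (may be \code{Inf}).
#' @param steps_per_delay Integration steps per delay interval (default 200).
#' @return An object of class \code{neuroscale_trajectory}: a list with
#'   numeric vectors \code{t}, \code{theta}, \code{omega}, \code{tau_act},
#'   \code{tau_gravity} and flags \code{diverged}, plus the task, delay and
#'   torque limit used. Non-finite blow-ups set \code{diverged = TRUE}
#'   rather than raising.
#' @export
simulate_feedback <- function(params, gains, cfg, horizon = NULL,
                              include_gravity = TRUE,
                              tau_iso = params$tau_iso,
                              steps_per_delay = 200L) {
  stopifnot(inherits(gains, "feedback_gains"), params$t_sm > 0,
            params$inertia > 0, tau_iso > 0)
  if (is.null(horizon)) horizon <- 20 * params$t_sm
  stopifnot(horizon > 0)
  gc_ <- if (include_gravity) gravity_coefficient(cfg$task, params) else 0
  raw <- sim_feedback_cpp(params$inertia, params$t_sm, gains$kp, gains$kd,
                          gains$tau_steadystate, tau_iso, cfg$theta_ref,
                          cfg$theta0, cfg$omega0, gc_, horizon,
                          as.integer(steps_per_delay))
  structure(list(t = raw$t, theta = raw$theta, omega = raw$omega,
                 tau_act = raw$tau_act, tau_gravity = gc_ * sin(raw$theta),
                 diverged = raw$diverged, task = cfg$task,
                 t_sm = params$t_sm, tau_iso = tau_iso,
                 horizon = horizon, control = "feedback"),
            class = "neuroscale_trajectory")
}

#' Simulate the bang-bang feedforward response
#'
#' Integrates the plant under the open-loop minimum-time torque profile
#' (deadtime, maximal torque, maximal opposing torque) and terminates at the
#' first zero-crossing of the angular velocity after the switch time ("comes
#' to rest"); the elapsed time is the response time.
#'
#' @param params \code{\link{animal_parameters}}.
#' @param plan \code{\link{feedforward_plan}} with
#'   \code{t_switch > params$t_sm}.
#' @param cfg \code{\link{task_config}}.
#' @param include_gravity Set \code{FALSE} to drop gravity.
#' @param tau_iso Force-capacity override, N m (must be finite and > 0).
#' @param horizon Safety horizon, s; default \code{50 * t_sm}. If the plant
#'   never comes to rest within it the trajectory is flagged
#'   \code{no_rest = TRUE}.
#' @param steps_per_delay Sets the target step \code{t_sm / steps_per_delay}.
#' @return A \code{neuroscale_trajectory} with additional fields
#'   \code{t_end}, \code{theta_end}, \code{no_rest}.
#' @export
simulate_feedforward <- function(params, plan, cfg, include_gravity = TRUE,
                                 tau_iso = params$tau_iso, horizon = NULL,
                                 steps_per_delay = 200L) {
  stopifnot(inherits(plan, "feedforward_plan"), plan$t_switch > params$t_sm,
            is.finite(tau_iso), tau_iso >= 0)
  if (is.null(horizon)) horizon <- 50 * params$t_sm
  stopifnot(horizon > plan$t_switch)
  gc_ <- if (include_gravity) gravity_coefficient(cfg$task, params) else 0
  h_target <- params$t_sm / steps_per_delay
  raw <- sim_feedforward_cpp(params$inertia, params$t_sm, plan$t_switch,
                             plan$direction, tau_iso, cfg$theta0, cfg$omega0,
                             gc_, horizon, h_target)
  structure(list(t = raw$t, theta = raw$theta, omega = raw$omega,
                 tau_act = raw$tau_act, tau_gravity = gc_ * sin(raw$theta),
                 diverged = raw$diverged, no_rest = !raw$event,
                 t_end = raw$t_end, theta_end = raw$theta_end,
                 task = cfg$task, t_sm = params$t_sm, tau_iso = tau_iso,
                 horizon = horizon, control = "feedforward"),
            class = "neuroscale_trajectory")
}

#' @export
print.neuroscale_trajectory <- function(x, ...) {
  cat(sprintf("%s %s trajectory: %d samples over %.4g s%s\n", x$task,
              x$control, length(x$t), max(x$t),
              if (isTRUE(x$diverged)) " [diverged]" else ""))
  invisible(x)
}

# linear interpolation of the time at which y crosses the level `band`
# between samples k and k+1
.cross_time <- function(t, y, k, band) {
  y0 <- y[k]; y1 <- y[k + 1]
  if (y1 == y0) return(t[k + 1])
  t[k] + (band - y0) / (y1 - y0) * (t[k + 1] - t[k])
}

#' Settling time of a response
#'
#' The response time: the last time the monitored signal exits a 2 percent
#' band, measured from perturbation onset. For the swing task the band is
#' \code{theta_ref +/- 0.02 * |theta_ref - theta0|} on the angle curve (2
#' percent of the entire movement); for the posture task it is
#' \code{0 +/- 0.02 * |omega0|} on the angular velocity curve (2 percent of
#' the perturbation velocity). The crossing is refined by linear
#' interpolation between stored samples. Returns \code{Inf} if the signal is
#' still outside the band at the end of the horizon (or the run diverged).
#'
#' @param traj A \code{neuroscale_trajectory}.
#' @param cfg The \code{\link{task_config}} used to produce it.
#' @param threshold Band half-width as a fraction of the movement
#'   (default 0.02).
#' @return Settling time in s (\code{Inf} if never settled).
#' @export
settling_time <- function(traj, cfg, threshold = 0.02) {
  if (length(traj$t) == 0L) stop("empty trajectory")
  if (isTRUE(traj$diverged)) return(Inf)
  if (cfg$task == "posture") {
    y <- traj$omega
    centre <- 0
    half <- threshold * abs(cfg$omega0)
  } else {
    y <- traj$theta
    centre <- cfg$theta_ref
    half <- threshold * abs(cfg$theta_ref - cfg$theta0)
  }
  outside <- abs(y - centre) > half
  if (!any(outside)) return(0)
  k <- max(which(outside))
  if (k == length(y)) return(Inf)
  band <- if (y[k] > centre + half) centre + half else centre - half
  .cross_time(traj$t, y, k, band)
}

#' Overshoot of the angle curve
#'
#' Swing: the maximal excursion of the angle past the reference target in
#' the direction of motion. Posture: the maximal excursion of the angle past
#' vertical on the side opposite the initial push. Zero for a monotone
#' (critically-damped-like) approach; the optimizers constrain it to zero.
#'
#' @param traj A \code{neuroscale_trajectory}.
#' @param cfg The \code{\link{task_config}} used to produce it.
#' @return Overshoot in rad, >= 0.
#' @export
overshoot <- function(traj, cfg) {
  if (length(traj$t) == 0L) stop("empty trajectory")
  if (cfg$task == "posture") {
    s0 <- sign(cfg$omega0)
    if (s0 == 0) return(0)
    max(0, max(-s0 * traj$theta))
  } else {
    s <- sign(cfg$theta_ref - cfg$theta0)
    max(0, max(s * (traj$theta - cfg$theta_ref)))
  }
}

#' Peak applied torques and torque fraction
#'
#' @param traj A \code{neuroscale_trajectory}.
#' @return A list with \code{peak_tau_pos} (max applied torque, N m),
#'   \code{peak_tau_neg} (min applied torque, N m) and
#'   \code{torque_fraction} = \code{max(|tau_act|) / tau_iso} (0 when the
#'   force capacity is unbounded).
#' @export
peak_torques <- function(traj) {
  if (length(traj$t) == 0L) stop("empty trajectory")
  pos <- max(traj$tau_act)
  neg <- min(traj$tau_act)
  frac <- if (is.finite(traj$tau_iso)) {
    max(abs(pos), abs(neg)) / traj$tau_iso
  } else {
    0
  }
  list(peak_tau_pos = pos, peak_tau_neg = neg, torque_fraction = frac)
}

#' Response metrics of a simulated perturbation response
#'
#' @param traj A \code{neuroscale_trajectory}.
#' @param cfg The \code{\link{task_config}} used to produce it.
#' @param threshold Settling band half-width fraction (default 0.02).
#' @return An object of class \code{response_metrics}: \code{response_time}
#'   (s; for feedforward runs the event time, for feedback runs the settling
#'   time), \code{overshoot} (rad), \code{peak_tau_pos}, \code{peak_tau_neg}
#'   (N m), \code{torque_fraction}, \code{settled}, \code{diverged}.
#' @export
response_metrics <- function(traj, cfg, threshold = 0.02) {
  pk <- peak_torques(traj)
  rt <- if (identical(traj$control, "feedforward")) {
    if (isTRUE(traj$no_rest)) Inf else traj$t_end
  } else {
    settling_time(traj, cfg, threshold)
  }
  structure(list(response_time = rt, overshoot = overshoot(traj, cfg),
                 peak_tau_pos = pk$peak_tau_pos,
                 peak_tau_neg = pk$peak_tau_neg,
                 torque_fraction = pk$torque_fraction,
                 settled = is.finite(rt),
                 diverged = isTRUE(traj$diverged)),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf(paste0("response time %.5g s, overshoot %.3g rad, ",
                     "peak torque [%.3g, %.3g] N.m, torque fraction %.3g\n"),
              x$response_time, x$overshoot, x$peak_tau_neg, x$peak_tau_pos,
              x$torque_fraction))
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' Columns t, theta, omega, tau_act, tau_gravity; one row per stored sample.
#'
#' @param traj A \code{neuroscale_trajectory}.
#' @param path Output file path.
#' @return The data.frame written, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$t, theta = traj$theta, omega = traj$omega,
                   tau_act = traj$tau_act, tau_gravity = traj$tau_gravity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Plot angle, angular velocity and torque profiles
#'
#' Three stacked base-graphics panels of the stored trajectory.
#'
#' @param x A \code{neuroscale_trajectory}.
#' @param ... Passed to \code{plot}.
#' @export
plot.neuroscale_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$theta, type = "l", xlab = "time (s)",
                 ylab = "angle (rad)", ...)
  graphics::plot(x$t, x$omega, type = "l", xlab = "time (s)",
                 ylab = "angular velocity (rad/s)", ...)
  graphics::plot(x$t, x$tau_act, type = "l", xlab = "time (s)",
                 ylab = "torque (N.m)", ...)
  invisible(x)
}
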