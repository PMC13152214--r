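#' Task configuration
#'
#' Builds the initial state, reference target and perturbation for a task.
#'
#' Swing: the limb is repositioned from \code{-movement_deg/2} to
#' \code{+movement_deg/2} (default a 30 degree movement from -15 to +15
#' degrees), starting and ending at rest. Angle zero is the limb hanging
#' vertically down, counterclockwise positive.
#'
#' Posture: the body starts upright (\code{theta0 = theta_ref = 0}, angle
#' zero vertically up, counterclockwise positive) with an initial angular
#' velocity from an impulsive push, Froude-scaled so animals of all sizes
#' receive dynamically similar perturbations:
#' \code{omega0 = froude * sqrt(g / L)} with \code{L} the leg length.
#'
#' @param params An \code{\link{animal_parameters}} object (or any list with
#'   \code{task}, \code{l_com} and \code{g} for posture).
#' @param movement_deg Swing movement size in degrees (default 30).
#' @param froude Dimensionless perturbation velocity for posture
#'   (default 0.21).
#' @return An object of class \code{task_config} with \code{task},
#'   \code{theta0}, \code{omega0}, \code{theta_ref} (rad, rad/s),
#'   \code{movement} (rad for swing, \code{|omega0|} rad/s for posture) and
#'   \code{angle_convention}.
#' @export
task_config <- function(params, movement_deg = 30, froude = 0.21) {
  task <- match.arg(params$task, c("swing", "posture"))
  if (task == "swing") {
    half <- movement_deg / 2 * pi / 180
    structure(list(task = "swing", theta0 = -half, omega0 = 0,
                   theta_ref = +half, movement = 2 * half,
                   angle_convention = "0 = vertically down, CCW positive"),
              class = "task_config")
  } else {
    omega0 <- froude * sqrt(params$g / params$l_com)
    structure(list(task = "posture", theta0 = 0, omega0 = omega0,
                   theta_ref = 0, movement = abs(omega0),
                   angle_convention = "0 = vertically up, CCW positive"),
              class = "task_config")
  }
}

#' Gravitational torque on the pendulum plant
#'
#' Swing (hanging pendulum): \code{-limb_mass * g * l_com * sin(theta)},
#' restoring toward the vertical. Posture (inverted pendulum):
#' \code{+body_mass * g * l_com * sin(theta)}, destabilizing away from the
#' vertical.
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param params \code{\link{animal_parameters}} for the task.
#' @param theta Angle in rad (vectorized).
#' @return Torque in N m.
#' @export
gravity_torque <- function(task, params, theta) {
  task <- match.arg(task, c("swing", "posture"))
  gravity_coefficient(task, params) * sin(theta)
}

# signed prefactor of sin(theta) in the gravity torque
gravity_coefficient <- function(task, params) {
  if (task == "swing") {
    -params$limb_mass * params$g * params$l_com
  } else {
    +params$body_mass * params$g * params$l_com
  }
}

#' Actuator saturation
#'
#' Clamps a desired torque to the muscle force-capacity limits
#' \code{[-tau_iso, +tau_iso]}.
#'
#' @param tau_des Desired torque, N m (vectorized).
#' @param tau_iso Maximum isometric torque, N m, > 0 (may be \code{Inf}).
#' @return The applied torque, N m.
#' @export
saturate <- function(tau_des, tau_iso) {
  stopifnot(tau_iso > 0)
  pmin(pmax(tau_des, -tau_iso), tau_iso)
}

#' Feedback controller gains
#'
#' @param kp Proportional gain, N m/rad, >= 0.
#' @param kd Derivative gain, N m/(rad/s), >= 0.
#' @param tau_steadystate Constant torque countering gravity at the target
#'   (N m); 0 for the posture task, which has no gravitational torque at its
#'   upright target.
#' @return An object of class \code{feedback_gains}.
#' @export
feedback_gains <- function(kp, kd, tau_steadystate = 0) {
  stopifnot(is.finite(kp), kp >= 0, is.finite(kd), kd >= 0,
            is.finite(tau_steadystate))
  structure(list(kp = kp, kd = kd, tau_steadystate = tau_steadystate),
            class = "feedback_gains")
}

#' Steady-state torque countering gravity at the target
#'
#' The constant torque that balances gravity once the plant has settled at
#' the reference target: \code{limb_mass * g * l_com * sin(theta_ref)} for
#' the swing task and 0 for the posture task (vertical target).
#'
#' @param params \code{\link{animal_parameters}}.
#' @param cfg \code{\link{task_config}}.
#' @return Torque in N m.
#' @export
steady_state_torque <- function(params, cfg) {
  if (cfg$task == "swing") {
    -gravity_torque("swing", params, cfg$theta_ref)
  } else {
    0
  }
}

#' Delayed PD desired torque
#'
#' The proportional-derivative control law on state information delayed by
#' the sensorimotor delay, with an initial deadtime during which the
#' controller produces no torque:
#' \code{0} for \code{t < t_sm}, otherwise
#' \code{kp * (theta_ref - theta_delayed) - kd * omega_delayed +
#' tau_steadystate}. Unsaturated (apply \code{\link{saturate}} to get the
#' actual torque).
#'
#' @param gains \code{\link{feedback_gains}}.
#' @param theta_delayed Angle at \code{t - t_sm}, rad.
#' @param omega_delayed Angular velocity at \code{t - t_sm}, rad/s.
#' @param theta_ref Reference target, rad.
#' @param t Current time, s, >= 0 (vectorized along with the delayed state).
#' @param t_sm Sensorimotor delay, s.
#' @return Desired torque, N m.
#' @export
pd_torque <- function(gains, theta_delayed, omega_delayed, theta_ref, t, t_sm) {
  stopifnot(all(t >= 0))
  ifelse(t < t_sm, 0,
         gains$kp * (theta_ref - theta_delayed) - gains$kd * omega_delayed +
           gains$tau_steadystate)
}

#' Bang-bang feedforward plan
#'
#' @param t_switch Time at which the torque reverses sign, s; must exceed
#'   the sensorimotor deadtime.
#' @param direction Sign of the first torque phase: +1 or -1.
#' @return An object of class \code{feedforward_plan}.
#' @export
feedforward_plan <- function(t_switch, direction = 1) {
  stopifnot(is.finite(t_switch), t_switch > 0, direction %in% c(-1, 1))
  structure(list(t_switch = t_switch, direction = direction),
            class = "feedforward_plan")
}

#' Bang-bang feedforward torque
#'
#' Minimum-time open-loop actuation: zero during the sensorimotor deadtime,
#' then maximal torque in the movement direction until the switch time, then
#' maximal opposing torque.
#'
#' @param plan \code{\link{feedforward_plan}}; \code{plan$t_switch} must
#'   exceed \code{t_sm}.
#' @param t Time, s (vectorized).
#' @param t_sm Sensorimotor delay (deadtime), s.
#' @param tau_iso Maximum isometric torque, N m.
#' @return Applied torque, N m.
#' @export
bang_bang_torque <- function(plan, t, t_sm, tau_iso) {
  stopifnot(plan$t_switch > t_sm)
  ifelse(t < t_sm, 0,
         ifelse(t < plan$t_switch, plan$direction * tau_iso,
                -plan$direction * tau_iso))
}

#' Angular acceleration of the plant
#'
#' Torque balance: \code{(tau_act + gravity_torque) / inertia}.
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param params \code{\link{animal_parameters}}.
#' @param theta Angle, rad.
#' @param tau_act Applied torque, N m.
#' @return Angular acceleration, rad/s^2.
#' @export
angular_acceleration <- function(task, params, theta, tau_act) {
  (tau_act + gravity_torque(task, params, theta)) / params$inertia
}
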