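#' Dimensionless feedback model configuration
#'
#' The normalized feedback system: gravity dropped, and time, inertia and
#' perturbation size scaled out so that the delay, the inertia and the
#' reference are all unity. Torques are expressed in units of
#' \code{I * theta_r / t_sm^2}, so the force capacity
#' \code{tau_iso_bar = tau_iso / (I * theta_r / t_sm^2)} is the single free
#' parameter; gains normalize as \code{kp_bar = kp * t_sm^2 / I} and
#' \code{kd_bar = kd * t_sm / I}, and times as \code{t_bar = t / t_sm}.
#'
#' @param tau_iso_bar Dimensionless force capacity (may be \code{Inf}).
#' @param gains_bar Dimensionless gains \code{c(kp_bar, kd_bar)}.
#' @param variant \code{"swing"} (step to a unit reference from rest) or
#'   \code{"posture"} (unit velocity perturbation at the origin; this
#'   variant normalizes the perturbation by the initial velocity and is
#'   exploratory).
#' @return An object of class \code{normalized_config}.
#' @export
normalized_config <- function(tau_iso_bar = Inf, gains_bar = c(0, 0),
                              variant = c("swing", "posture")) {
  variant <- match.arg(variant)
  stopifnot(tau_iso_bar > 0, length(gains_bar) == 2, all(gains_bar >= 0))
  structure(list(tau_iso_bar = tau_iso_bar, gains_bar = gains_bar,
                 variant = variant),
            class = "normalized_config")
}

# unit plant: delay 1, inertia 1, no gravity
.unit_params <- function(task, tau_iso_bar) {
  structure(list(task = task, body_mass = 1, t_sm = 1, inertia = 1,
                 limb_mass = 0, l_com = 1, tau_iso = tau_iso_bar,
                 g = GRAVITY),
            class = "animal_params")
}

.unit_config <- function(variant) {
  if (variant == "swing") {
    structure(list(task = "swing", theta0 = 0, omega0 = 0, theta_ref = 1,
                   movement = 1,
                   angle_convention = "dimensionless step to unit reference"),
              class = "task_config")
  } else {
    structure(list(task = "posture", theta0 = 0, omega0 = 1, theta_ref = 0,
                   movement = 1,
                   angle_convention = "dimensionless unit velocity push"),
              class = "task_config")
  }
}

#' Simulate the dimensionless feedback system
#'
#' Delegates to \code{\link{simulate_feedback}} with the unit plant (unit
#' delay, unit inertia, gravity disabled). The swing variant steps from
#' state (0, 0) to the unit reference; all times in the returned trajectory
#' are in multiples of the delay and torques in units of the normalization
#' factor.
#'
#' @param cfg A \code{\link{normalized_config}}.
#' @param horizon Dimensionless horizon (default 20 delay multiples).
#' @param steps_per_delay Integration resolution.
#' @return A \code{neuroscale_trajectory} in dimensionless units.
#' @export
simulate_normalized <- function(cfg, horizon = 20, steps_per_delay = 200L) {
  stopifnot(inherits(cfg, "normalized_config"))
  params <- .unit_params(cfg$variant, cfg$tau_iso_bar)
  tcfg <- .unit_config(cfg$variant)
  simulate_feedback(params, feedback_gains(cfg$gains_bar[1], cfg$gains_bar[2]),
                    tcfg, horizon = horizon, include_gravity = FALSE,
                    tau_iso = cfg$tau_iso_bar,
                    steps_per_delay = steps_per_delay)
}

#' Optimize the dimensionless feedback gains
#'
#' Finds the fastest zero-overshoot gains of the normalized unit-delay
#' system at a given force capacity.
#'
#' @param tau_iso_bar Dimensionless force capacity (may be \code{Inf}).
#' @param variant \code{"swing"} or \code{"posture"}.
#' @param start_center Optional warm-start \code{c(kp_bar, kd_bar)}.
#' @param start_span Log10 half-width of the global-phase gain grid.
#' @param start_n Grid points per gain axis in the global phase.
#' @param steps_per_delay Integration resolution.
#' @param seed Integer recorded with the result.
#' @param ... Further arguments passed to \code{\link{optimize_gains}}
#'   (e.g. \code{maxit}, \code{horizon}, \code{threshold}).
#' @return An \code{optimization_result}; its metrics are dimensionless
#'   (response time in delay multiples, torques in normalized units).
#' @export
optimize_normalized_gains <- function(tau_iso_bar = Inf,
                                      variant = c("swing", "posture"),
                                      start_center = NULL, start_span = 0.5,
                                      start_n = 13L,
                                      steps_per_delay = 200L, seed = 1L,
                                      ...) {
  variant <- match.arg(variant)
  params <- .unit_params(variant, tau_iso_bar)
  tcfg <- .unit_config(variant)
  if (is.null(start_center)) start_center <- c(0.1617, 0.6343)
  optimize_gains(params, tcfg, tau_iso = tau_iso_bar,
                 include_gravity = FALSE, start_center = start_center,
                 start_span = start_span, start_n = start_n,
                 steps_per_delay = steps_per_delay, seed = seed, ...)
}

#' Sweep the normalized force capacity
#'
#' Re-optimizes the dimensionless gains for each force-capacity value on an
#' ascending grid, sweeping from high capacity to low and warm-starting each
#' point at its neighbour's optimum (the middle/low regions have many
#' near-degenerate local minima; warm starts stabilize the curve). Records
#' the optimal gains, response time, peak torques and saturation flags per
#' point; infeasible points are recorded and the sweep continues.
#'
#' @param grid Ascending positive vector of dimensionless force capacities.
#' @param variant \code{"swing"} or \code{"posture"}.
#' @param steps_per_delay Integration resolution.
#' @param sat_tol Saturation detection: a peak counts as saturated when its
#'   magnitude reaches \code{(1 - sat_tol) * tau_iso_bar}.
#' @param warm_span Log10 half-width of the gain grid for warm-started
#'   points (the first, highest-capacity point uses the full default span).
#' @param seed Integer recorded with the sweep.
#' @return An object of class \code{capacity_sweep}: a data.frame with
#'   columns \code{tau_iso_bar}, \code{kp_bar}, \code{kd_bar},
#'   \code{t_resp_bar}, \code{peak_pos}, \code{peak_neg}, \code{sat_pos},
#'   \code{sat_neg}, \code{feasible}.
#' @export
sweep_force_capacity <- function(grid, variant = c("swing", "posture"),
                                 steps_per_delay = 200L, sat_tol = 1e-6,
                                 warm_span = 0.15, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(all(grid > 0), !is.unsorted(grid))
  n <- length(grid)
  out <- data.frame(tau_iso_bar = grid, kp_bar = NA_real_, kd_bar = NA_real_,
                    t_resp_bar = NA_real_, peak_pos = NA_real_,
                    peak_neg = NA_real_, sat_pos = NA, sat_neg = NA,
                    feasible = FALSE)
  warm <- NULL
  for (i in rev(seq_len(n))) {
    tib <- grid[i]
    res <- optimize_normalized_gains(
      tau_iso_bar = tib, variant = variant,
      start_center = warm,
      start_span = if (is.null(warm)) 0.5 else warm_span,
      start_n = if (is.null(warm)) 13L else 5L,
      steps_per_delay = steps_per_delay, seed = seed)
    if (!res$converged && !is.null(warm)) {
      # the optimum moves quickly near the low-capacity floor; retry the
      # failed warm start with the full-width grid before recording failure
      res <- optimize_normalized_gains(
        tau_iso_bar = tib, variant = variant, start_center = warm,
        start_span = 0.7, start_n = 13L,
        steps_per_delay = steps_per_delay, seed = seed)
    }
    if (res$converged) {
      m <- res$metrics
      out$kp_bar[i] <- res$best_params$kp
      out$kd_bar[i] <- res$best_params$kd
      out$t_resp_bar[i] <- m$response_time
      out$peak_pos[i] <- m$peak_tau_pos
      out$peak_neg[i] <- m$peak_tau_neg
      out$sat_pos[i] <- m$peak_tau_pos >= (1 - sat_tol) * tib
      out$sat_neg[i] <- abs(m$peak_tau_neg) >= (1 - sat_tol) * tib
      out$feasible[i] <- TRUE
      warm <- c(res$best_params$kp, res$best_params$kd)
    }
  }
  structure(out, class = c("capacity_sweep", "data.frame"),
            variant = variant, seed = as.integer(seed))
}

#' Classify delay-limited and force-limited regions of a sweep
#'
#' Labels each sweep point: \code{"high"} (delay-limited, no saturation),
#' \code{"middle"} (positive torque saturated), \code{"low"} (both torques
#' saturated), and extracts the region boundaries.
#'
#' @param sweep A \code{\link{sweep_force_capacity}} result.
#' @return A list with \code{high_boundary} (largest capacity at which the
#'   positive torque saturates — the top of the force-limited range),
#'   \code{mid_boundary} (largest capacity at which the negative torque also
#'   saturates), \code{low_floor} (smallest capacity with a feasible
#'   zero-overshoot settle) and the per-point \code{region} labels. Warns if
#'   the saturation pattern is not monotone in capacity.
#' @export
classify_regions <- function(sweep) {
  stopifnot(inherits(sweep, "capacity_sweep"))
  feas <- sweep$feasible
  region <- rep(NA_character_, nrow(sweep))
  region[feas & !sweep$sat_pos] <- "high"
  region[feas & sweep$sat_pos & !sweep$sat_neg] <- "middle"
  region[feas & sweep$sat_pos & sweep$sat_neg] <- "low"

  sat_pos_tau <- sweep$tau_iso_bar[feas & sweep$sat_pos]
  sat_neg_tau <- sweep$tau_iso_bar[feas & sweep$sat_neg]
  high_boundary <- if (length(sat_pos_tau)) max(sat_pos_tau) else NA_real_
  mid_boundary <- if (length(sat_neg_tau)) max(sat_neg_tau) else NA_real_
  low_floor <- if (any(feas)) min(sweep$tau_iso_bar[feas]) else NA_real_

  # saturation should switch on once, going down in capacity
  ord <- order(sweep$tau_iso_bar)
  sp <- sweep$sat_pos[ord][feas[ord]]
  if (any(diff(as.integer(sp)) > 0)) {
    warning("non-monotone saturation pattern across the sweep")
  }
  list(high_boundary = high_boundary, mid_boundary = mid_boundary,
       low_floor = low_floor, region = region)
}
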