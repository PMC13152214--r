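#' Available movement time for a perturbation response
#'
#' The shortest time available to complete a corrective movement. Swing: the
#' swing duration at maximum sprint speed, taken from its published scaling
#' law (147.9 M^0.17 ms). Posture: the time to fall freely through a height
#' equal to the leg length, \code{sqrt(2 L / g)} with \code{L} from the
#' leg-length scaling law.
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param mass Body mass, kg (vectorized).
#' @return Available time in seconds.
#' @export
#' @examples
#' available_time("swing", 1)   # 0.1479 s
#' available_time("posture", 1) # ~0.182 s
available_time <- function(task, mass) {
  task <- match.arg(task, c("swing", "posture"))
  if (any(mass <= 0)) stop("mass must be > 0")
  if (task == "swing") {
    evaluate_law(.get_law("swing", "available_time"), mass) / 1000
  } else {
    L <- evaluate_law(.get_law("posture", "l_com"), mass)
    sqrt(2 * L / GRAVITY)
  }
}

#' Run one task across the body-mass grid under both control strategies
#'
#' For each mass: materialize the animal parameters, optimize the PD
#' feedback gains for the fastest zero-overshoot response, optimize the
#' bang-bang switch time, and record the response metrics. Power laws are
#' then fitted to each optimized output (gains in SI units, times in ms)
#' against body mass.
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param masses Body masses, kg; default the ten-size grid.
#' @param movement_deg Swing movement size, degrees.
#' @param froude Posture dimensionless perturbation velocity.
#' @param threshold Settling band half-width fraction (default 0.02).
#' @param steps_per_delay Integration resolution.
#' @param seed Integer recorded with the run.
#' @return An object of class \code{scaling_run}: \code{task},
#'   \code{per_size} (data.frame with one row per mass: delay, optimized
#'   gains, feedback and feedforward response times, switch time, torque
#'   fraction, available time, feasibility flags), \code{fits} (list of
#'   \code{\link{fit_power_law}} results for kp, kd, feedback response time,
#'   switch time and feedforward response time; times fitted in ms so the
#'   coefficients are ms at 1 kg) and \code{partial} (TRUE if any size was
#'   infeasible and excluded from the fits, with a warning).
#' @export
run_task_scaling <- function(task, masses = size_grid(), movement_deg = 30,
                             froude = 0.21, threshold = 0.02,
                             steps_per_delay = 200L, seed = 1L) {
  task <- match.arg(task, c("swing", "posture"))
  rows <- vector("list", length(masses))
  for (i in seq_along(masses)) {
    m <- masses[i]
    params <- animal_parameters(task, m)
    cfg <- task_config(params, movement_deg = movement_deg, froude = froude)
    fb <- optimize_gains(params, cfg, steps_per_delay = steps_per_delay,
                         threshold = threshold, seed = seed)
    ff <- optimize_switch_time(params, cfg,
                               steps_per_delay = steps_per_delay, seed = seed)
    rows[[i]] <- data.frame(
      body_mass = m,
      t_sm = params$t_sm,
      kp = fb$best_params$kp,
      kd = fb$best_params$kd,
      fb_time = fb$metrics$response_time,
      fb_overshoot = fb$metrics$overshoot,
      torque_fraction = fb$metrics$torque_fraction,
      fb_feasible = fb$converged,
      t_switch = if (ff$converged) ff$best_params$t_switch else NA_real_,
      ff_time = if (ff$converged) ff$metrics$response_time else NA_real_,
      ff_feasible = ff$converged,
      available_time = available_time(task, m)
    )
  }
  per_size <- do.call(rbind, rows)
  ok <- per_size$fb_feasible & per_size$ff_feasible
  if (!all(ok)) {
    warning("infeasible sizes excluded from the fits: ",
            paste(per_size$body_mass[!ok], collapse = ", "), " kg")
  }
  fit_on <- function(values) {
    fit_power_law(per_size$body_mass[ok], values[ok])
  }
  fits <- list(
    kp = fit_on(per_size$kp),
    kd = fit_on(per_size$kd),
    fb_time_ms = fit_on(per_size$fb_time * 1000),
    t_switch_ms = fit_on(per_size$t_switch * 1000),
    ff_time_ms = fit_on(per_size$ff_time * 1000)
  )
  structure(list(task = task, per_size = per_size, fits = fits,
                 movement_deg = movement_deg, froude = froude,
                 threshold = threshold, partial = !all(ok),
                 seed = as.integer(seed)),
            class = "scaling_run")
}

#' @export
print.scaling_run <- function(x, ...) {
  cat(sprintf("%s-task scaling run over %d sizes%s\n", x$task,
              nrow(x$per_size), if (x$partial) " [partial]" else ""))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-12s %.4g * M^%.3f  (r^2 %.4f)\n", nm, f$coefficient,
                f$exponent, f$r_squared))
  }
  invisible(x)
}

#' Compare feedback and feedforward strategies across sizes
#'
#' @param run A \code{\link{run_task_scaling}} result.
#' @return A data.frame with one row per size: the feedback-to-feedforward
#'   response-time ratio, the feedback time as a multiple of the
#'   sensorimotor delay, both response times as fractions of the available
#'   movement time, and the feedback torque fraction.
#' @export
compare_strategies <- function(run) {
  stopifnot(inherits(run, "scaling_run"))
  ps <- run$per_size
  data.frame(
    body_mass = ps$body_mass,
    fb_ff_ratio = ps$fb_time / ps$ff_time,
    fb_over_t_sm = ps$fb_time / ps$t_sm,
    fb_frac_available = ps$fb_time / ps$available_time,
    ff_frac_available = ps$ff_time / ps$available_time,
    torque_fraction = ps$torque_fraction
  )
}

#' Write the scaling-run report files
#'
#' Writes a table of fitted power laws (parameter, source, coefficient,
#' exponent), the per-size results, the strategy comparison, and a JSON
#' summary with configuration and seed provenance.
#'
#' @param run A \code{\link{run_task_scaling}} result.
#' @param comparison The matching \code{\link{compare_strategies}} table.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of files written.
#' @export
write_scaling_report <- function(run, comparison, dir) {
  stopifnot(inherits(run, "scaling_run"), nrow(run$per_size) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- c(kp = "Kp: Proportional gain (N.m/rad)",
              kd = "Kd: Derivative gain (N.m/(rad/s))",
              fb_time_ms = "Feedback response time (ms)",
              t_switch_ms = "tswitch: Switch time (ms)",
              ff_time_ms = "Feedforward response time (ms)")
  fit_tab <- do.call(rbind, lapply(names(run$fits), function(nm) {
    f <- run$fits[[nm]]
    data.frame(parameter = labels[[nm]], source = "optimization",
               coefficient = f$coefficient, exponent = f$exponent,
               r_squared = f$r_squared)
  }))
  files <- c(
    fits = file.path(dir, sprintf("%s_power_law_fits.csv", run$task)),
    per_size = file.path(dir, sprintf("%s_per_size.csv", run$task)),
    comparison = file.path(dir, sprintf("%s_comparison.csv", run$task)),
    summary = file.path(dir, sprintf("%s_summary.json", run$task))
  )
  utils::write.csv(fit_tab, files[["fits"]], row.names = FALSE)
  utils::write.csv(run$per_size, files[["per_size"]], row.names = FALSE)
  utils::write.csv(comparison, files[["comparison"]], row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      task = run$task, movement_deg = run$movement_deg,
      froude = run$froude, threshold = run$threshold, seed = run$seed,
      partial = run$partial,
      fits = lapply(run$fits, function(f) {
        list(coefficient = f$coefficient, exponent = f$exponent,
             r_squared = f$r_squared)
      })
    )
    jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                         digits = NA)
  } else {
    files <- files[names(files) != "summary"]
  }
  invisible(files)
}
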