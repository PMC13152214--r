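#' Allometric power law
#'
#' A power law \code{value = a * M^b} relating a physical or neural
#' parameter to body mass \code{M} (kg). The coefficient \code{a} is the
#' value of the parameter at \code{M = 1} kg, in the parameter's natural
#' units; the exponent \code{b} is dimensionless.
#'
#' @param coefficient Positive value of the parameter at 1 kg.
#' @param exponent Dimensionless scaling exponent.
#' @param units Unit label for the coefficient (e.g. \code{"ms"}).
#' @return An object of class \code{allometric_law}.
#' @export
#' @examples
#' law <- allometric_law(31, 0.21, "ms") # sensorimotor delay
#' evaluate_law(law, 1)      # 31 ms at 1 kg
#' evaluate_law(law, 0.001)  # a 1 g animal
allometric_law <- function(coefficient, exponent, units = "") {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient), coefficient > 0,
            is.numeric(exponent), length(exponent) == 1L, is.finite(exponent))
  structure(list(coefficient = coefficient, exponent = exponent,
                 units = as.character(units)),
            class = "allometric_law")
}

#' @export
print.allometric_law <- function(x, ...) {
  cat(sprintf("allometric law: %g * M^%g %s\n",
              x$coefficient, x$exponent, x$units))
  invisible(x)
}

#' Evaluate an allometric law at a body mass
#'
#' @param law An \code{\link{allometric_law}}.
#' @param mass Body mass in kg, strictly positive (vectorized).
#' @return \code{law$coefficient * mass^law$exponent}, in the law's units.
#' @export
evaluate_law <- function(law, mass) {
  stopifnot(inherits(law, "allometric_law"))
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be strictly positive and finite")
  }
  law$coefficient * mass^law$exponent
}

#' Parameter scaling laws for the swing and posture tasks
#'
#' Returns the table of input power laws (coefficient, exponent, units) used
#' to materialize animal parameters: sensorimotor delay, segment inertia,
#' limb mass and centre-of-mass length (swing) or leg length (posture), and
#' maximum isometric torque, plus the swing-duration-at-max-sprint law used
#' as the available movement time in the swing task.
#'
#' @param task Optional, \code{"swing"} or \code{"posture"} to filter rows.
#' @return A data.frame with columns task, parameter, source, coefficient,
#'   exponent, units.
#' @export
scaling_laws <- function(task = NULL) {
  path <- system.file("extdata", "scaling_laws.csv", package = "neuroscale",
                      mustWork = TRUE)
  laws <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(task)) {
    task <- match.arg(task, c("swing", "posture"))
    laws <- laws[laws$task == task, , drop = FALSE]
    rownames(laws) <- NULL
  }
  laws
}

.get_law <- function(task, parameter) {
  laws <- scaling_laws(task)
  row <- laws[laws$parameter == parameter, ]
  if (nrow(row) != 1L) stop("no law for ", task, "/", parameter)
  allometric_law(row$coefficient, row$exponent, row$units)
}

#' Standard gravitational acceleration used throughout (m/s^2)
#' @export
GRAVITY <- 9.81

#' Materialize animal parameters at a body mass
#'
#' Evaluates the task's input scaling laws at a body mass and converts all
#' quantities to strict SI units (s, kg, m, N.m). For the swing task the
#' controlled segment is the forelimb (distributed-mass pendulum about the
#' shoulder); for the posture task it is the whole body (point-mass inverted
#' pendulum on a leg-length lever, inertia M L^2).
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param mass Body mass in kg, > 0.
#' @return An object of class \code{animal_params}: a list with
#'   \code{task}, \code{body_mass} (kg), \code{t_sm} (s), \code{inertia}
#'   (kg m^2), \code{l_com} (m; shoulder-to-COM distance for swing, leg
#'   length for posture), \code{tau_iso} (N m), \code{g} (m/s^2) and, for
#'   the swing task, \code{limb_mass} (kg).
#' @export
#' @examples
#' p <- animal_parameters("swing", 1)
#' p$t_sm     # 0.031 s
#' p$tau_iso  # 0.54 N.m
animal_parameters <- function(task, mass) {
  task <- match.arg(task, c("swing", "posture"))
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  p <- list(
    task = task,
    body_mass = mass,
    t_sm = evaluate_law(.get_law(task, "t_sm"), mass) / 1000, # ms -> s
    inertia = evaluate_law(.get_law(task, "inertia"), mass),
    l_com = evaluate_law(.get_law(task, "l_com"), mass),
    tau_iso = evaluate_law(.get_law(task, "tau_iso"), mass),
    g = GRAVITY
  )
  if (task == "swing") {
    p$limb_mass <- evaluate_law(.get_law(task, "limb_mass"), mass)
  }
  structure(p, class = "animal_params")
}

#' @export
print.animal_params <- function(x, ...) {
  cat(sprintf("%s-task animal, body mass %g kg\n", x$task, x$body_mass))
  cat(sprintf("  t_sm     %.4g s\n", x$t_sm))
  cat(sprintf("  inertia  %.4g kg.m^2\n", x$inertia))
  if (!is.null(x$limb_mass)) cat(sprintf("  limb mass %.4g kg\n", x$limb_mass))
  cat(sprintf("  l_com    %.4g m\n", x$l_com))
  cat(sprintf("  tau_iso  %.4g N.m\n", x$tau_iso))
  invisible(x)
}

#' The ten-animal body-mass grid
#'
#' Eight logarithmically spaced sizes from 1 g to 10 t covering the range of
#' terrestrial mammals, plus 5 g and 5 t, for ten sizes in total.
#'
#' @return Ascending numeric vector of body masses in kg.
#' @export
size_grid <- function() {
  c(1e-3, 5e-3, 1e-2, 1e-1, 1, 10, 1e2, 1e3, 5e3, 1e4)
}

#' Fit a power law to positive data
#'
#' Ordinary least squares on (log10 mass, log10 value); the fitted
#' coefficient is the predicted value at 1 kg and the exponent is the slope.
#' This is the regression used to summarize how optimized gains and response
#' times scale with body mass.
#'
#' @param masses Body masses in kg, > 0, at least two.
#' @param values Positive values of the quantity at each mass.
#' @return An object of class \code{power_law_fit} with \code{coefficient},
#'   \code{exponent} and \code{r_squared} (on the log10 scale).
#' @export
#' @examples
#' fit <- fit_power_law(size_grid(), 2 * size_grid()^0.5)
#' c(fit$coefficient, fit$exponent) # 2, 0.5
fit_power_law <- function(masses, values) {
  if (length(masses) < 2L || length(values) != length(masses)) {
    stop("need at least two (mass, value) pairs of equal length")
  }
  if (any(!is.finite(masses)) || any(masses <= 0) ||
      any(!is.finite(values)) || any(values <= 0)) {
    stop("masses and values must be strictly positive and finite")
  }
  x <- log10(masses)
  y <- log10(values)
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-300) {
    if (rss < 1e-300) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  structure(list(coefficient = 10^fit$coefficients[[1]],
                 exponent = fit$coefficients[[2]],
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: %.4g * M^%.4g  (r^2 = %.4f on logs)\n",
              x$coefficient, x$exponent, x$r_squared))
  invisible(x)
}

#' Write a materialized parameter grid
#'
#' Evaluates \code{\link{animal_parameters}} on a mass grid and writes the
#' result as CSV (and optionally JSON).
#'
#' @param task \code{"swing"} or \code{"posture"}.
#' @param masses Body masses in kg; default the ten-size grid.
#' @param csv_path Path for the CSV output, or \code{NULL} to skip.
#' @param json_path Path for the JSON output, or \code{NULL} to skip
#'   (requires the jsonlite package).
#' @return The parameter grid data.frame, invisibly.
#' @export
write_parameter_grid <- function(task, masses = size_grid(),
                                 csv_path = NULL, json_path = NULL) {
  rows <- lapply(masses, function(m) {
    p <- animal_parameters(task, m)
    data.frame(task = p$task, body_mass = p$body_mass, t_sm = p$t_sm,
               inertia = p$inertia,
               limb_mass = if (is.null(p$limb_mass)) NA_real_ else p$limb_mass,
               l_com = p$l_com, tau_iso = p$tau_iso, g = p$g)
  })
  grid <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(grid, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON output")
    }
    jsonlite::write_json(grid, json_path, digits = NA)
  }
  invisible(grid)
}
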