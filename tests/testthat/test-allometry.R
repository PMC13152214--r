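test_that("power laws evaluate as coefficient * mass^exponent", {
  tsm <- allometric_law(31, 0.21, "ms")
  expect_identical(evaluate_law(tsm, 1), 31)
  # 31 * 0.001^0.21 = 31 * 10^-0.63
  expect_equal(evaluate_law(tsm, 0.001), 7.26712, tolerance = 1e-5)
  flat <- allometric_law(5, 0)
  expect_identical(evaluate_law(flat, 0.007), 5)
  expect_identical(evaluate_law(flat, 4000), 5)
  expect_error(evaluate_law(tsm, 0), "positive")
  expect_error(evaluate_law(tsm, -2), "positive")
  expect_error(allometric_law(-1, 0.2))
})

test_that("animal parameters at 1 kg reproduce the input tables in SI units", {
  sw <- animal_parameters("swing", 1)
  expect_equal(sw$t_sm, 0.031)
  expect_equal(sw$inertia, 2.52e-4)
  expect_equal(sw$limb_mass, 5.8e-2)
  expect_equal(sw$l_com, 5.6e-2)
  expect_equal(sw$tau_iso, 0.54)
  expect_equal(sw$g, 9.81)

  po <- animal_parameters("posture", 1)
  expect_equal(po$t_sm, 0.031)
  expect_equal(po$l_com, 0.162)
  expect_equal(po$inertia, 2.64e-2)
  expect_equal(po$tau_iso, 3.41)
  expect_null(po$limb_mass)

  expect_error(animal_parameters("hop", 1))
  expect_error(animal_parameters("swing", 0))
})

test_that("posture inertia is consistent with a point mass on a leg-length lever", {
  # the inertia and leg-length laws describe the same body: I ~ M * L^2
  for (m in size_grid()) {
    p <- animal_parameters("posture", m)
    expect_equal(p$inertia, p$body_mass * p$l_com^2, tolerance = 0.05)
  }
})

test_that("parameters with positive exponents increase with mass", {
  grid <- size_grid()
  for (task in c("swing", "posture")) {
    ps <- lapply(grid, animal_parameters, task = task)
    for (field in c("t_sm", "inertia", "l_com", "tau_iso")) {
      vals <- vapply(ps, `[[`, numeric(1), field)
      expect_true(all(diff(vals) > 0), info = paste(task, field))
    }
  }
})

test_that("the body-mass grid covers 1 g to 10 t in ten ascending sizes", {
  g <- size_grid()
  expect_length(g, 10)
  expect_equal(min(g), 1e-3)
  expect_equal(max(g), 1e4)
  expect_true(all(diff(g) > 0))
  expect_true(all(c(5e-3, 5e3) %in% g))
})

test_that("power-law fitting recovers exact laws and matches a hand OLS", {
  g <- size_grid()
  fit <- fit_power_law(g, 2 * g^0.5)
  expect_equal(fit$coefficient, 2, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # round trip through evaluate_law for several laws
  for (ab in list(c(31, 0.21), c(5.64e-3, 1.34), c(147.9, -0.4))) {
    law <- allometric_law(ab[1], ab[2])
    f <- fit_power_law(g, evaluate_law(law, g))
    expect_equal(f$coefficient, ab[1], tolerance = 1e-10)
    expect_equal(f$exponent, ab[2], tolerance = 1e-10)
    expect_equal(evaluate_law(allometric_law(f$coefficient, f$exponent), 1),
                 f$coefficient)
  }

  # multiplicative noise: compare against closed-form OLS on logs
  set.seed(42)
  y <- 3 * g^0.8 * exp(rnorm(length(g), sd = 0.1))
  f <- fit_power_law(g, y)
  x <- log10(g); ly <- log10(y)
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sum((x - mean(x))^2)
  intercept <- mean(ly) - slope * mean(x)
  expect_equal(f$exponent, slope, tolerance = 1e-12)
  expect_equal(f$coefficient, 10^intercept, tolerance = 1e-12)

  expect_error(fit_power_law(1, 2))
  expect_error(fit_power_law(c(1, 2), c(1, -1)))
  expect_error(fit_power_law(c(1, -2), c(1, 1)))
})

test_that("the shipped law table materializes into a writable grid", {
  laws <- scaling_laws("swing")
  expect_true(all(c("t_sm", "inertia", "l_com", "tau_iso", "limb_mass") %in%
                    laws$parameter))
  expect_true(all(laws$coefficient > 0))
  tmp <- tempfile(fileext = ".csv")
  grid <- write_parameter_grid("posture", csv_path = tmp)
  back <- read.csv(tmp)
  expect_equal(back$tau_iso, grid$tau_iso)
  expect_equal(nrow(back), 10)
})
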