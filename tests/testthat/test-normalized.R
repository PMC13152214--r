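test_that("the published dimensionless gains reproduce the benchmark run", {
  cfg <- normalized_config(Inf, c(0.1617, 0.6343))
  tr <- simulate_normalized(cfg)
  tcfg <- step_cfg()
  expect_equal(settling_time(tr, tcfg), 7.0903, tolerance = 1e-3)
  expect_equal(overshoot(tr, tcfg), 0)
  pk <- peak_torques(tr)
  # the first post-deadtime torque sample is kp * (reference - history) = kp
  expect_equal(pk$peak_tau_pos, 0.1617, tolerance = 1e-12)
  expect_equal(pk$peak_tau_neg, -0.0950, tolerance = 1e-3)
})

test_that("a capacity above the unconstrained peak changes nothing", {
  free <- simulate_normalized(normalized_config(Inf, c(0.1617, 0.6343)))
  capped <- simulate_normalized(normalized_config(0.25, c(0.1617, 0.6343)))
  expect_identical(capped$theta, free$theta)
  expect_identical(capped$tau_act, free$tau_act)
})

test_that("zero gains leave the normalized plant at the origin", {
  tr <- simulate_normalized(normalized_config(Inf, c(0, 0)))
  expect_true(all(tr$theta == 0))
  expect_true(all(tr$omega == 0))
})

test_that("dimensional and normalized optima coincide under rescaling", {
  # optimize the gravity-free scaled swing plant and normalize the result:
  # kp_bar = kp * t_sm^2 / I, kd_bar = kd * t_sm / I, t_bar = t / t_sm
  norm <- optimize_normalized_gains(start_span = 0.3, start_n = 7L)
  sw <- animal_parameters("swing", 1)
  cfg <- task_config(sw)
  dim <- optimize_gains(sw, cfg, tau_iso = Inf, include_gravity = FALSE,
                        start_span = 0.3, start_n = 7L)
  expect_true(norm$converged && dim$converged)
  kp_bar <- dim$best_params$kp * sw$t_sm^2 / sw$inertia
  kd_bar <- dim$best_params$kd * sw$t_sm / sw$inertia
  t_bar <- dim$metrics$response_time / sw$t_sm
  expect_equal(kp_bar, norm$best_params$kp, tolerance = 0.01)
  expect_equal(kd_bar, norm$best_params$kd, tolerance = 0.01)
  expect_equal(t_bar, norm$metrics$response_time, tolerance = 0.01)
})

test_that("a one-point sweep duplicates single-point optimization", {
  single <- optimize_normalized_gains(tau_iso_bar = 0.12)
  sw <- sweep_force_capacity(0.12)
  expect_true(sw$feasible)
  expect_equal(sw$t_resp_bar, single$metrics$response_time, tolerance = 1e-9)
  expect_equal(sw$kp_bar, single$best_params$kp, tolerance = 1e-9)
  expect_true(sw$sat_pos)
})

test_that("region classification reads the saturation pattern", {
  fake <- structure(
    data.frame(tau_iso_bar = c(0.05, 0.10, 0.15, 0.20),
               kp_bar = 0.1, kd_bar = 0.5,
               t_resp_bar = c(9, 8, 7.2, 7.1),
               peak_pos = c(0.05, 0.10, 0.15, 0.16),
               peak_neg = c(-0.05, -0.08, -0.09, -0.09),
               sat_pos = c(TRUE, TRUE, TRUE, FALSE),
               sat_neg = c(TRUE, FALSE, FALSE, FALSE),
               feasible = TRUE),
    class = c("capacity_sweep", "data.frame"))
  cl <- classify_regions(fake)
  expect_equal(cl$high_boundary, 0.15)
  expect_equal(cl$mid_boundary, 0.05)
  expect_equal(cl$low_floor, 0.05)
  expect_equal(cl$region, c("low", "middle", "middle", "high"))

  none <- fake
  none$sat_pos <- none$sat_neg <- FALSE
  cl2 <- classify_regions(none)
  expect_true(all(cl2$region == "high"))
  expect_true(is.na(cl2$high_boundary))

  weird <- fake
  weird$sat_pos <- c(TRUE, FALSE, TRUE, FALSE)
  expect_warning(classify_regions(weird), "non-monotone")
})
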