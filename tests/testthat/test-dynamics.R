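test_that("gravity restores the swing pendulum and destabilizes posture", {
  sw <- animal_parameters("swing", 1)
  po <- animal_parameters("posture", 1)
  expect_equal(gravity_torque("swing", sw, 0), 0)
  # -0.058 * 9.81 * 0.056 * sin(15 deg)
  expect_equal(gravity_torque("swing", sw, 15 * pi / 180), -8.2465e-3,
               tolerance = 1e-4)
  # 1 * 9.81 * 0.162 * sin(0.1)
  expect_equal(gravity_torque("posture", po, 0.1), 0.158657,
               tolerance = 1e-5)
  th <- seq(0.01, pi - 0.01, length.out = 50)
  expect_true(all(gravity_torque("swing", sw, th) < 0))   # opposes angle
  expect_true(all(gravity_torque("swing", sw, -th) > 0))
  expect_true(all(gravity_torque("posture", po, th) > 0)) # grows with angle
  expect_true(all(gravity_torque("posture", po, -th) < 0))
})

test_that("saturation clamps, is idempotent, odd and bounded", {
  expect_equal(saturate(0.3, 0.25), 0.25)
  expect_equal(saturate(-0.3, 0.25), -0.25)
  expect_equal(saturate(0.1, 0.25), 0.1)
  x <- seq(-5, 5, length.out = 101)
  s <- saturate(x, 0.7)
  expect_true(all(abs(s) <= 0.7))
  expect_equal(saturate(s, 0.7), s)          # idempotent
  expect_equal(saturate(-x, 0.7), -s)        # odd
  expect_equal(saturate(x, Inf), x)          # no limit
  expect_error(saturate(1, 0))
})

test_that("the PD law is silent during the deadtime and linear afterwards", {
  g <- feedback_gains(0.1617, 0.6343, 0.02)
  expect_equal(pd_torque(g, 0.5, 2, 1, t = 0.5, t_sm = 1), 0)
  expect_equal(pd_torque(g, 99, -99, 1, t = 0.99, t_sm = 1), 0)
  # zero error at the target returns exactly the steady-state torque
  expect_equal(pd_torque(g, 1, 0, 1, t = 3, t_sm = 1), 0.02)
  g2 <- feedback_gains(0.1617, 0)
  expect_equal(pd_torque(g2, 0, 0, 1, t = 2, t_sm = 1), 0.1617)
  expect_error(feedback_gains(-1, 0))
})

test_that("bang-bang torque has a deadtime and one sign reversal", {
  plan <- feedforward_plan(3, 1)
  expect_equal(bang_bang_torque(plan, 0.5, 1, 0.25), 0)
  expect_equal(bang_bang_torque(plan, 2, 1, 0.25), 0.25)
  expect_equal(bang_bang_torque(plan, 4, 1, 0.25), -0.25)
  down <- feedforward_plan(3, -1)
  expect_equal(bang_bang_torque(down, 2, 1, 0.25), -0.25)
  expect_error(bang_bang_torque(feedforward_plan(0.5, 1), 1, 1, 0.25))
})

test_that("angular acceleration is the torque balance over inertia", {
  sw <- animal_parameters("swing", 1)
  th <- 0.3
  tau_bal <- -gravity_torque("swing", sw, th)
  expect_equal(angular_acceleration("swing", sw, th, tau_bal), 0)
  expect_equal(angular_acceleration("swing", sw, 0, 0.54), 0.54 / 2.52e-4)
  expect_equal(angular_acceleration("swing", sw, 0, 0), 0)
})

test_that("task configurations encode the study perturbations", {
  sw <- task_config(animal_parameters("swing", 1))
  expect_equal(sw$theta0, -15 * pi / 180)
  expect_equal(sw$theta_ref, 15 * pi / 180)
  expect_equal(sw$omega0, 0)
  big <- task_config(animal_parameters("swing", 1), movement_deg = 180)
  expect_equal(big$theta_ref - big$theta0, pi)

  po <- task_config(animal_parameters("posture", 1))
  expect_equal(po$theta0, 0)
  expect_equal(po$theta_ref, 0)
  # 0.21 * sqrt(9.81 / 0.162)
  expect_equal(po$omega0, 1.634166, tolerance = 1e-6)
  # Froude scaling: the linear push velocity is 0.21 * sqrt(g * L)
  p <- animal_parameters("posture", 1)
  expect_equal(po$omega0 * p$l_com, 0.21 * sqrt(p$g * p$l_com))
})

test_that("the steady-state torque balances gravity at the target", {
  sw <- animal_parameters("swing", 1)
  cfg <- task_config(sw)
  tss <- steady_state_torque(sw, cfg)
  expect_equal(tss + gravity_torque("swing", sw, cfg$theta_ref), 0)
  po <- animal_parameters("posture", 1)
  expect_equal(steady_state_torque(po, task_config(po)), 0)
})
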