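test_that("an unforced plant at rest stays put", {
  p <- unit_params()
  cfg <- step_cfg(theta0 = 0.3, theta_ref = 1)
  tr <- simulate_feedback(p, feedback_gains(0, 0, 0), cfg,
                          include_gravity = FALSE)
  expect_false(tr$diverged)
  expect_equal(tr$t[1], 0)
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$theta == 0.3))
  expect_true(all(tr$omega == 0))
  expect_true(all(tr$tau_act == 0))
})

test_that("the method-of-steps engine agrees with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(gains = feedback_gains(0.1617, 0.6343), tau_iso = Inf),
    list(gains = feedback_gains(0.25, 0.9), tau_iso = 0.1),  # saturating
    list(gains = feedback_gains(0.05, 0.2), tau_iso = Inf)   # ringing
  )
  p <- unit_params()
  cfg <- step_cfg()
  for (cs in cases) {
    tr <- simulate_feedback(p, cs$gains, cfg, tau_iso = cs$tau_iso,
                            steps_per_delay = 200)
    or <- dede_feedback_oracle(p, cs$gains, cfg, horizon = 20,
                               tau_iso = cs$tau_iso)
    diff <- max(abs(traj_theta_at(tr, or$t) - or$theta))
    expect_lt(diff, 1e-4)
  }
  # with gravity: the 1 kg swing plant at table-scale gains
  sw <- animal_parameters("swing", 1)
  scfg <- task_config(sw)
  g <- feedback_gains(0.0175, 4.76e-3, steady_state_torque(sw, scfg))
  tr <- simulate_feedback(sw, g, scfg)
  or <- dede_feedback_oracle(sw, g, scfg, horizon = 20 * sw$t_sm,
                             tau_iso = sw$tau_iso,
                             grav_coef = -sw$limb_mass * sw$g * sw$l_com)
  diff <- max(abs(traj_theta_at(tr, or$t) - or$theta))
  expect_lt(diff / max(abs(or$theta)), 1e-4)
})

test_that("settling time converges under step refinement", {
  p <- unit_params()
  cfg <- step_cfg()
  g <- feedback_gains(0.1617, 0.6343)
  s1 <- settling_time(simulate_feedback(p, g, cfg, steps_per_delay = 200), cfg)
  s2 <- settling_time(simulate_feedback(p, g, cfg, steps_per_delay = 400), cfg)
  expect_lt(abs(s2 - s1) / s1, 1e-3)
})

test_that("linear feedback response time is invariant to movement size", {
  # with gravity off and gains fixed, scaling the step scales the whole
  # trajectory; the settling band scales with it, so time is unchanged
  p <- unit_params()
  g <- feedback_gains(0.1617, 0.6343)
  s1 <- settling_time(simulate_feedback(p, g, step_cfg(0, 1),
                                        include_gravity = FALSE),
                      step_cfg(0, 1))
  s5 <- settling_time(simulate_feedback(p, g, step_cfg(0, 5),
                                        include_gravity = FALSE),
                      step_cfg(0, 5))
  sshift <- settling_time(simulate_feedback(p, g, step_cfg(2, 4),
                                            include_gravity = FALSE),
                          step_cfg(2, 4))
  expect_equal(s5, s1, tolerance = 1e-9)
  expect_equal(sshift, s1, tolerance = 1e-9)
})

test_that("settling time matches the first-order closed form", {
  # theta(t) = 1 - exp(-t / tau_c) crosses the 2 percent band at tau_c ln 50
  tau_c <- 0.7
  t <- seq(0, 10 * tau_c, length.out = 20001)
  tr <- make_traj(t, 1 - exp(-t / tau_c))
  expect_equal(settling_time(tr, step_cfg()), tau_c * log(50),
               tolerance = 1e-6)
})

test_that("settling handles in-band, never-settling and empty inputs", {
  t <- seq(0, 20, length.out = 2001)
  inside <- make_traj(t, rep(1, length(t)))
  expect_equal(settling_time(inside, step_cfg()), 0)
  ringing <- make_traj(t, 1 + 0.5 * sin(t))
  expect_identical(settling_time(ringing, step_cfg()), Inf)
  empty <- make_traj(numeric(0), numeric(0))
  expect_error(settling_time(empty, step_cfg()), "empty")
  # posture settles on the velocity band, normalized by the push velocity
  po <- make_traj(t, 0.1 * exp(-t), omega = exp(-t), task = "posture")
  expect_equal(settling_time(po, push_cfg(1)), log(50), tolerance = 1e-4)
})

test_that("overshoot measures excursion past the target only", {
  t <- seq(0, 10, length.out = 1001)
  mono <- make_traj(t, 1 - exp(-t))
  expect_equal(overshoot(mono, step_cfg()), 0)
  peaky <- make_traj(t, pmin(1 + 0.01 * sin(t), 1.01))
  expect_equal(overshoot(peaky, step_cfg()), 0.01, tolerance = 1e-3)
  # critically damped second-order step has exactly zero overshoot
  wn <- 2
  crit <- make_traj(t, 1 - (1 + wn * t) * exp(-wn * t))
  expect_equal(overshoot(crit, step_cfg()), 0)
  # posture: only the side opposite the push counts
  swing_back <- make_traj(t, 0.1 * sin(t) * exp(-t), task = "posture")
  expect_equal(overshoot(swing_back, push_cfg(1)),
               max(0, -min(0.1 * sin(t) * exp(-t))), tolerance = 1e-12)
})

test_that("peak torques and the torque fraction are bounded by capacity", {
  t <- seq(0, 5, length.out = 501)
  quiet <- make_traj(t, rep(0, 501))
  pk <- peak_torques(quiet)
  expect_equal(c(pk$peak_tau_pos, pk$peak_tau_neg, pk$torque_fraction),
               c(0, 0, 0))
  # a saturating closed-loop run never exceeds the capacity at any sample
  p <- unit_params()
  cfg <- step_cfg()
  tr <- simulate_feedback(p, feedback_gains(0.3, 0.8), cfg, tau_iso = 0.08)
  expect_true(all(abs(tr$tau_act) <= 0.08 + 1e-12))
  expect_lte(peak_torques(tr)$torque_fraction, 1)
})

test_that("bang-bang response matches the double-integrator closed form", {
  # I = 1, tau = 0.25, deadtime 1, 0 -> 1: each phase lasts 2 s, ends at 5 s
  p <- unit_params(tau_iso = 0.25)
  cfg <- step_cfg()
  tr <- simulate_feedforward(p, feedforward_plan(3, 1), cfg,
                             include_gravity = FALSE)
  expect_false(tr$no_rest)
  expect_equal(tr$t_end, 5, tolerance = 1e-9)
  expect_equal(tr$theta_end, 1, tolerance = 1e-9)
  expect_equal(tr$omega[length(tr$omega)], 0, tolerance = 1e-9)
  # switch happens at the midpoint of travel in the symmetric case
  expect_equal(traj_theta_at(tr, 3), 0.5, tolerance = 1e-9)
  # theta and omega stay continuous across the torque jumps
  expect_true(max(abs(diff(tr$theta))) < 0.02)
  expect_true(max(abs(diff(tr$omega))) < 0.02)
})

test_that("an unactuated feedforward run never comes to rest", {
  p <- unit_params(tau_iso = 1)
  tr <- simulate_feedforward(p, feedforward_plan(3, 1), step_cfg(),
                             include_gravity = FALSE, tau_iso = 0)
  expect_true(tr$no_rest)
})

test_that("trajectories round-trip through the tidy CSV writer", {
  p <- unit_params()
  tr <- simulate_feedback(p, feedback_gains(0.1617, 0.6343), step_cfg(),
                          steps_per_delay = 50)
  tmp <- tempfile(fileext = ".csv")
  df <- write_trajectory(tr, tmp)
  back <- read.csv(tmp)
  expect_equal(back$theta, df$theta)
  expect_equal(names(back), c("t", "theta", "omega", "tau_act", "tau_gravity"))
})
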