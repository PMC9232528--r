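test_that("a pure-LJ pair at the potential minimum feels zero force", {
  st <- make_fluid(2, 12, wca = FALSE, seed = 1)
  st$positions <- rbind(c(2, 2, 2), c(2, 2, 2 + 2^(1 / 6)))
  f <- compute_forces(st)
  expect_lt(max(abs(f$forces)), 1e-10)
})

test_that("forces are exact negative gradients of the energy (finite-difference oracle)", {
  for (seed in 1:3) {
    st <- make_random_molecules(seed)
    checks <- finite_difference_forces(st, beads = c(1, 4, 8, 12, 20, 23))
    for (ch in checks) {
      denom <- pmax(1, abs(ch$analytic))
      expect_lt(max(abs(ch$fd - ch$analytic) / denom), 1e-5)
    }
  }
})

test_that("internal forces sum to zero (Newton's third law)", {
  for (seed in 4:6) {
    st <- make_random_molecules(seed)
    f <- compute_forces(st)
    expect_lt(max(abs(colSums(f$forces))), 1e-10)
  }
})

test_that("too-large cutoffs for the box are rejected", {
  st <- make_fluid(5, 6, seed = 2)
  expect_error(compute_forces(st, cutoff = 4), "cutoff too large")
})

test_that("ballistic motion and the analytic harmonic dimer period are reproduced", {
  # T = 0, gamma = 0, no forces: straight-line motion, velocities unchanged
  st <- make_gas(3, 20, seed = 1)
  st$velocities <- matrix(rep(c(0.3, -0.2, 0.1), each = 3), 3)
  p <- integrator_params(dt = 0.01, temperature = 0, gamma = 0, n_steps = 100,
                         com_interval = 0)
  st2 <- run_dynamics(st, p)$state
  expect_equal(st2$velocities, st$velocities, tolerance = 1e-12)
  d <- st2$positions - (st$positions + 1 * st$velocities)
  d <- d - 20 * round(d / 20) # positions are reported wrapped
  expect_lt(max(abs(d)), 1e-9)
  # harmonic dimer: period 2 pi sqrt(mu / k) within 1% at dt = period / 100
  k <- 50
  period <- 2 * pi * sqrt(0.5 / k)
  dimer <- make_dimer(k_bond = k, r0 = 1, sep = 1.2)
  tr <- run_dynamics(
    dimer,
    integrator_params(dt = period / 100, temperature = 0, gamma = 0,
                      n_steps = 400, com_interval = 0),
    reporter_config(stride_frames = 1)
  )
  sep <- vapply(tr$frames, function(f) abs(f[2, 3] - f[1, 3]), numeric(1))
  peaks <- which(diff(sign(diff(sep))) < 0) + 1
  est <- mean(diff(peaks)) * period / 100
  expect_lt(abs(est - period) / period, 0.01)
})

test_that("trajectories are bit-identical under a repeated seed", {
  st <- make_fluid(25, 8, wca = FALSE, seed = 2)
  p <- integrator_params(n_steps = 300, seed = 77)
  t1 <- run_dynamics(st, p)
  t2 <- run_dynamics(st, p)
  expect_identical(t1$state$positions, t2$state$positions)
  expect_identical(t1$state$velocities, t2$state$velocities)
  t3 <- run_dynamics(st, integrator_params(n_steps = 300, seed = 78))
  expect_false(identical(t1$state$positions, t3$state$positions))
})

test_that("free-particle diffusion matches the Einstein relation within 5%", {
  # 150 non-interacting tracers, D = kT / (m gamma) = 1
  st <- make_gas(150, 12, seed = 4)
  tr <- run_dynamics(
    st,
    integrator_params(dt = 0.005, temperature = 1, gamma = 1, n_steps = 2e5,
                      seed = 5, com_interval = 0),
    reporter_config(stride_frames = 2000)
  )
  # frames keep unwrapped engine coordinates: MSD over increasing lags
  p0 <- tr$frames[[5]]
  lags <- 6:length(tr$frames)
  msd <- vapply(lags, function(l) {
    mean(rowSums((tr$frames[[l]] - p0)^2))
  }, numeric(1))
  dt_frame <- tr$frame_times[2] - tr$frame_times[1]
  tt <- (lags - 5) * dt_frame
  d_est <- unname(coef(lm(msd ~ tt))[2] / 6)
  expect_lt(abs(d_est - 1), 0.05)
})

test_that("a tethered bead satisfies equipartition within 3%", {
  st <- make_gas(1, 10, seed = 1)
  k <- 4
  tr <- run_dynamics(
    st,
    integrator_params(dt = 0.005, temperature = 1, gamma = 1, n_steps = 2.5e5,
                      seed = 6, com_interval = 0),
    reporter_config(stride_frames = 25),
    tether = list(enabled = TRUE, idx = 1L, k = k,
                  ref = matrix(st$positions[1, ], 1))
  )
  x <- vapply(tr$frames, function(f) f[1, 1], numeric(1))
  expect_lt(abs(var(x) - 1 / k) / (1 / k), 0.03)
})

test_that("microcanonical WCA fluid conserves energy to 1e-3 over 1e4 steps", {
  st <- make_fluid(40, 6, wca = TRUE, seed = 3)
  st <- thermalize(st, 500, temperature = 0.8, seed = 4)
  tr <- run_dynamics(
    st,
    integrator_params(dt = 0.005, temperature = 0, gamma = 0, n_steps = 1e4,
                      com_interval = 0),
    reporter_config(stride_energy = 100)
  )
  e <- tr$energy$e_pot + tr$energy$e_kin
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-3)
})

test_that("momentum is conserved without the thermostat", {
  st <- make_fluid(30, 7, wca = FALSE, seed = 6)
  st <- thermalize(st, 300, seed = 7)
  # zero net momentum, then integrate at gamma = 0
  st$velocities <- sweep(st$velocities, 2, colMeans(st$velocities))
  tr <- run_dynamics(
    st,
    integrator_params(dt = 0.005, temperature = 0, gamma = 0, n_steps = 2000,
                      com_interval = 0)
  )
  drift <- colSums(tr$state$velocities * st$beads$mass)
  expect_lt(max(abs(drift)) / 2000, 1e-8)
})

test_that("thermostatted runs hold the kinetic temperature within 2%", {
  st <- make_fluid(60, 7, wca = FALSE, seed = 8)
  st <- thermalize(st, 1000, seed = 9)
  tr <- run_dynamics(
    st,
    integrator_params(dt = 0.005, temperature = 1, gamma = 1, n_steps = 4e4,
                      seed = 10),
    reporter_config(stride_energy = 100)
  )
  expect_lt(abs(mean(tr$energy$t_inst[-1]) - 1), 0.02)
})

test_that("diverging integrations raise an error naming the step", {
  st <- make_dimer(k_bond = 1e7, r0 = 1, sep = 2.5)
  expect_error(
    run_dynamics(st, integrator_params(dt = 0.05, temperature = 0, gamma = 0,
                                       n_steps = 5000, com_interval = 0)),
    "diverged"
  )
})
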