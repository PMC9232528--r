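test_that("neat TAG melts build at the requested size, homogeneous after thermalization", {
  m1 <- build_neat_tag(24, density = 0.9, seed = 3)
  expect_equal(length(m1$molecules), 24)
  expect_true(m1$pbc_z)
  expect_identical(m1$positions,
                   build_neat_tag(24, density = 0.9, seed = 3)$positions)
  m1 <- thermalize(m1, 2500, seed = 4)
  prof <- melt_density_profile(m1, nc = 2)
  # thermalized melt is void-free: with ~30 beads per octant the counting
  # fluctuation is ~18%, so the check targets cavitation, not noise
  expect_gt(min(prof$density), 0.5 * mean(prof$density))
  expect_lt(abs(mean(prof$density) - 0.9) / 0.9, 0.05)
  expect_error(build_neat_tag(0), "n_tag")
})

test_that("zero force produces no detected drift", {
  fb <- free_bead_state()
  proto <- pull_protocol(force_start = 0, force_step = 0.5, interval = 2000,
                         min_disp = 5, max_levels = 1)
  expect_error(
    stepwise_pull(fb, 1L, proto, integrator_params(gamma = 1, seed = 2)),
    "no-drift"
  )
})

test_that("a free bead under any positive force drifts at the first level", {
  fb <- free_bead_state()
  proto <- pull_protocol(force_start = 2, force_step = 1, interval = 1e5,
                         min_disp = 5)
  pull <- stepwise_pull(fb, 1L, proto,
                        integrator_params(gamma = 2, seed = 3,
                                          com_interval = 0))
  expect_equal(pull$detected_level, 1L)
  expect_true(pull$levels$drift_detected[1])
})

test_that("the friction estimator recovers the Langevin bath collision rate within 5%", {
  fb <- free_bead_state()
  proto <- pull_protocol(force_start = 1, force_step = 0.5, interval = 2e5,
                         min_disp = 20)
  res <- measure_friction(fb, 1L, proto,
                          integrator_params(gamma = 2, seed = 5,
                                            com_interval = 0))
  expect_lt(abs(res$zeta - 2) / 2, 0.05)
  expect_gt(res$r2, 0.95)
})

test_that("zeta is force-independent in the linear-response regime (within 10%)", {
  fb <- free_bead_state()
  zs <- vapply(c(1, 2), function(f) {
    proto <- pull_protocol(force_start = f, force_step = 0.5, interval = 1.5e5,
                           min_disp = 15)
    measure_friction(fb, 1L, proto,
                     integrator_params(gamma = 2, seed = 7,
                                       com_interval = 0))$zeta
  }, numeric(1))
  expect_lt(abs(zs[2] - zs[1]) / zs[1], 0.10)
})

test_that("drift detection level is seed-robust within one force step", {
  levels <- vapply(1:3, function(s) {
    fb <- free_bead_state()
    proto <- pull_protocol(force_start = 0.5, force_step = 0.5,
                           interval = 2e4, min_disp = 4)
    stepwise_pull(fb, 1L, proto,
                  integrator_params(gamma = 2, seed = s,
                                    com_interval = 0))$detected_level
  }, integer(1))
  expect_lte(max(levels) - min(levels), 1L)
})

test_that("unreliable drift fits are rejected", {
  # a diffusing bead with no applied force has no positive drift to fit
  fb <- free_bead_state()
  tr <- run_dynamics(
    fb, integrator_params(gamma = 1, n_steps = 5000, seed = 9,
                          com_interval = 0),
    reporter_config(stride_cv = 20), cv = list(enabled = TRUE, solute_id = 1)
  )
  expect_error(estimate_friction(tr$cv, force = 1, mass = 1), "unreliable-fit")
})
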