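test_that("multiwalker metadynamics on a slab deposits shared hills deterministically", {
  cfg <- system_config(n_phospholipid = 12, n_tag = 10, n_tail_beads = 3,
                       seed = 5)
  st <- assemble_slab(cfg)
  st <- thermalize(st, 1000, seed = 6)
  st <- calibrate_slab_references(st)
  st <- insert_solute(st, "flexible", seed = 7)
  mp <- metad_params(
    cvs = c("z", "mu"), sigma = c(z = 0.3, mu = 0.08), omega0 = 0.5,
    pace = 100, gamma_wt = 10, n_walkers = 2,
    grid = list(z = c(-8, 4, 61), mu = c(0, 1, 21)),
    sync_interval = 1000, seed = 9
  )
  res <- run_metadynamics(
    st, mp, integrator_params(n_steps = 2000, seed = 9),
    solute_id = length(st$molecules)
  )
  # both walkers deposited; hills are time-ordered; FES is finite and
  # min-shifted to zero
  expect_setequal(unique(res$bias$hills$walker), c(1, 2))
  expect_true(!is.unsorted(res$bias$hills$time))
  expect_equal(nrow(res$bias$hills), 2 * (2000 %/% 100))
  expect_true(all(is.finite(res$fes$F)))
  expect_equal(min(res$fes$F), 0)
  # well-tempered: heights never exceed omega0 and decay where revisited
  expect_true(all(res$bias$hills$height <= 0.5 + 1e-12))
  # determinism of the whole multiwalker orchestration
  res2 <- run_metadynamics(
    st, mp, integrator_params(n_steps = 2000, seed = 9),
    solute_id = length(st$molecules)
  )
  expect_identical(res$bias$hills, res2$bias$hills)
})

test_that("biased dynamics feels the grid bias through the CV chain rule", {
  # a biased run's solute samples a wider depth range than an unbiased one
  cfg <- system_config(n_phospholipid = 12, n_tag = 10, n_tail_beads = 3,
                       seed = 11)
  st <- assemble_slab(cfg)
  st <- thermalize(st, 1000, seed = 12)
  st <- calibrate_slab_references(st)
  st <- insert_solute(st, "flexible", seed = 13)
  sid <- length(st$molecules)
  mp <- metad_params(
    cvs = "z", sigma = c(z = 0.4), omega0 = 1.5, pace = 50, gamma_wt = 15,
    grid = list(z = c(-8, 4, 61)), seed = 3
  )
  unb <- run_dynamics(
    st, integrator_params(n_steps = 6000, seed = 14),
    reporter_config(stride_cv = 25), cv = list(enabled = TRUE, solute_id = sid)
  )
  bia <- run_dynamics(
    st, integrator_params(n_steps = 6000, seed = 14),
    reporter_config(stride_cv = 25), metad = mp,
    cv = list(enabled = TRUE, solute_id = sid)
  )
  expect_gt(nrow(bia$hills), 0)
  expect_gt(diff(range(bia$cv$z)), diff(range(unb$cv$z)))
})

test_that("explicit-solvent slabs assemble with solvent beads and run stably", {
  cfg <- system_config(n_phospholipid = 12, n_tag = 8, n_solvent = 120,
                       n_tail_beads = 3, seed = 21)
  st <- assemble_slab(cfg)
  expect_equal(sum(st$beads$type_id == "W"), 120)
  expect_false(isTRUE(st$field$enabled)) # explicit water, no implicit field
  tr <- run_dynamics(
    st, integrator_params(n_steps = 1500, seed = 22),
    reporter_config(stride_energy = 500)
  )
  expect_true(all(is.finite(tr$energy$e_pot)))
  # solvent stays outside the TAG core (expelled by the WCA cross pairs)
  stf <- tr$state
  w <- which(stf$beads$type_id == "W")
  zc <- mean(range(stf$positions[stf$beads$molecule_class == "tag", 3]))
  th <- cfg$tag_slab_thickness
  frac_inside <- mean(abs(stf$positions[w, 3] - zc) < th / 4)
  expect_lt(frac_inside, 0.05)
})
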