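make_cv_state <- function(head_z = 5, solute_xyz) {
  types <- default_bead_types()
  heads <- ldflex:::new_topology(
    "phospholipid", types[rep(which(types$type_id == "H"), 4), ],
    ldflex:::empty_bonds(), ldflex:::empty_angles(), ldflex:::empty_dihedrals()
  )
  sol <- build_solute("rigid", nrow(solute_xyz), 2.4)
  new_state(
    list(
      list(topology = heads, xyz = cbind(1:4, 1:4, head_z)),
      list(topology = sol, xyz = solute_xyz)
    ),
    box = c(30, 30, 30), pbc_z = FALSE
  )
}

test_that("migration depth is the COM z relative to the head plane, negative into the core", {
  sol <- cbind(5, 5, seq(2.5, 3.5, length.out = 3))
  st <- make_cv_state(head_z = 5, solute_xyz = sol)
  expect_equal(migration_depth(st, 2, "upper"), -2)
  # solute COM on the head plane -> 0
  sol0 <- cbind(5, 5, seq(4.5, 5.5, length.out = 3))
  st0 <- make_cv_state(head_z = 5, solute_xyz = sol0)
  expect_equal(migration_depth(st0, 2, "upper"), 0, tolerance = 1e-12)
})

test_that("migration depth matches a brute-force mass-weighted oracle and is z-shift invariant", {
  for (seed in 1:5) {
    xyz <- ldflex:::with_seed(seed, matrix(runif(9, 2, 8), 3))
    st <- make_cv_state(head_z = 10, solute_xyz = xyz)
    idx <- st$molecules[[2]]$first:st$molecules[[2]]$last
    m <- st$beads$mass[idx]
    oracle <- sum(m * st$positions[idx, 3]) / sum(m) - 10
    expect_equal(migration_depth(st, 2, "upper"), oracle, tolerance = 1e-12)
    shifted <- st
    shifted$positions[, 3] <- shifted$positions[, 3] + 3.21
    expect_equal(migration_depth(shifted, 2, "upper"),
                 migration_depth(st, 2, "upper"), tolerance = 1e-10)
  }
})

test_that("end-to-end distance and z-component follow the geometry", {
  sol <- rbind(c(5, 5, 2), c(5, 5, 3.2), c(5, 5, 4.4))
  st <- make_cv_state(5, sol)
  ee <- end_to_end(st, 2)
  expect_equal(unname(ee["r_ee"]), 2.4, tolerance = 1e-12)
  expect_equal(unname(ee["z_ee"]), 2.4, tolerance = 1e-12)
  # rod in the xy-plane: z_ee = 0
  sol2 <- rbind(c(5, 5, 2), c(6.2, 5, 2), c(7.4, 5, 2))
  st2 <- make_cv_state(5, sol2)
  ee2 <- end_to_end(st2, 2)
  expect_equal(unname(ee2["r_ee"]), 2.4, tolerance = 1e-12)
  expect_equal(unname(ee2["z_ee"]), 0, tolerance = 1e-12)
})

test_that("conformation order and orientation angle are consistent", {
  expect_equal(conformation_order(2.4, 2.4), 1)
  expect_equal(conformation_order(2.4, 0), 0)
  expect_equal(conformation_order(2.4, 1.2), 0.5)
  expect_equal(conformation_order(2.4, -1.2), 0.5) # sign of z_ee irrelevant
  expect_equal(orientation_angle(1), 0)
  expect_equal(orientation_angle(0), 90)
  expect_equal(orientation_angle(0.5), 60)
  expect_error(conformation_order(0, 0), "undefined-CV")
  expect_error(orientation_angle(1.5), "mu")
  # arccos round trip
  mus <- seq(0, 1, by = 0.05)
  expect_equal(cos(orientation_angle(mus) * pi / 180), mus, tolerance = 1e-12)
})

test_that("streamed CVs equal CVs recomputed from written frames", {
  st <- make_fluid(30, 8, wca = FALSE, seed = 3)
  top <- build_solute("flexible", 6, 4)
  st2 <- new_state(
    c(
      list(list(
        topology = top,
        xyz = linear_chain_coords(top) + 4
      )),
      lapply(seq_along(st$molecules), function(i) {
        list(
          topology = ldflex:::new_topology(
            "tracer", default_bead_types()[5, ], ldflex:::empty_bonds(),
            ldflex:::empty_angles(), ldflex:::empty_dihedrals()
          ),
          xyz = st$positions[i, , drop = FALSE]
        )
      })
    ),
    box = st$box, pbc_z = TRUE
  )
  tr <- run_dynamics(
    st2, integrator_params(n_steps = 500, seed = 4),
    reporter_config(stride_frames = 50, stride_cv = 50),
    cv = list(enabled = TRUE, solute_id = 1)
  )
  re <- cv_from_frames(tr, solute_id = 1)
  streamed <- tr$cv[tr$cv$time %in% re$time, ]
  expect_equal(streamed$r_ee, re$r_ee, tolerance = 1e-9)
  expect_equal(streamed$mu, re$mu, tolerance = 1e-9)
})
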