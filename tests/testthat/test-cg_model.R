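test_that("molecule templates have closed-form bead/bond counts", {
  cases <- list(
    list(top = build_phospholipid(4), beads = 9, bonds = 8, polar = 1),
    list(top = build_phospholipid(2), beads = 5, bonds = 4, polar = 1),
    list(top = build_tag(4), beads = 13, bonds = 12, polar = 0),
    list(top = build_tag(2), beads = 7, bonds = 6, polar = 0),
    list(top = build_solute("rigid", 3, 2), beads = 3, bonds = 2, polar = 0)
  )
  for (cs in cases) {
    cnt <- topology_counts(cs$top)
    expect_equal(cnt$n_beads, cs$beads)
    expect_equal(cnt$n_bonds, cs$bonds)
    expect_equal(cnt$n_polar, cs$polar)
  }
  # three-bead rigid chain has exactly one stiff angle
  expect_equal(topology_counts(build_solute("rigid", 3, 2))$n_angles, 1)
})

test_that("TAG tails attach to the hub with identical bond parameters and all-apolar beads", {
  top <- build_tag(4)
  hub_bonds <- top$bonds[top$bonds$i == 1L, ]
  expect_equal(nrow(hub_bonds), 3)
  expect_equal(length(unique(hub_bonds$k_bond)), 1)
  expect_equal(length(unique(hub_bonds$r0)), 1)
  expect_true(all(top$beads$polarity == "apolar"))
})

test_that("invalid topologies are rejected", {
  expect_error(build_phospholipid(1), "invalid-topology")
  expect_error(build_tag(1), "invalid-topology")
  expect_error(build_solute("floppy"), "unknown flexibility")
  expect_error(build_solute("rigid", 2, 1), "invalid-topology")
  expect_error(build_solute("rigid", 8, -1), "contour_length")
})

test_that("rigid solute stiffness is at least 50x the flexible solute's", {
  rig <- build_solute("rigid", 8, 6.79)
  flex <- build_solute("flexible", 8, 6.79)
  expect_gte(min(rig$angles$k_angle) / max(flex$angles$k_angle), 50)
  expect_gte(min(rig$dihedrals$k_dih) / max(flex$dihedrals$k_dih), 50)
  expect_equal(rig$end_indices, c(1L, 8L))
  # rigid_polar gets polar terminal beads, plain rigid stays apolar
  rp <- build_solute("rigid_polar", 8, 6.79)
  expect_equal(rp$beads$polarity[c(1, 8)], rep("polar_terminal", 2))
  expect_true(all(rig$beads$polarity == "apolar"))
})

test_that("slab assembly is seed-deterministic and respects the overlap criterion", {
  cfg <- system_config(
    n_phospholipid = 12, n_tag = 8, n_tail_beads = 3,
    solutes = list(list(
      flexibility = "flexible", n_beads = 8,
      contour_length = 6.79, placement = "cytosol"
    )),
    seed = 7
  )
  st1 <- assemble_slab(cfg)
  st2 <- assemble_slab(cfg)
  expect_identical(st1$positions, st2$positions)
  expect_gte(min_pair_distance(st1), 0.85)
  # composition: 2 leaflets + TAGs + 1 solute
  expect_equal(length(st1$molecules), 12 * 2 + 8 + 1)
})

test_that("assembled monolayer heads sit outside the TAG slab", {
  cfg <- system_config(n_phospholipid = 12, n_tag = 8, n_tail_beads = 3, seed = 2)
  st <- assemble_slab(cfg)
  heads <- which(st$beads$type_id == "H")
  zc <- mean(st$positions[, 3])
  expect_true(all(abs(st$positions[heads, 3] - zc) >
    cfg$tag_slab_thickness / 2))
})

test_that("infeasible packing is rejected with the offending species named", {
  expect_error(
    system_config(n_phospholipid = 16, n_tag = 600, n_tail_beads = 3,
                  box = c(6, 6, 12)),
    "packing infeasible"
  )
})

test_that("topology TSV dump is human-readable and complete", {
  top <- build_solute("rigid", 8, 6.79)
  path <- withr_local_file("topology.tsv")
  write_topology(top, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# beads\t8", lines)))
  expect_true(any(grepl("^# bonds\t7", lines)))
  expect_true(any(grepl("^# end_indices\t1\t8", lines)))
})
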