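# small reusable builders for engine tests

make_dimer <- function(k_bond = 50, r0 = 1, sep = 1.2, box = 10) {
  types <- default_bead_types()
  top <- ldflex:::new_topology(
    "tracer_pair", types[rep(which(types$type_id == "S"), 2), ],
    tibble::tibble(i = 1L, j = 2L, k_bond = k_bond, r0 = r0),
    ldflex:::empty_angles(), ldflex:::empty_dihedrals()
  )
  new_state(
    list(list(topology = top, xyz = rbind(
      c(box / 2, box / 2, box / 2), c(box / 2, box / 2, box / 2 + sep)
    ))),
    box = rep(box, 3), pbc_z = TRUE
  )
}

# fluid of n non-bonded single beads, optionally WCA (repulsive-only)
make_fluid <- function(n, box, wca = TRUE, seed = 1, type = "S") {
  types <- default_bead_types()
  pair <- pair_tables(types, wca = wca)
  top <- ldflex:::new_topology(
    "tracer", types[types$type_id == type, ],
    ldflex:::empty_bonds(), ldflex:::empty_angles(), ldflex:::empty_dihedrals()
  )
  xyz <- ldflex:::with_seed(seed, matrix(runif(3 * n, 0, box), ncol = 3))
  mols <- lapply(seq_len(n), function(i) list(topology = top, xyz = xyz[i, , drop = FALSE]))
  st <- new_state(mols, box = rep(box, 3), pbc_z = TRUE, pair = pair)
  ldflex:::relax_overlaps(st)
}

# ideal-gas tracers (no interactions): for diffusion statistics
make_gas <- function(n, box, seed = 1) {
  types <- default_bead_types()
  types$lj_epsilon <- 0
  pair <- pair_tables(types)
  top <- ldflex:::new_topology(
    "tracer", types[types$type_id == "S", ],
    ldflex:::empty_bonds(), ldflex:::empty_angles(), ldflex:::empty_dihedrals()
  )
  xyz <- ldflex:::with_seed(seed, matrix(runif(3 * n, 0, box), ncol = 3))
  mols <- lapply(seq_len(n), function(i) list(topology = top, xyz = xyz[i, , drop = FALSE]))
  new_state(mols, box = rep(box, 3), pbc_z = TRUE, pair = pair)
}

# random small bonded system for force-consistency property tests; torsion
# forces are tapered off near collinear chains, so configurations whose
# dihedral flanking angles fall inside the taper band (where the taper
# factor varies and the gradient is intentionally approximate) are
# rejected and redrawn
dihedral_in_taper_band <- function(state) {
  d <- state$dihedrals
  if (!nrow(d)) return(FALSE)
  p <- state$positions
  sin2 <- function(i, j, k) {
    b1 <- p[j + 1, ] - p[i + 1, ]
    b2 <- p[k + 1, ] - p[j + 1, ]
    n <- c(
      b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
      b1[1] * b2[2] - b1[2] * b2[1]
    )
    sum(n^2) / (sum(b1^2) * sum(b2^2))
  }
  for (r in seq_len(nrow(d))) {
    s1 <- sin2(d[r, 1], d[r, 2], d[r, 3])
    s2 <- sin2(d[r, 2], d[r, 3], d[r, 4])
    if ((s1 > 0.015 && s1 < 0.09) || (s2 > 0.015 && s2 < 0.09)) return(TRUE)
  }
  FALSE
}

make_random_molecules <- function(seed) {
  for (try_seed in seed + (0:20) * 1000) {
    st <- ldflex:::with_seed(try_seed, {
      mols <- list(
        list(
          topology = build_solute("flexible", 6, 5),
          xyz = linear_chain_coords(build_solute("flexible", 6, 5)) +
            matrix(rnorm(18, 0, 0.25), 6) + 5
        ),
        list(
          topology = build_tag(3),
          xyz = ldflex:::template_coords(build_tag(3)) +
            matrix(rnorm(30, 0, 0.2), 10) + 9
        ),
        list(
          topology = build_phospholipid(3),
          xyz = ldflex:::template_coords(build_phospholipid(3)) +
            matrix(rnorm(21, 0, 0.2), 7) + c(rep(12, 7), rep(12, 7), rep(5, 7))
        )
      )
      new_state(mols, box = c(16, 16, 16), pbc_z = TRUE)
    })
    if (!dihedral_in_taper_band(st)) return(st)
  }
  st
}

finite_difference_forces <- function(state, beads, h = 1e-5) {
  f0 <- compute_forces(state)
  out <- list()
  for (i in beads) {
    g <- numeric(3)
    for (d in 1:3) {
      sp <- state
      sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- state
      sm$positions[i, d] <- sm$positions[i, d] - h
      g[d] <- -(compute_forces(sp)$energy - compute_forces(sm)$energy) / (2 * h)
    }
    out[[as.character(i)]] <- list(analytic = f0$forces[i, ], fd = g)
  }
  out
}

withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e9, 1), "-", name))
  withr::defer(unlink(path), envir = env)
  path
}
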