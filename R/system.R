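#' System configuration for the monolayer/TAG slab
#'
#' Describes the composition and geometry of the water | phospholipid
#' monolayer | TAG core | phospholipid monolayer | water slab. The box
#' cross-section follows from the phospholipid count at the target area
#' per lipid, and the TAG-core thickness from the TAG count at the target
#' melt bead density, so composition and geometry stay consistent.
#'
#' @param n_phospholipid Phospholipids per leaflet (two leaflets built).
#' @param n_tag TAG molecules in the core.
#' @param n_solvent Explicit solvent beads (0 = implicit-solvent mode:
#'   Langevin bath plus soft reflective z-walls above the monolayers).
#' @param solutes List of solute descriptors, each a list with
#'   `flexibility`, `n_beads`, `contour_length` and `placement` (one of
#'   `"cytosol"`, `"interface"`, `"core"`).
#' @param n_tail_beads Beads per phospholipid/TAG tail.
#' @param area_per_lipid Monolayer area per phospholipid (sigma^2).
#' @param density Target TAG melt bead density (sigma^-3).
#' @param solvent_gap Height of the solvent/cytosol region above each
#'   head-group plane (sigma).
#' @param box Optional explicit box (Lx, Ly, Lz); when given, the packing
#'   feasibility of the requested composition inside it is checked.
#' @param seed Integer seed controlling the random placement.
#' @return A `cg_config` list; `tag_slab_thickness` and `box` are derived.
#' @export
#' @examples
#' cfg <- system_config(n_phospholipid = 16, n_tag = 8)
system_config <- function(n_phospholipid = 64, n_tag = 140, n_solvent = 0,
                          solutes = list(), n_tail_beads = 4,
                          area_per_lipid = 2.4, density = 0.8,
                          solvent_gap = 5, box = NULL, seed = 1) {
  for (v in c(n_phospholipid, n_tag, n_solvent)) {
    if (!is.numeric(v) || v < 0) abort("counts must be >= 0")
  }
  r0 <- 0.97
  lx <- if (!is.null(box)) {
    box[1]
  } else if (n_phospholipid > 0) {
    sqrt(n_phospholipid * area_per_lipid)
  } else {
    max(8, (n_tag * (1 + 3 * n_tail_beads) / density)^(1 / 3))
  }
  beads_per_tag <- 1 + 3 * n_tail_beads
  thick <- if (n_tag > 0) n_tag * beads_per_tag / (density * lx^2) else 0
  tail_len <- n_tail_beads * r0
  mono_h <- tail_len + 1
  lz <- if (!is.null(box)) box[3] else thick + 2 * mono_h + 2 * solvent_gap
  cfg <- structure(
    list(
      n_phospholipid = as.integer(n_phospholipid), n_tag = as.integer(n_tag),
      n_solvent = as.integer(n_solvent), solutes = solutes,
      n_tail_beads = as.integer(n_tail_beads),
      area_per_lipid = area_per_lipid, density = density,
      solvent_gap = solvent_gap,
      box = if (!is.null(box)) box else c(lx, lx, lz),
      tag_slab_thickness = thick, seed = as.integer(seed)
    ),
    class = "cg_config"
  )
  if (cfg$tag_slab_thickness >= lz) {
    abort(sprintf(
      "packing infeasible: TAG slab thickness %.1f exceeds box height %.1f (species: tag)",
      cfg$tag_slab_thickness, lz
    ))
  }
  # feasibility: overall bead packing fraction of the slab interior
  nb <- n_phospholipid * 2 * (1 + 2 * n_tail_beads) +
    n_tag * beads_per_tag + n_solvent +
    sum(vapply(solutes, function(s) s$n_beads %||% 8L, numeric(1)))
  pack <- nb * pi / 6 / (lx^2 * lz)
  if (pack > 0.9) {
    dominant <- c("phospholipid", "tag", "solvent")[which.max(c(
      n_phospholipid * 2 * (1 + 2 * n_tail_beads), n_tag * beads_per_tag,
      n_solvent
    ))]
    abort(sprintf(
      "packing infeasible: fraction %.2f > 0.9 (species: %s)", pack, dominant
    ))
  }
  cfg
}

#' Desk-scale default slab configuration
#'
#' 64 phospholipids per leaflet and 140 TAGs, the reference composition
#' (256 phospholipids / 555 TAGs) scaled down by ~4x, implicit solvent.
#'
#' @param solutes Solute descriptor list, as in [system_config()].
#' @param seed Integer seed.
#' @return A `cg_config`.
#' @export
desk_config <- function(solutes = list(), seed = 1) {
  system_config(n_phospholipid = 64, n_tag = 140, solutes = solutes, seed = seed)
}

#' Miniature slab configuration for fast runs
#'
#' 32 phospholipids per leaflet over a ~6-sigma TAG core; used for
#' test-scale migration runs.
#'
#' @param solutes Solute descriptor list.
#' @param seed Integer seed.
#' @return A `cg_config`.
#' @export
mini_config <- function(solutes = list(), seed = 1) {
  system_config(
    n_phospholipid = 32, n_tag = 36, n_tail_beads = 3,
    solutes = solutes, seed = seed
  )
}

solute_descriptor <- function(flexibility = "flexible", n_beads = 8,
                              contour_length = 6.79, placement = "cytosol") {
  list(
    flexibility = flexibility, n_beads = as.integer(n_beads),
    contour_length = contour_length, placement = placement
  )
}

#' Low-level state constructor
#'
#' Builds a `cg_state` from explicit molecule instances. Used by
#' [assemble_slab()] and [build_neat_tag()] and directly by small test
#' systems (free beads, WCA fluids, dimers).
#'
#' @param molecules List of entries `list(topology =, xyz =)` giving each
#'   molecule's template and its placed coordinates (n_beads x 3).
#' @param box Numeric length-3 box.
#' @param pbc_z Logical; z-periodic (melts) or slab mode (walls).
#' @param walls List `(enabled, zlo, zhi, k)`; defaults disabled.
#' @param pair Pair tables from [pair_tables()]; defaults to the package
#'   tables over [default_bead_types()].
#' @param time Simulation time carried by the state.
#' @return A `cg_state`.
#' @export
new_state <- function(molecules, box, pbc_z = FALSE, walls = NULL,
                      pair = pair_tables(), time = 0) {
  types <- rownames(pair$eps)
  beads_l <- list()
  bonds_l <- list()
  angles_l <- list()
  dih_l <- list()
  excl_l <- list()
  mol_info <- list()
  pos_l <- list()
  off <- 0L
  for (m in seq_along(molecules)) {
    top <- molecules[[m]]$topology
    xyz <- molecules[[m]]$xyz
    n <- nrow(top$beads)
    stopifnot(nrow(xyz) == n)
    t0 <- match(top$beads$type_id, types) - 1L
    if (anyNA(t0)) abort("topology uses bead types absent from pair tables")
    beads_l[[m]] <- tibble(
      molecule_id = m, molecule_class = top$molecule_class,
      type_id = top$beads$type_id, type0 = t0, mass = top$beads$mass,
      polarity = top$beads$polarity
    )
    if (nrow(top$bonds)) {
      bonds_l[[m]] <- cbind(top$bonds$i - 1 + off, top$bonds$j - 1 + off,
                            top$bonds$k_bond, top$bonds$r0)
    }
    if (nrow(top$angles)) {
      angles_l[[m]] <- cbind(top$angles$i - 1 + off, top$angles$j - 1 + off,
                             top$angles$k - 1 + off, top$angles$k_angle,
                             top$angles$theta0)
    }
    if (nrow(top$dihedrals)) {
      dih_l[[m]] <- cbind(top$dihedrals$i - 1 + off, top$dihedrals$j - 1 + off,
                          top$dihedrals$k - 1 + off, top$dihedrals$l - 1 + off,
                          top$dihedrals$k_dih, top$dihedrals$multiplicity,
                          top$dihedrals$phase)
    }
    excl_l[[m]] <- topology_exclusions(top) + off
    mol_info[[m]] <- list(
      class = top$molecule_class, first = off + 1L, last = off + n,
      end_indices = if (!is.null(top$end_indices)) top$end_indices + off
    )
    pos_l[[m]] <- xyz
    off <- off + n
  }
  beads <- bind_rows(beads_l)
  to_mat <- function(l, ncol) {
    if (length(l)) do.call(rbind, l) else matrix(0, 0, ncol)
  }
  structure(
    list(
      positions = do.call(rbind, pos_l),
      velocities = matrix(0, off, 3),
      box = box, pbc_z = pbc_z, time = time,
      walls = walls %||% list(enabled = FALSE, zlo = 0, zhi = 0, k = 10),
      beads = beads,
      bonds = to_mat(bonds_l, 4), angles = to_mat(angles_l, 5),
      dihedrals = to_mat(dih_l, 7),
      exclusions = {
        e <- to_mat(excl_l, 2)
        storage.mode(e) <- "integer"
        e
      },
      pair = pair, molecules = mol_info,
      field = list(enabled = FALSE)
    ),
    class = "cg_state"
  )
}

# nonbonded exclusions: pairs within bond-graph distance <= 2 (0-based)
topology_exclusions <- function(top) {
  n <- nrow(top$beads)
  if (!nrow(top$bonds)) return(matrix(integer(), 0, 2))
  adj <- vector("list", n)
  for (b in seq_len(nrow(top$bonds))) {
    i <- top$bonds$i[b]; j <- top$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1]))
    near <- setdiff(unique(c(d1, d2)), i)
    near <- near[near > i]
    if (length(near)) out[[length(out) + 1L]] <- cbind(i, near)
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 2)
  m - 1L
}

#' Molecule ids of solutes in a state
#'
#' @param state A `cg_state`.
#' @return Integer vector of molecule ids whose class starts `solute_`.
#' @export
solute_ids <- function(state) {
  which(vapply(state$molecules, function(m) grepl("^solute", m$class), logical(1)))
}

solute_info <- function(state, solute_id) {
  if (solute_id < 1 || solute_id > length(state$molecules)) {
    abort("missing solute: molecule id out of range")
  }
  state$molecules[[solute_id]]
}

head_bead_indices <- function(state, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  heads <- which(state$beads$type_id == "H")
  if (!length(heads)) return(integer())
  zc <- if (state$pbc_z) state$box[3] / 2 else mean(state$positions[, 3])
  hz <- state$positions[heads, 3]
  if (leaflet == "upper") heads[hz >= zc] else heads[hz < zc]
}

random_rotation <- function() {
  # uniform random rotation matrix via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Assemble the monolayer | TAG | monolayer slab
#'
#' Builds molecule templates, places the TAG core centered in z with the
#' two phospholipid monolayers head-out above and below, places solutes in
#' their requested regions, then relaxes overlaps by capped
#' steepest-descent minimization until no nonbonded pair is closer than
#' 0.85 sigma. Placement is deterministic given `config$seed`.
#'
#' @param config A [system_config()] object.
#' @param templates Optional named list overriding the default templates
#'   (`phospholipid`, `tag`, `solvent`).
#' @return A `cg_state` (velocities zero; thermalize before production).
#' @export
assemble_slab <- function(config, templates = NULL) {
  templates <- templates %||% list(
    phospholipid = build_phospholipid(config$n_tail_beads),
    tag = build_tag(config$n_tail_beads),
    solvent = build_solvent_bead()
  )
  r0 <- 0.97
  lx <- config$box[1]
  lz <- config$box[3]
  zc <- lz / 2
  th <- config$tag_slab_thickness
  tail_len <- config$n_tail_beads * r0
  hz_up <- zc + th / 2 + tail_len + 0.5
  hz_lo <- zc - th / 2 - tail_len - 0.5
  mols <- list()
  with_seed(config$seed, {
    # TAG core: random placement inside the slab region
    for (i in seq_len(config$n_tag)) {
      ref <- template_coords(templates$tag) %*% random_rotation()
      com <- c(runif(1, 0, lx), runif(1, 0, lx),
               runif(1, zc - th / 2 + 1, zc + th / 2 - 1))
      mols[[length(mols) + 1L]] <- list(
        topology = templates$tag, xyz = sweep(ref, 2, -com)
      )
    }
    # monolayers: heads out, straight tails toward the core, jittered grid
    npl <- config$n_phospholipid
    if (npl > 0) {
      ng <- ceiling(sqrt(npl))
      grid_xy <- expand.grid(
        x = (seq_len(ng) - 0.5) * lx / ng,
        y = (seq_len(ng) - 0.5) * lx / ng
      )[seq_len(npl), ]
      for (side in c(1, -1)) {
        hz <- if (side > 0) hz_up else hz_lo
        for (i in seq_len(npl)) {
          top <- templates$phospholipid
          n_tb <- config$n_tail_beads
          xyz <- matrix(0, 1 + 2 * n_tb, 3)
          xy <- c(grid_xy$x[i] + runif(1, -0.1, 0.1),
                  grid_xy$y[i] + runif(1, -0.1, 0.1))
          xyz[1, ] <- c(xy, hz)
          for (t in 1:2) {
            dxy <- c(0.35, -0.35)[t]
            for (b in seq_len(n_tb)) {
              xyz[1 + (t - 1) * n_tb + b, ] <-
                c(xy[1] + dxy, xy[2], hz - side * b * r0)
            }
          }
          mols[[length(mols) + 1L]] <- list(topology = top, xyz = xyz)
        }
      }
    }
    # solutes
    for (s in config$solutes) {
      top <- build_solute(s$flexibility, s$n_beads, s$contour_length)
      ref <- linear_chain_coords(top)
      com <- switch(s$placement,
        cytosol = c(runif(1, 0, lx), runif(1, 0, lx), hz_up + 2.5),
        interface = c(runif(1, 0, lx), runif(1, 0, lx), hz_up),
        core = c(runif(1, 0, lx), runif(1, 0, lx), zc),
        abort(sprintf("unknown placement region: %s", s$placement))
      )
      # lie flat (in xy) when starting in the thin cytosol region
      rot <- if (s$placement == "cytosol") {
        ang <- runif(1, 0, 2 * pi)
        rbind(c(cos(ang), sin(ang), 0), c(-sin(ang), cos(ang), 0), c(0, 0, 1))
      } else {
        random_rotation()
      }
      mols[[length(mols) + 1L]] <- list(
        topology = top, xyz = sweep(ref %*% rot, 2, -com)
      )
    }
    # explicit solvent above/below the monolayers
    for (i in seq_len(config$n_solvent)) {
      side <- if (i %% 2 == 0) 1 else -1
      zr <- if (side > 0) c(hz_up + 1, lz - 1) else c(1, hz_lo - 1)
      mols[[length(mols) + 1L]] <- list(
        topology = templates$solvent,
        xyz = matrix(c(runif(1, 0, lx), runif(1, 0, lx), runif(1, zr[1], zr[2])), 1)
      )
    }
  })
  walls <- list(
    enabled = TRUE, zlo = hz_lo - config$solvent_gap + 1,
    zhi = hz_up + config$solvent_gap - 1, k = 10
  )
  state <- new_state(mols, box = config$box, pbc_z = FALSE, walls = walls)
  state$config <- config
  state$head_planes <- c(lower = hz_lo, upper = hz_up)
  if (config$n_solvent == 0) {
    # implicit solvent: solvophobic field stands in for the missing water,
    # pushing apolar beads out of the cytosol regions
    state$field <- list(
      enabled = TRUE, eps = 4, w = 0.5,
      z_upper = hz_up + 0.5, z_lower = hz_lo - 0.5, two_sided = TRUE,
      apolar = as.integer(state$beads$polarity == "apolar")
    )
  }
  relax_overlaps(state)
}

#' Straight-line reference coordinates for a linear chain
#'
#' COM-centered coordinates of a solute chain laid out straight along x;
#' the standard starting conformation for isolated-solute runs.
#'
#' @param top A linear `cg_topology` (e.g. from [build_solute()]).
#' @return Matrix `n_beads x 3`.
#' @export
linear_chain_coords <- function(top) {
  n <- nrow(top$beads)
  r0 <- top$bonds$r0[1]
  xyz <- cbind((seq_len(n) - 1) * r0, 0, 0)
  sweep(xyz, 2, colSums(xyz * top$beads$mass) / sum(top$beads$mass))
}

# capped steepest descent until the overlap criterion is met
relax_overlaps <- function(state, min_dist = 0.85, rounds = 6L,
                           iter_per_round = 300L) {
  for (r in seq_len(rounds)) {
    if (min_pair_distance(state) >= min_dist) break
    out <- cpp_minimize(
      state$positions, state$beads$mass, state$beads$type0, state$box,
      state$pbc_z, state$pair$eps, state$pair$sigma, state$pair$cutoff,
      state$bonds, state$angles, state$dihedrals, state$exclusions,
      state$walls, state$field, iter_per_round, 1.0, 0.05
    )
    state$positions <- out$positions
  }
  if (min_pair_distance(state) < min_dist) {
    dens <- state$beads$molecule_class[which_min_pair(state)]
    abort(sprintf(
      "placement error: could not relax overlaps below %.2f sigma (species: %s)",
      min_dist, paste(unique(dens), collapse = ", ")
    ))
  }
  state
}

#' Minimum nonbonded pair distance in a state
#'
#' Pairs excluded from nonbonded interactions (bond-graph distance <= 2)
#' are skipped.
#'
#' @param state A `cg_state`.
#' @return Scalar distance (reduced units).
#' @export
min_pair_distance <- function(state) {
  cpp_min_distance(state$positions, state$box, state$pbc_z, state$exclusions)
}

# beads of the closest nonbonded pair (diagnostic for placement errors)
which_min_pair <- function(state) {
  p <- state$positions
  n <- nrow(p)
  best <- c(1L, 2L)
  bd <- Inf
  ex <- paste(state$exclusions[, 1], state$exclusions[, 2])
  for (i in seq_len(n - 1)) {
    dx <- p[(i + 1):n, 1] - p[i, 1]
    dy <- p[(i + 1):n, 2] - p[i, 2]
    dz <- p[(i + 1):n, 3] - p[i, 3]
    dx <- dx - state$box[1] * round(dx / state$box[1])
    dy <- dy - state$box[2] * round(dy / state$box[2])
    if (state$pbc_z) dz <- dz - state$box[3] * round(dz / state$box[3])
    d2 <- dx^2 + dy^2 + dz^2
    j <- which.min(d2)
    if (d2[j] < bd && !(paste(i - 1L, i + j - 1L) %in% ex)) {
      bd <- d2[j]
      best <- c(i, i + j)
    }
  }
  best
}

#' Build a neat TAG melt
#'
#' Solvent-free, fully periodic TAG melt at the target bead density,
#' optionally with one solute chain inserted at the box center; used for
#' steered-pull friction estimation.
#'
#' @param n_tag Number of TAG molecules (desk default 60).
#' @param solute Optional solute descriptor (as in [system_config()]).
#' @param n_tail_beads Beads per TAG tail.
#' @param density Target bead density (sigma^-3).
#' @param seed Integer placement seed.
#' @return A `cg_state` with `pbc_z = TRUE` (not yet thermalized).
#' @export
build_neat_tag <- function(n_tag = 60, solute = NULL, n_tail_beads = 4,
                           density = 0.8, seed = 1) {
  if (n_tag < 1) abort("n_tag must be >= 1")
  tag <- build_tag(n_tail_beads)
  nb <- n_tag * nrow(tag$beads) +
    (if (!is.null(solute)) solute$n_beads else 0)
  side <- (nb / density)^(1 / 3)
  mols <- list()
  with_seed(seed, {
    if (!is.null(solute)) {
      top <- build_solute(solute$flexibility, solute$n_beads, solute$contour_length)
      mols[[1]] <- list(
        topology = top,
        xyz = sweep(linear_chain_coords(top), 2, -side / 2)
      )
    }
    for (i in seq_len(n_tag)) {
      ref <- template_coords(tag) %*% random_rotation()
      com <- runif(3, 0, side)
      mols[[length(mols) + 1L]] <- list(topology = tag, xyz = sweep(ref, 2, -com))
    }
  })
  state <- new_state(mols, box = rep(side, 3), pbc_z = TRUE)
  state$equilibrated <- FALSE
  relax_overlaps(state)
}

#' Local-density homogeneity of a melt
#'
#' Bead counts over an `nc^3` subcell grid, as a diagnostic that a
#' thermalized melt is homogeneous (no voids).
#'
#' @param state A periodic `cg_state`.
#' @param nc Cells per box edge.
#' @return Tibble with per-cell density and the global target.
#' @export
melt_density_profile <- function(state, nc = 3) {
  p <- state$positions
  b <- state$box
  ix <- pmin(nc - 1, floor(p[, 1] %% b[1] / (b[1] / nc)))
  iy <- pmin(nc - 1, floor(p[, 2] %% b[2] / (b[2] / nc)))
  iz <- pmin(nc - 1, floor(p[, 3] %% b[3] / (b[3] / nc)))
  cell <- ix * nc^2 + iy * nc + iz
  counts <- tabulate(cell + 1, nbins = nc^3)
  vol <- prod(b) / nc^3
  tibble(
    cell = seq_len(nc^3), density = counts / vol,
    target = nrow(p) / prod(b)
  )
}
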