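#' Bead specification
#'
#' A coarse-grained bead type: reduced mass, Lennard-Jones parameters and a
#' polarity class used to build hydrophobicity-scaled cross interactions.
#'
#' @param type_id Short string label (e.g. `"T"` for an apolar tail bead).
#' @param mass Reduced mass, > 0.
#' @param lj_epsilon Reduced LJ well depth, >= 0.
#' @param lj_sigma Reduced LJ diameter, > 0.
#' @param polarity One of `"polar"`, `"apolar"`, `"polar_terminal"`.
#' @return One-row tibble describing the bead type.
#' @export
bead_spec <- function(type_id, mass = 1, lj_epsilon = 1, lj_sigma = 1,
                      polarity = c("apolar", "polar", "polar_terminal")) {
  polarity <- match.arg(polarity)
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  stopifnot_scalar_number(lj_sigma, "lj_sigma", positive = TRUE)
  stopifnot_scalar_number(lj_epsilon, "lj_epsilon", nonneg = TRUE)
  tibble(
    type_id = as.character(type_id), mass = mass,
    lj_epsilon = lj_epsilon, lj_sigma = lj_sigma, polarity = polarity
  )
}

#' Default bead-type table
#'
#' Bead types: phospholipid head (H, polar) and tail (T, apolar; cohesion
#' 0.6 versus 1.0 for the TAG beads), TAG glycerol hub (C) and tail (G)
#' beads (apolar), flexible solute chain bead (S, apolar), wide rigid-rod
#' bead (R, apolar, sigma 1.3: ring-bearing rod-like lipids are thicker
#' than a thin isoprenoid chain), polar solute terminal (P), and explicit
#' solvent (W, polar).
#'
#' @return Tibble of [bead_spec()] rows.
#' @export
default_bead_types <- function() {
  bind_rows(
    bead_spec("H", polarity = "polar"),
    bead_spec("T", lj_epsilon = 0.6, polarity = "apolar"),
    bead_spec("C", polarity = "apolar"),
    bead_spec("G", polarity = "apolar"),
    bead_spec("S", polarity = "apolar"),
    bead_spec("R", lj_sigma = 1.3, polarity = "apolar"),
    bead_spec("P", polarity = "polar_terminal"),
    bead_spec("W", polarity = "polar")
  )
}

#' Pairwise Lennard-Jones tables from a bead-type table
#'
#' Cross-species interactions follow Lorentz-Berthelot combination; the
#' epsilon of polar/apolar cross pairs is scaled by `polar_apolar_scale`
#' to encode hydrophobic mismatch. Pairs can be switched to purely
#' repulsive WCA form (cutoff at the LJ minimum) via `wca`.
#'
#' @param beads Bead-type tibble as from [default_bead_types()].
#' @param polar_apolar_scale Epsilon scale for polar-apolar cross pairs.
#' @param cutoff Attractive-pair cutoff in units of the combined sigma.
#' @param wca If `TRUE`, all pairs are WCA (repulsive only).
#' @return List of square matrices `eps`, `sigma`, `cutoff` indexed by type.
#' @export
pair_tables <- function(beads = default_bead_types(), polar_apolar_scale = 0.3,
                        cutoff = 2.0, wca = FALSE) {
  nt <- nrow(beads)
  polar <- beads$polarity %in% c("polar", "polar_terminal")
  eps <- outer(beads$lj_epsilon, beads$lj_epsilon, function(a, b) sqrt(a * b))
  sig <- outer(beads$lj_sigma, beads$lj_sigma, function(a, b) (a + b) / 2)
  cross <- outer(polar, polar, FUN = "!=")
  eps[cross] <- eps[cross] * polar_apolar_scale
  # hydrophobic mismatch: polar-apolar pairs are repulsive-only (WCA), so
  # head groups and solvent are expelled from the oil phase
  cut <- if (wca) 2^(1 / 6) * sig else cutoff * sig
  cut[cross] <- 2^(1 / 6) * sig[cross]
  dimnames(eps) <- dimnames(sig) <- dimnames(cut) <-
    list(beads$type_id, beads$type_id)
  list(eps = eps, sigma = sig, cutoff = cut)
}

new_topology <- function(molecule_class, beads, bonds, angles, dihedrals,
                         end_indices = NULL) {
  top <- structure(
    list(
      molecule_class = molecule_class, beads = beads, bonds = bonds,
      angles = angles, dihedrals = dihedrals, end_indices = end_indices
    ),
    class = "cg_topology"
  )
  validate_topology(top)
  top
}

empty_bonds <- function() tibble(i = integer(), j = integer(), k_bond = double(), r0 = double())
empty_angles <- function() tibble(i = integer(), j = integer(), k = integer(), k_angle = double(), theta0 = double())
empty_dihedrals <- function() {
  tibble(
    i = integer(), j = integer(), k = integer(), l = integer(),
    k_dih = double(), multiplicity = double(), phase = double()
  )
}

#' Validate a molecule topology
#'
#' Checks bonded indices are in range and distinct, masses/sigmas positive,
#' and that solute topologies declare exactly one end-to-end bead pair.
#'
#' @param top A `cg_topology`.
#' @return The topology, invisibly; errors on violation.
#' @export
validate_topology <- function(top) {
  n <- nrow(top$beads)
  chk <- function(idx, what) {
    idx <- as.matrix(idx)
    if (length(idx) && (any(idx < 1) || any(idx > n))) {
      abort(sprintf("invalid-topology: %s indices out of range", what))
    }
    if (length(idx) && any(apply(idx, 1, function(r) anyDuplicated(r) > 0))) {
      abort(sprintf("invalid-topology: %s indices must be distinct", what))
    }
  }
  chk(top$bonds[, c("i", "j")], "bond")
  chk(top$angles[, c("i", "j", "k")], "angle")
  chk(top$dihedrals[, c("i", "j", "k", "l")], "dihedral")
  if (any(top$beads$mass <= 0) || any(top$beads$lj_sigma <= 0)) {
    abort("invalid-topology: bead mass and sigma must be > 0")
  }
  if (grepl("^solute", top$molecule_class)) {
    if (is.null(top$end_indices) || length(top$end_indices) != 2L) {
      abort("invalid-topology: solute must declare exactly one end_indices pair")
    }
  }
  invisible(top)
}

chain_bonds <- function(idx, k_bond, r0) {
  if (length(idx) < 2) return(empty_bonds())
  tibble(i = idx[-length(idx)], j = idx[-1], k_bond = k_bond, r0 = r0)
}
chain_angles <- function(idx, k_angle, theta0 = pi) {
  if (length(idx) < 3) return(empty_angles())
  tibble(
    i = idx[seq_len(length(idx) - 2)], j = idx[seq_len(length(idx) - 2) + 1],
    k = idx[seq_len(length(idx) - 2) + 2], k_angle = k_angle, theta0 = theta0
  )
}
chain_dihedrals <- function(idx, k_dih, multiplicity = 1, phase = 0) {
  if (length(idx) < 4) return(empty_dihedrals())
  s <- seq_len(length(idx) - 3)
  tibble(
    i = idx[s], j = idx[s + 1], k = idx[s + 2], l = idx[s + 3],
    k_dih = k_dih, multiplicity = multiplicity, phase = phase
  )
}

#' Build a two-tail phospholipid template
#'
#' One polar head bead with two semi-flexible apolar tails of
#' `n_tail_beads` beads each; the paired tails align in parallel in an
#' assembled monolayer.
#'
#' @param n_tail_beads Beads per tail, >= 2.
#' @param k_bond,r0 Harmonic bond stiffness and rest length (reduced).
#' @param k_angle Tail bending stiffness (reduced energy/rad^2).
#' @return A `cg_topology` with `1 + 2 * n_tail_beads` beads.
#' @export
#' @examples
#' top <- build_phospholipid(4)
#' nrow(top$beads) # 9
build_phospholipid <- function(n_tail_beads = 4, k_bond = 100, r0 = 0.97,
                               k_angle = 5) {
  if (!is.numeric(n_tail_beads) || n_tail_beads < 2) {
    abort("invalid-topology: n_tail_beads must be >= 2")
  }
  n_tail_beads <- as.integer(n_tail_beads)
  types <- default_bead_types()
  beads <- bind_rows(
    types[types$type_id == "H", ],
    types[rep(which(types$type_id == "T"), 2 * n_tail_beads), ]
  )
  t1 <- 1 + seq_len(n_tail_beads)
  t2 <- 1 + n_tail_beads + seq_len(n_tail_beads)
  bonds <- bind_rows(
    chain_bonds(c(1L, t1), k_bond, r0),
    chain_bonds(c(1L, t2), k_bond, r0)
  )
  angles <- bind_rows(
    chain_angles(c(1L, t1), k_angle),
    chain_angles(c(1L, t2), k_angle)
  )
  new_topology("phospholipid", beads, bonds, angles, empty_dihedrals())
}

#' Build a three-tail triacylglycerol template
#'
#' One apolar glycerol-hub bead carrying three floppy apolar tails; the
#' tails are weakly bending so an assembled melt is polymer-melt-like with
#' intertwined chains. All beads are apolar.
#'
#' @param n_tail_beads Beads per tail, >= 2.
#' @param k_bond,r0 Harmonic bond parameters.
#' @param k_angle Tail bending stiffness (weak by default).
#' @return A `cg_topology` with `1 + 3 * n_tail_beads` beads.
#' @export
build_tag <- function(n_tail_beads = 4, k_bond = 100, r0 = 0.97, k_angle = 2) {
  if (!is.numeric(n_tail_beads) || n_tail_beads < 2) {
    abort("invalid-topology: n_tail_beads must be >= 2")
  }
  n_tail_beads <- as.integer(n_tail_beads)
  types <- default_bead_types()
  beads <- bind_rows(
    types[types$type_id == "C", ],
    types[rep(which(types$type_id == "G"), 3 * n_tail_beads), ]
  )
  tails <- lapply(0:2, function(t) 1L + t * n_tail_beads + seq_len(n_tail_beads))
  bonds <- bind_rows(lapply(tails, function(tl) chain_bonds(c(1L, tl), k_bond, r0)))
  angles <- bind_rows(lapply(tails, function(tl) chain_angles(c(1L, tl), k_angle)))
  new_topology("tag", beads, bonds, angles, empty_dihedrals())
}

#' Build a linear solute template (flexible or rigid chain)
#'
#' A linear chain of `n_beads` apolar beads spanning `contour_length`.
#' `"flexible"` uses weak bending and torsion terms so the end-to-end
#' distance fluctuates broadly (worm-like triterpene analog);
#' `"rigid"` uses stiff bending/torsion (>= 50x the flexible stiffness)
#' so the end-to-end distance stays at the contour length (rod-like
#' carotenoid analog). `"rigid_polar"` additionally makes the two terminal
#' beads polar (hydroxylated-carotenoid analog).
#'
#' @param flexibility `"flexible"`, `"rigid"` or `"rigid_polar"`.
#' @param n_beads Number of beads, >= 3.
#' @param contour_length Straight-chain end-to-end length (reduced).
#' @param k_bond Harmonic bond stiffness.
#' @return A `cg_topology` with `end_indices = c(1, n_beads)`.
#' @export
#' @examples
#' rod <- build_solute("rigid", n_beads = 8, contour_length = 6.79)
build_solute <- function(flexibility = c("flexible", "rigid", "rigid_polar"),
                         n_beads = 8, contour_length = 6.79, k_bond = NULL) {
  if (!is.character(flexibility) ||
    !flexibility[1] %in% c("flexible", "rigid", "rigid_polar")) {
    abort(sprintf("unknown flexibility tag: %s", flexibility[1]))
  }
  flexibility <- flexibility[1]
  if (!is.numeric(n_beads) || n_beads < 3) {
    abort("invalid-topology: n_beads must be >= 3")
  }
  stopifnot_scalar_number(contour_length, "contour_length", positive = TRUE)
  n_beads <- as.integer(n_beads)
  r0 <- contour_length / (n_beads - 1)
  types <- default_bead_types()
  stiff <- flexibility != "flexible"
  chain_type <- if (stiff) "R" else "S"
  beads <- types[rep(which(types$type_id == chain_type), n_beads), ]
  if (flexibility == "rigid_polar") {
    beads[c(1, n_beads), ] <- types[rep(which(types$type_id == "P"), 2), ]
  }
  # rod rigidity needs stiff bonds too: longitudinal bond noise otherwise
  # dominates the end-to-end fluctuation
  k_bond <- k_bond %||% if (stiff) 1000 else 100
  k_angle <- if (stiff) 200 else 1
  k_dih <- if (stiff) 2 else 0.04
  idx <- seq_len(n_beads)
  new_topology(
    paste0("solute_", if (stiff) "rigid" else "flexible"),
    beads,
    chain_bonds(idx, k_bond, r0),
    chain_angles(idx, k_angle),
    chain_dihedrals(idx, k_dih),
    end_indices = c(1L, n_beads)
  )
}

#' Build a single-bead solvent template
#'
#' Explicit polar solvent bead for the optional explicit-solvent mode.
#'
#' @return A `cg_topology` with a single polar bead.
#' @export
build_solvent_bead <- function() {
  types <- default_bead_types()
  new_topology(
    "solvent", types[types$type_id == "W", ],
    empty_bonds(), empty_angles(), empty_dihedrals()
  )
}

#' Straight-chain reference coordinates of a template
#'
#' Reference conformation used for initial placement: tails extended along
#' given directions; solute/chains extended along one axis.
#'
#' @param top A `cg_topology`.
#' @return Matrix `n_beads x 3` centered on the center of mass.
#' @keywords internal
template_coords <- function(top) {
  n <- nrow(top$beads)
  xyz <- matrix(0, n, 3)
  b <- top$bonds
  if (nrow(b)) {
    # lay out along the bond graph: follow chains from bead 1
    placed <- rep(FALSE, n)
    placed[1] <- TRUE
    # simple BFS with straight-line extension per chain; branch directions
    # spread in a cone so tails do not overlap
    dirs <- rbind(
      c(0, 0, -1), c(0.6, 0, -0.8), c(-0.6, 0, -0.8), c(0, 0.6, -0.8),
      c(0, -0.6, -0.8)
    )
    branch <- 0L
    bead_dir <- matrix(NA_real_, n, 3)
    queue <- 1L
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- c(b$j[b$i == cur], b$i[b$j == cur])
      for (x in nb) {
        if (placed[x]) next
        r0 <- b$r0[(b$i == cur & b$j == x) | (b$i == x & b$j == cur)][1]
        d <- bead_dir[cur, ]
        if (any(is.na(d))) {
          branch <- branch + 1L
          d <- dirs[(branch - 1L) %% nrow(dirs) + 1L, ]
          d <- d / sqrt(sum(d^2))
        }
        xyz[x, ] <- xyz[cur, ] + d * r0
        bead_dir[x, ] <- d
        placed[x] <- TRUE
        queue <- c(queue, x)
      }
    }
  }
  m <- top$beads$mass
  sweep(xyz, 2, colSums(xyz * m) / sum(m))
}

#' Bead and bonded-term counts of a topology
#'
#' @param top A `cg_topology`.
#' @return Tibble with one row: beads, bonds, angles, dihedrals, polar beads.
#' @export
topology_counts <- function(top) {
  tibble(
    molecule_class = top$molecule_class, n_beads = nrow(top$beads),
    n_bonds = nrow(top$bonds), n_angles = nrow(top$angles),
    n_dihedrals = nrow(top$dihedrals),
    n_polar = sum(top$beads$polarity != "apolar")
  )
}

#' Write a topology as human-readable TSV tables
#'
#' Dumps the bead table and the bonded-term tables into one TSV file with
#' section header lines prefixed `#`.
#'
#' @param top A `cg_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cg_topology\t%s", top$molecule_class), con)
  dump1 <- function(tag, df) {
    writeLines(sprintf("# %s\t%d", tag, nrow(df)), con)
    if (nrow(df)) {
      writeLines(paste(names(df), collapse = "\t"), con)
      utils::write.table(df, con, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  dump1("beads", top$beads)
  dump1("bonds", top$bonds)
  dump1("angles", top$angles)
  dump1("dihedrals", top$dihedrals)
  if (!is.null(top$end_indices)) {
    writeLines(sprintf("# end_indices\t%d\t%d", top$end_indices[1],
                       top$end_indices[2]), con)
  }
  invisible(path)
}
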