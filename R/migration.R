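#' Recalibrate slab references to the current head-group planes
#'
#' The TAG core relaxes toward its equilibrium density during
#' thermalization and the monolayers follow it, so the soft z-walls and
#' the implicit-solvent solvophobic field are re-anchored to the
#' instantaneous mean head-bead z of each leaflet.
#'
#' @param state An equilibrated slab `cg_state`.
#' @param field_offset Field onset above/below the head plane (sigma).
#' @param wall_offset Wall position above/below the head plane (sigma).
#' @return The state with updated `walls`, `field` and `head_planes`.
#' @export
calibrate_slab_references <- function(state, field_offset = 0.5,
                                      wall_offset = 4) {
  up <- head_bead_indices(state, "upper")
  lo <- head_bead_indices(state, "lower")
  if (!length(up) || !length(lo)) abort("state has no monolayers to calibrate")
  hz_up <- mean(state$positions[up, 3])
  hz_lo <- mean(state$positions[lo, 3])
  state$head_planes <- c(lower = hz_lo, upper = hz_up)
  state$walls$zlo <- hz_lo - wall_offset
  state$walls$zhi <- hz_up + wall_offset
  if (isTRUE(state$field$enabled)) {
    state$field$z_upper <- hz_up + field_offset
    state$field$z_lower <- hz_lo - field_offset
  }
  state
}

#' Insert a solute molecule into an assembled slab
#'
#' Appends a linear solute chain, lying in the xy-plane at `z_offset`
#' above the current upper head plane (the cytosol region), with a
#' seed-deterministic position and orientation.
#'
#' @param state A slab `cg_state`.
#' @param flexibility,n_beads,contour_length Passed to [build_solute()].
#' @param z_offset Height above the upper head plane (sigma).
#' @param seed Integer placement seed.
#' @param relax Relax overlaps after insertion (the chain can land on a
#'   protruding lipid); on by default.
#' @return The state with the solute appended (its molecule id is
#'   `length(state$molecules)`).
#' @export
insert_solute <- function(state, flexibility = "flexible", n_beads = 8,
                          contour_length = 6.79, z_offset = 2, seed = 1,
                          relax = TRUE) {
  top <- build_solute(flexibility, n_beads, contour_length)
  up <- head_bead_indices(state, "upper")
  hz_up <- if (length(up)) mean(state$positions[up, 3]) else state$box[3] / 2
  ref <- linear_chain_coords(top)
  xyz <- with_seed(seed, {
    ang <- runif(1, 0, 2 * pi)
    rot <- rbind(
      c(cos(ang), sin(ang), 0), c(-sin(ang), cos(ang), 0), c(0, 0, 1)
    )
    com <- c(runif(2, 0, state$box[1]), hz_up + z_offset)
    sweep(ref %*% rot, 2, -com)
  })
  n0 <- nrow(state$positions)
  n <- nrow(top$beads)
  types <- rownames(state$pair$eps)
  t0 <- match(top$beads$type_id, types) - 1L
  state$positions <- rbind(state$positions, xyz)
  state$velocities <- rbind(state$velocities, matrix(0, n, 3))
  state$beads <- bind_rows(state$beads, tibble(
    molecule_id = length(state$molecules) + 1L,
    molecule_class = top$molecule_class,
    type_id = top$beads$type_id, type0 = t0, mass = top$beads$mass,
    polarity = top$beads$polarity
  ))
  state$bonds <- rbind(state$bonds, cbind(
    top$bonds$i - 1 + n0, top$bonds$j - 1 + n0, top$bonds$k_bond, top$bonds$r0
  ))
  state$angles <- rbind(state$angles, cbind(
    top$angles$i - 1 + n0, top$angles$j - 1 + n0, top$angles$k - 1 + n0,
    top$angles$k_angle, top$angles$theta0
  ))
  if (nrow(top$dihedrals)) {
    state$dihedrals <- rbind(state$dihedrals, cbind(
      top$dihedrals$i - 1 + n0, top$dihedrals$j - 1 + n0,
      top$dihedrals$k - 1 + n0, top$dihedrals$l - 1 + n0,
      top$dihedrals$k_dih, top$dihedrals$multiplicity, top$dihedrals$phase
    ))
  }
  excl <- topology_exclusions(top) + n0
  storage.mode(excl) <- "integer"
  state$exclusions <- rbind(state$exclusions, excl)
  state$molecules[[length(state$molecules) + 1L]] <- list(
    class = top$molecule_class, first = n0 + 1L, last = n0 + n,
    end_indices = top$end_indices + n0
  )
  if (isTRUE(state$field$enabled)) {
    state$field$apolar <- as.integer(state$beads$polarity == "apolar")
  }
  if (relax) state <- relax_overlaps(state, min_dist = 0.8)
  state
}

#' Phospholipid-TAG boundary depth of a slab
#'
#' The Interface-II position of the upper leaflet: the depth (relative to
#' the mean head-bead z) at which the TAG bead density first exceeds the
#' phospholipid-tail bead density on the way down from the head plane.
#'
#' @param state A slab `cg_state`.
#' @param bin z-bin width (sigma).
#' @return Boundary depth (negative, reduced length).
#' @export
interface_boundary <- function(state, bin = 0.25) {
  hb <- head_bead_indices(state, "upper")
  if (!length(hb)) abort("state has no phospholipids")
  href <- mean(state$positions[hb, 3])
  zc <- mean(state$positions[, 3])
  tail_z <- state$positions[
    state$beads$molecule_class == "phospholipid" &
      state$beads$type_id == "T" & state$positions[, 3] > zc, 3
  ] - href
  tag_z <- state$positions[state$beads$molecule_class == "tag", 3] - href
  keep <- function(z) z[is.finite(z) & z > -15 & z < 1]
  tail_z <- keep(tail_z)
  tag_z <- keep(tag_z)
  if (!length(tail_z) || !length(tag_z)) {
    abort("interface_boundary: no tail/TAG beads in the upper-leaflet window")
  }
  lo <- floor(min(c(tail_z, tag_z)) / bin) * bin
  breaks <- seq(lo, 1, by = bin)
  ht <- hist(tail_z[tail_z < 1], breaks = breaks, plot = FALSE)$counts
  hg <- hist(tag_z[tag_z < 1], breaks = breaks, plot = FALSE)$counts
  mids <- breaks[-1] - bin / 2
  # walk downward from the head plane to the first bin where TAG dominates
  ord <- order(mids, decreasing = TRUE)
  for (i in ord) {
    if (hg[i] > ht[i] && hg[i] > 0) {
      next_down <- which(mids < mids[i])
      # require TAG dominance to persist below this bin
      if (all(hg[next_down] >= ht[next_down])) return(mids[i])
    }
  }
  min(mids[hg > 0]) # degenerate: no crossing found
}

#' Unrestrained solute migration run (cytosol start)
#'
#' The desk-scale analog of an unrestrained migration simulation:
#' assemble the slab, thermalize it, re-anchor the implicit-solvent
#' references to the relaxed monolayers, insert the solute in the
#' cytosol region above the upper leaflet, and integrate while streaming
#' the migration CVs.
#'
#' @param flexibility Solute class (`"flexible"`, `"rigid"`,
#'   `"rigid_polar"`).
#' @param seed Integer master seed (assembly, thermalization, production
#'   streams are derived from it).
#' @param config Slab configuration (no solutes; default [mini_config()]).
#' @param n_steps Production steps.
#' @param n_equil Thermalization steps before solute insertion.
#' @param gamma Langevin collision rate for all stages.
#' @param n_beads,contour_length Solute geometry.
#' @param stride_cv CV recording stride.
#' @return List: `cv` (CVSeries tibble), final `state`, `boundary`
#'   (phospholipid-TAG boundary depth), `final_depth` (median migration
#'   depth over the last tenth of the run), `solute_id`.
#' @export
migration_run <- function(flexibility, seed, config = mini_config(),
                          n_steps = 6e4, n_equil = 4000, gamma = 0.5,
                          n_beads = 8, contour_length = 6.79,
                          stride_cv = 200) {
  config$seed <- derive_seed(seed, "assemble")
  state <- assemble_slab(config)
  state <- thermalize(state, n_equil, gamma = gamma,
                      seed = derive_seed(seed, "equil"))
  state <- calibrate_slab_references(state)
  state <- insert_solute(state, flexibility, n_beads, contour_length,
                         z_offset = 2, seed = derive_seed(seed, "insert"))
  sid <- length(state$molecules)
  tr <- run_dynamics(
    state,
    integrator_params(n_steps = n_steps, gamma = gamma,
                      seed = derive_seed(seed, "prod")),
    reporter_config(stride_cv = stride_cv),
    cv = list(enabled = TRUE, solute_id = sid)
  )
  nfin <- max(5L, nrow(tr$cv) %/% 10L)
  list(
    cv = tr$cv, state = tr$state,
    boundary = interface_boundary(tr$state),
    final_depth = median(tail(tr$cv$z, nfin)),
    solute_id = sid
  )
}
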