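#' Langevin integrator parameters
#'
#' BAOAB-splitting Langevin dynamics in reduced units; `gamma = 0` gives
#' microcanonical (velocity-Verlet) integration.
#'
#' @param dt Time step (reduced), default 0.005.
#' @param temperature Reduced temperature (T = 1 maps to 300 K).
#' @param gamma Langevin collision rate (1/reduced time), >= 0.
#' @param n_steps Number of steps.
#' @param seed Integer RNG seed of the thermostat stream.
#' @param com_interval Steps between center-of-mass momentum removal in
#'   thermostatted runs (0 disables).
#' @return An `integrator_params` list.
#' @export
integrator_params <- function(dt = 0.005, temperature = 1, gamma = 1,
                              n_steps = 1000, seed = 1, com_interval = 1000) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(temperature, "temperature", nonneg = TRUE)
  stopifnot_scalar_number(gamma, "gamma", nonneg = TRUE)
  structure(
    list(
      dt = dt, temperature = temperature, gamma = gamma,
      n_steps = as.numeric(n_steps), seed = as.numeric(seed),
      com_interval = as.integer(com_interval)
    ),
    class = "integrator_params"
  )
}

#' Reporter strides for a dynamics run
#'
#' @param stride_frames Steps between stored coordinate frames (0 = none).
#' @param stride_energy Steps between energy-log rows (0 = none).
#' @param stride_cv Steps between collective-variable rows (0 = none).
#' @return A list of strides.
#' @export
reporter_config <- function(stride_frames = 0, stride_energy = 0,
                            stride_cv = 0) {
  list(
    stride_frames = as.integer(stride_frames),
    stride_energy = as.integer(stride_energy),
    stride_cv = as.integer(stride_cv)
  )
}

# engine keeps positions unwrapped between neighbor-list rebuilds; restore
# the primary-box convention (x/y always, z when periodic) on the way out
wrap_positions <- function(pos, box, pbc_z) {
  pos[, 1] <- pos[, 1] %% box[1]
  pos[, 2] <- pos[, 2] %% box[2]
  if (pbc_z) pos[, 3] <- pos[, 3] %% box[3]
  pos
}

cv_spec_for <- function(state, solute_id = NULL, leaflet = "upper") {
  if (is.null(solute_id)) {
    ids <- solute_ids(state)
    if (!length(ids)) return(list(enabled = FALSE))
    solute_id <- ids[1]
  }
  m <- solute_info(state, solute_id)
  heads <- head_bead_indices(state, leaflet)
  list(
    enabled = TRUE,
    solute = seq.int(m$first, m$last) - 1L,
    heads = as.integer(heads - 1L),
    e1 = if (!is.null(m$end_indices)) as.integer(m$end_indices[1] - 1L) else -1L,
    e2 = if (!is.null(m$end_indices)) as.integer(m$end_indices[2] - 1L) else -1L
  )
}

pull_spec_for <- function(state, solute_id, force) {
  m <- solute_info(state, solute_id)
  idx <- seq.int(m$first, m$last)
  w <- state$beads$mass[idx] / sum(state$beads$mass[idx])
  list(enabled = TRUE, idx = as.integer(idx - 1L), w = w, force = force)
}

#' Evaluate forces and potential energy of a state
#'
#' Harmonic bonds/angles, cosine dihedrals, truncated-shifted LJ/WCA pairs
#' (cell list), soft z-walls. Forces are exact negative gradients of the
#' declared potential.
#'
#' @param state A `cg_state`.
#' @param cutoff Optional override check: errors if larger than half the
#'   smallest periodic box edge.
#' @return List with `forces` (N x 3), `energy`, and per-term `terms`.
#' @export
compute_forces <- function(state, cutoff = NULL) {
  maxcut <- max(state$pair$cutoff)
  cutoff <- cutoff %||% maxcut
  if (cutoff > min(state$box[1:2]) / 2 ||
    (state$pbc_z && cutoff > state$box[3] / 2)) {
    abort("cutoff too large for box (must be <= half the box edge)")
  }
  cpp_compute_forces(
    state$positions, state$velocities, state$beads$mass, state$beads$type0,
    state$box, state$pbc_z, state$pair$eps, state$pair$sigma,
    state$pair$cutoff, state$bonds, state$angles, state$dihedrals,
    state$exclusions, state$walls, state$field %||% list(enabled = FALSE)
  )
}

# make every molecule contiguous (no periodic splits) so the engine can use
# raw coordinate differences for intramolecular quantities
unwrap_molecules <- function(state) {
  pos <- state$positions
  box <- state$box
  b <- state$bonds
  if (!nrow(b)) return(state)
  adj <- vector("list", nrow(pos))
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1] + 1L
    j <- b[r, 2] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (m in state$molecules) {
    if (m$last - m$first < 1L) next
    seen <- rep(FALSE, m$last - m$first + 1L)
    seen[1] <- TRUE
    queue <- m$first
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (x in adj[[cur]]) {
        li <- x - m$first + 1L
        if (li < 1L || li > length(seen) || seen[li]) next
        d <- pos[x, ] - pos[cur, ]
        d[1] <- d[1] - box[1] * round(d[1] / box[1])
        d[2] <- d[2] - box[2] * round(d[2] / box[2])
        if (state$pbc_z) d[3] <- d[3] - box[3] * round(d[3] / box[3])
        pos[x, ] <- pos[cur, ] + d
        seen[li] <- TRUE
        queue <- c(queue, x)
      }
    }
  }
  state$positions <- pos
  state
}

run_engine <- function(state, params, reporters, pull = NULL, metad = NULL,
                       cv = NULL, tether = NULL) {
  state <- unwrap_molecules(state)
  cv <- cv %||% list(enabled = FALSE)
  if (isTRUE(cv$enabled) && is.null(cv[["solute"]])) {
    cv <- cv_spec_for(state, cv[["solute_id"]], cv[["leaflet"]] %||% "upper")
  }
  tether <- tether %||% list(enabled = FALSE)
  if (isTRUE(tether$enabled)) tether$idx <- as.integer(tether$idx - 1L)
  metad_l <- if (is.null(metad)) list(enabled = FALSE) else metad
  out <- cpp_run(
    state$positions, state$velocities, state$beads$mass, state$beads$type0,
    state$box, state$pbc_z, state$pair$eps, state$pair$sigma,
    state$pair$cutoff, state$bonds, state$angles, state$dihedrals,
    state$exclusions, state$walls, state$field %||% list(enabled = FALSE),
    tether,
    pull %||% list(enabled = FALSE),
    unclass(params), cv, metad_l, reporters, state$time
  )
  out
}

#' Advance a state by one Langevin (BAOAB) step
#'
#' Deterministic given the seed; repeated calls with the same seed and
#' state reproduce the identical step.
#'
#' @param state A `cg_state`.
#' @param params An [integrator_params()]; `n_steps` is ignored (one step).
#' @return The advanced `cg_state`.
#' @export
langevin_step <- function(state, params) {
  p <- params
  p$n_steps <- 1
  run_dynamics(state, p, reporters = reporter_config())$state
}

#' Run Langevin dynamics with streamed reporters
#'
#' Propagates the state for `params$n_steps` BAOAB steps, optionally under
#' a constant COM pulling force, a harmonic tether, or a well-tempered
#' metadynamics bias over (z, mu), recording frames, energies and
#' collective variables at the configured strides.
#'
#' @param state A `cg_state`.
#' @param params [integrator_params()].
#' @param reporters [reporter_config()].
#' @param pull Optional list `(solute_id, force)` with a length-3 force
#'   vector applied to the solute COM (mass-weighted over beads).
#' @param metad Optional [metad_params()] bias settings.
#' @param cv Optional list `(enabled = TRUE, solute_id =, leaflet =)`
#'   selecting the tracked solute; defaults to the first solute when
#'   CV or metadynamics reporting is requested.
#' @param tether Optional list `(enabled, idx, k, ref)` harmonic tethers.
#' @return A `cg_trajectory`: final `state`, `frames`, `energy`, `cv`
#'   (tibbles), deposited `hills`, and the bias grid when metadynamics ran.
#' @export
run_dynamics <- function(state, params, reporters = reporter_config(),
                         pull = NULL, metad = NULL, cv = NULL, tether = NULL) {
  if (!is.null(pull) && !is.null(pull$solute_id)) {
    pull <- pull_spec_for(state, pull$solute_id, pull$force)
  }
  need_cv <- (!is.null(metad)) || reporters$stride_cv > 0
  if (is.null(cv) && need_cv) cv <- list(enabled = TRUE)
  metad_l <- NULL
  if (!is.null(metad)) {
    metad_l <- metad_engine_list(metad, params$temperature)
  }
  out <- run_engine(state, params, reporters, pull, metad_l, cv, tether)
  new_state <- state
  new_state$positions <- wrap_positions(out$positions, state$box, state$pbc_z)
  new_state$velocities <- out$velocities
  new_state$time <- out$time
  hills <- as_tibble(out$hills)
  traj <- structure(
    list(
      state = new_state,
      frames = out$frames, frame_times = out$frame_times,
      energy = as_tibble(out$energy),
      cv = finish_cv_series(as_tibble(out$cv)),
      hills = hills,
      n_cv_wall_events = out$n_cv_wall_events,
      bias_grid = if (!is.null(metad)) {
        list(V = out$V, G1 = out$G1, G2 = out$G2, params = metad)
      }
    ),
    class = "cg_trajectory"
  )
  if (!is.null(metad) && out$n_cv_wall_events > 0) {
    warning(sprintf(
      "metadynamics CV left the grid %d times; bias clamped at the edges",
      as.integer(out$n_cv_wall_events)
    ), call. = FALSE)
  }
  traj
}

#' Thermalize a state
#'
#' Short thermostatted run that discards reporters and marks the state
#' equilibrated.
#'
#' @param state A `cg_state`.
#' @param n_steps Number of steps.
#' @param temperature,gamma,dt,seed Passed to [integrator_params()].
#' @return The thermalized `cg_state`.
#' @export
thermalize <- function(state, n_steps = 5000, temperature = 1, gamma = 1,
                       dt = 0.005, seed = 1) {
  p <- integrator_params(
    dt = dt, temperature = temperature, gamma = gamma,
    n_steps = n_steps, seed = seed
  )
  st <- run_dynamics(state, p)$state
  st$equilibrated <- TRUE
  st
}

#' Instantaneous kinetic temperature of a state
#'
#' @param state A `cg_state`.
#' @return 2 E_kin / (3 N) in reduced units.
#' @export
kinetic_temperature <- function(state) {
  v <- state$velocities
  sum(state$beads$mass * rowSums(v^2)) / (3 * nrow(v))
}
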