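#' Constant-force stepwise pulling protocol
#'
#' The pulling force on the solute center of mass starts at `force_start`
#' and is increased by `force_step` every `interval` steps until the
#' solute shows drift motion at constant velocity, detected by a linear
#' fit of COM displacement along the pull direction.
#'
#' @param force_start First force level (reduced force).
#' @param force_step Force increment per level, > 0.
#' @param interval Steps per force level, > 0.
#' @param direction Pull direction (normalized internally).
#' @param r2_min Minimum R^2 of the displacement fit for "constant
#'   velocity".
#' @param min_disp Minimum post-transient displacement (sigma) within the
#'   interval.
#' @param max_levels Maximum number of force levels.
#' @param discard_fraction Leading fraction of each interval discarded as
#'   transient before the fit.
#' @return A `pull_protocol` list.
#' @export
pull_protocol <- function(force_start = 0.5, force_step = 0.5,
                          interval = 20000, direction = c(1, 0, 0),
                          r2_min = 0.98, min_disp = 5, max_levels = 8,
                          discard_fraction = 0.25) {
  stopifnot_scalar_number(force_step, "force_step", positive = TRUE)
  if (interval <= 0) abort("interval must be > 0")
  nd <- sqrt(sum(direction^2))
  if (nd <= 0) abort("direction must be a nonzero vector")
  structure(
    list(
      force_start = force_start, force_step = force_step,
      interval = as.integer(interval), direction = direction / nd,
      r2_min = r2_min, min_disp = min_disp,
      max_levels = as.integer(max_levels),
      discard_fraction = discard_fraction
    ),
    class = "pull_protocol"
  )
}

drift_fit <- function(segment, direction, discard_fraction) {
  disp <- cbind(
    segment$com_x - segment$com_x[1],
    segment$com_y - segment$com_y[1],
    segment$com_z - segment$com_z[1]
  ) %*% direction
  d <- tibble(time = segment$time - segment$time[1], disp = as.numeric(disp))
  keep <- d$time >= discard_fraction * max(d$time)
  fit <- lm(disp ~ time, data = d[keep, ])
  ss <- summary(fit)
  list(
    v = unname(coef(fit)[2]), r2 = ss$r.squared,
    residual_sd = ss$sigma,
    disp_total = d$disp[nrow(d)] - d$disp[which(keep)[1]],
    data = d
  )
}

#' Stepwise constant-force pull of a solute
#'
#' At each force level the constant force (mass-weighted over the solute
#' beads) is applied to the solute COM for `protocol$interval` steps; the
#' run stops at the first level whose post-transient displacement fit
#' meets the drift criterion, or errors after `max_levels`.
#'
#' @param state A `cg_state` containing the solute (e.g. a thermalized
#'   neat TAG melt from [build_neat_tag()]).
#' @param solute_id Molecule id of the pulled solute.
#' @param protocol A [pull_protocol()].
#' @param integrator [integrator_params()]; `n_steps` is overridden per
#'   level and the seed is advanced per level.
#' @param stride_cv COM recording stride (steps).
#' @return A `pull_result`: tibble `levels` (force, drift stats,
#'   detected), list `segments` of COM traces, `detected_level`, final
#'   `state`.
#' @export
stepwise_pull <- function(state, solute_id, protocol, integrator,
                          stride_cv = 25) {
  levels <- list()
  segments <- list()
  detected <- NA_integer_
  for (lev in seq_len(protocol$max_levels)) {
    force <- protocol$force_start + (lev - 1) * protocol$force_step
    p <- integrator
    p$n_steps <- protocol$interval
    p$seed <- derive_seed(integrator$seed, paste0("pull", lev))
    traj <- run_dynamics(
      state, p, reporter_config(stride_cv = stride_cv),
      pull = list(solute_id = solute_id, force = force * protocol$direction),
      cv = list(enabled = TRUE, solute_id = solute_id)
    )
    state <- traj$state
    seg <- traj$cv
    fit <- drift_fit(seg, protocol$direction, protocol$discard_fraction)
    drift <- force > 0 && fit$v > 0 && fit$r2 >= protocol$r2_min &&
      fit$disp_total >= protocol$min_disp
    levels[[lev]] <- tibble(
      level = lev, force = force, v = fit$v, r2 = fit$r2,
      residual_sd = fit$residual_sd, displacement = fit$disp_total,
      drift_detected = drift
    )
    segments[[lev]] <- seg
    if (drift) {
      detected <- lev
      break
    }
  }
  if (is.na(detected)) {
    abort(sprintf(
      "no-drift: criterion not met by level %d (last force %.3g, R^2 %.3f, displacement %.2f)",
      protocol$max_levels, levels[[length(levels)]]$force,
      levels[[length(levels)]]$r2, levels[[length(levels)]]$displacement
    ))
  }
  structure(
    list(
      levels = bind_rows(levels), segments = segments,
      detected_level = detected, protocol = protocol, state = state,
      solute_id = solute_id
    ),
    class = "pull_result"
  )
}

#' Langevin friction coefficient from a drift segment
#'
#' `zeta = F / (m v)` with `v` the slope of the post-transient COM
#' displacement along the pull direction and `m` the solute mass. The
#' drag coefficient is reported positive: with `v` measured along the
#' force, the minus sign of the force-balance form is a sign convention,
#' not a property of the estimate.
#'
#' @param segment COM trace tibble (columns time, com_x/y/z) from
#'   [stepwise_pull()] or a CV series.
#' @param force Applied force magnitude.
#' @param mass Solute mass (reduced).
#' @param direction Pull direction.
#' @param discard_fraction Leading transient fraction discarded.
#' @param r2_min Minimum fit R^2 for a reliable estimate.
#' @return A `friction_result`: force, drift velocity, mass, `zeta`
#'   (1/time), fit diagnostics.
#' @export
estimate_friction <- function(segment, force, mass, direction = c(1, 0, 0),
                              discard_fraction = 0.25, r2_min = 0.9) {
  direction <- direction / sqrt(sum(direction^2))
  fit <- drift_fit(segment, direction, discard_fraction)
  if (!is.finite(fit$v) || fit$v <= 0 || fit$r2 < r2_min) {
    abort(sprintf(
      "unreliable-fit: drift velocity %.3g, R^2 %.3f below criterion %.2f",
      fit$v, fit$r2, r2_min
    ))
  }
  structure(
    list(
      force = force, v = fit$v, mass = mass, zeta = force / (mass * fit$v),
      r2 = fit$r2, residual_sd = fit$residual_sd
    ),
    class = "friction_result"
  )
}

#' Friction of a solute in a TAG melt, end to end
#'
#' Runs the stepwise pull and estimates the friction coefficient at the
#' detected drift level.
#'
#' @param state Thermalized melt `cg_state` containing the solute.
#' @param solute_id Molecule id of the solute.
#' @param protocol [pull_protocol()].
#' @param integrator [integrator_params()].
#' @return A `friction_result` with the `pull_result` attached as
#'   attribute `"pull"`.
#' @export
measure_friction <- function(state, solute_id, protocol = pull_protocol(),
                             integrator = integrator_params()) {
  pull <- stepwise_pull(state, solute_id, protocol, integrator)
  m <- solute_info(state, solute_id)
  mass <- sum(state$beads$mass[seq.int(m$first, m$last)])
  lev <- pull$levels[pull$detected_level, ]
  res <- estimate_friction(
    pull$segments[[pull$detected_level]], lev$force, mass,
    protocol$direction, protocol$discard_fraction,
    r2_min = min(protocol$r2_min, 0.95)
  )
  attr(res, "pull") <- pull
  res
}

#' A single free bead in an implicit Langevin bath
#'
#' One-bead tracer state for friction-estimator validation: under force F
#' and bath friction gamma the analytic drift is `v = F / (m gamma)`.
#'
#' @param box Cubic box edge.
#' @param mass Bead mass.
#' @return A `cg_state` with one tracer bead.
#' @export
free_bead_state <- function(box = 20, mass = 1) {
  types <- default_bead_types()
  top <- new_topology(
    "tracer",
    within_mass(types[types$type_id == "S", ], mass),
    empty_bonds(), empty_angles(), empty_dihedrals()
  )
  new_state(
    list(list(topology = top, xyz = matrix(box / 2, 1, 3))),
    box = rep(box, 3), pbc_z = TRUE
  )
}

within_mass <- function(beads, mass) {
  beads$mass <- mass
  beads
}
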