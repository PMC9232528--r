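#' Migration depth of a solute
#'
#' Mass-weighted solute center-of-mass z relative to the mean z of the
#' chosen leaflet's head beads. The head-group plane defines z = 0;
#' migration into the droplet core is negative.
#'
#' @param state A `cg_state`.
#' @param solute_id Molecule id of the solute.
#' @param leaflet `"upper"` or `"lower"`: which head-group plane is the
#'   reference (the leaflet the solute approaches).
#' @return Signed depth (reduced length).
#' @export
#' @examples
#' # a solute 2 below the head plane has depth -2
migration_depth <- function(state, solute_id, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  m <- solute_info(state, solute_id)
  heads <- head_bead_indices(state, leaflet)
  if (!length(heads)) abort(sprintf("empty leaflet: no head beads (%s)", leaflet))
  idx <- seq.int(m$first, m$last)
  mass <- state$beads$mass[idx]
  com_z <- sum(mass * state$positions[idx, 3]) / sum(mass)
  href <- mean(state$positions[heads, 3])
  depth <- com_z - href
  if (leaflet == "lower") depth <- -depth # migration into the core is negative
  depth
}

#' End-to-end distance of a solute
#'
#' Euclidean distance between the two declared end beads (minimum image in
#' x/y; the slab is not z-periodic) and its signed z-component.
#'
#' @param state A `cg_state`.
#' @param solute_id Molecule id of the solute.
#' @return Named numeric `c(r_ee =, z_ee =)`.
#' @export
end_to_end <- function(state, solute_id) {
  m <- solute_info(state, solute_id)
  if (is.null(m$end_indices)) abort("solute does not declare end_indices")
  # chains can span more than half the box, so the end-to-end vector is
  # accumulated bond-wise (minimum image per consecutive bead pair), which
  # unwraps the contiguous molecule exactly
  lo <- min(m$end_indices)
  hi <- max(m$end_indices)
  seg <- state$positions[lo:hi, , drop = FALSE]
  steps <- diff(seg)
  steps[, 1] <- steps[, 1] - state$box[1] * round(steps[, 1] / state$box[1])
  steps[, 2] <- steps[, 2] - state$box[2] * round(steps[, 2] / state$box[2])
  if (state$pbc_z) {
    steps[, 3] <- steps[, 3] - state$box[3] * round(steps[, 3] / state$box[3])
  }
  d <- colSums(steps)
  if (m$end_indices[1] > m$end_indices[2]) d <- -d
  c(r_ee = sqrt(sum(d^2)), z_ee = unname(d[3]))
}

#' Conformation order parameter
#'
#' `mu = |z_ee| / R_ee`, the unsigned fraction of the end-to-end vector
#' aligned with the membrane normal; 1 for a rod along z, 0 for a rod in
#' the monolayer plane. Clipped to `[0, 1]` against rounding.
#'
#' @param r_ee End-to-end distance, > 0.
#' @param z_ee Signed z-component of the end-to-end vector.
#' @return mu in `[0, 1]`.
#' @export
#' @examples
#' conformation_order(2.4, 1.2) # 0.5
conformation_order <- function(r_ee, z_ee) {
  if (any(!is.finite(r_ee)) || any(r_ee <= 0)) {
    abort("undefined-CV: conformation order requires R_ee > 0")
  }
  pmin(1, pmax(0, abs(z_ee) / r_ee))
}

#' Orientation angle from the conformation order
#'
#' `theta = arccos(mu)` in degrees; 0 for a rod along the membrane normal,
#' 90 for a rod lying in the monolayer plane.
#'
#' @param mu Conformation order in `[0, 1]` (tolerance 1e-9).
#' @return Angle in degrees, `[0, 90]`.
#' @export
orientation_angle <- function(mu) {
  if (any(!is.finite(mu)) || any(mu < -1e-9) || any(mu > 1 + 1e-9)) {
    abort("orientation_angle: mu must lie in [0, 1]")
  }
  acos(pmin(1, pmax(0, mu))) * 180 / pi
}

# complete the engine's streamed CV matrix into the CVSeries tibble
finish_cv_series <- function(cv) {
  if (!nrow(cv)) {
    return(tibble(
      time = double(), z = double(), r_ee = double(), z_ee = double(),
      mu = double(), theta = double(),
      com_x = double(), com_y = double(), com_z = double()
    ))
  }
  cv$mu <- pmin(1, pmax(0, cv$mu))
  cv$theta <- acos(pmin(1, pmax(0, cv$mu))) * 180 / pi
  cv[, c("time", "z", "r_ee", "z_ee", "mu", "theta",
         "com_x", "com_y", "com_z")]
}

#' Recompute a CV series from stored trajectory frames
#'
#' Frame-for-frame recomputation of (z, R_ee, z_ee, mu, theta) from the
#' coordinates written by a run; matches the streamed series.
#'
#' @param traj A `cg_trajectory` with stored frames.
#' @param solute_id Molecule id of the solute (default: first solute).
#' @param leaflet Head-plane reference leaflet.
#' @return CVSeries tibble.
#' @export
cv_from_frames <- function(traj, solute_id = NULL, leaflet = "upper") {
  state <- traj$state
  solute_id <- solute_id %||% solute_ids(state)[1]
  has_heads <- length(head_bead_indices(state, leaflet)) > 0
  rows <- purrr::map2(traj$frames, traj$frame_times, function(fr, tm) {
    st <- state
    st$positions <- fr
    ee <- end_to_end(st, solute_id)
    mu <- conformation_order(ee["r_ee"], ee["z_ee"])
    tibble(
      time = tm,
      z = if (has_heads) migration_depth(st, solute_id, leaflet) else NA_real_,
      r_ee = unname(ee["r_ee"]), z_ee = unname(ee["z_ee"]),
      mu = unname(mu), theta = orientation_angle(unname(mu))
    )
  })
  bind_rows(rows)
}

#' Write / read a CV series as TSV
#'
#' @param cv CVSeries tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_cv_series <- function(cv, path) {
  readr::write_tsv(cv, path)
  invisible(path)
}

#' @rdname write_cv_series
#' @export
read_cv_series <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
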