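#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy surface into a long tibble
#'
#' @param x A `fes`.
#' @param ... Unused.
#' @return Tibble with one row per grid bin: CV columns and `free_energy`.
#' @export
tidy.fes <- function(x, ...) {
  if (is.matrix(x$F)) {
    g <- expand.grid(i = seq_along(x$axes[[1]]), j = seq_along(x$axes[[2]]))
    out <- tibble(
      !!names(x$axes)[1] := x$axes[[1]][g$i],
      !!names(x$axes)[2] := x$axes[[2]][g$j],
      free_energy = x$F[cbind(g$i, g$j)]
    )
  } else {
    out <- tibble(
      !!names(x$axes)[1] := x$axes[[1]],
      free_energy = as.numeric(x$F)
    )
  }
  out
}

#' @rdname tidy.fes
#' @export
glance.fes <- function(x, ...) {
  tibble(
    gamma_wt = x$metadata$gamma_wt, n_hills = x$metadata$n_hills,
    n_walkers = x$metadata$n_walkers,
    f_max = max(x$F[is.finite(x$F)]),
    n_bins = length(x$F)
  )
}

#' Tidy a friction estimate
#'
#' @param x A `friction_result`.
#' @param ... Unused.
#' @return One-row tibble: force, drift velocity, mass, zeta, diagnostics.
#' @export
tidy.friction_result <- function(x, ...) {
  tibble(
    force = x$force, v = x$v, mass = x$mass, zeta = x$zeta,
    r_squared = x$r2, residual_sd = x$residual_sd
  )
}

#' Tidy a stepwise pull
#'
#' @param x A `pull_result`.
#' @param ... Unused.
#' @return The per-level tibble with drift diagnostics.
#' @export
tidy.pull_result <- function(x, ...) x$levels

#' @rdname tidy.pull_result
#' @export
glance.pull_result <- function(x, ...) {
  lev <- x$levels[x$detected_level, ]
  tibble(
    detected_level = x$detected_level, force = lev$force, v = lev$v,
    r_squared = lev$r2
  )
}

#' Tidy a storage-scaling report
#'
#' @param x A `scaling_report`.
#' @param ... Unused.
#' @return The per-strain geometry/titer table.
#' @export
tidy.scaling_report <- function(x, ...) x$table

#' @rdname tidy.scaling_report
#' @export
glance.scaling_report <- function(x, ...) {
  tibble(
    lipid = x$lipid, classification = x$classification,
    cor_volume = x$cor_volume, cor_surface = x$cor_surface
  )
}

#' Tidy a trajectory's collective-variable series
#'
#' @param x A `cg_trajectory`.
#' @param ... Unused.
#' @return The CVSeries tibble.
#' @export
tidy.cg_trajectory <- function(x, ...) x$cv

#' @rdname tidy.cg_trajectory
#' @export
glance.cg_trajectory <- function(x, ...) {
  tibble(
    n_frames = length(x$frames), time = x$state$time,
    n_beads = nrow(x$state$positions),
    mean_t_inst = if (nrow(x$energy)) mean(x$energy$t_inst) else NA_real_,
    n_hills = nrow(x$hills)
  )
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf(
    "<fes> %s grid %s, F in [0, %.3g] (reduced), %d hills, %d walker(s)\n",
    paste(names(x$axes), collapse = " x "),
    paste(vapply(x$axes, length, integer(1)), collapse = " x "),
    max(x$F[is.finite(x$F)]), x$metadata$n_hills, x$metadata$n_walkers
  ))
  invisible(x)
}

#' @export
print.friction_result <- function(x, ...) {
  cat(sprintf(
    "<friction_result> zeta = %.4g (F = %.3g, v = %.4g, m = %.3g, R^2 = %.3f)\n",
    x$zeta, x$force, x$v, x$mass, x$r2
  ))
  invisible(x)
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf(
    "<scaling_report> %s: %s (rho_V = %.3f, rho_S = %.3f)\n",
    x$lipid, x$classification, x$cor_volume, x$cor_surface
  ))
  if (!is.null(x$reason)) cat(" ", x$reason, "\n")
  invisible(x)
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf(
    "<cg_state> %d beads, %d molecules, box %.2f x %.2f x %.2f (%s), t = %.3g\n",
    nrow(x$positions), length(x$molecules), x$box[1], x$box[2], x$box[3],
    if (x$pbc_z) "periodic" else "slab", x$time
  ))
  invisible(x)
}

#' @export
print.cg_topology <- function(x, ...) {
  print(topology_counts(x))
  invisible(x)
}
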