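#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_col geom_errorbar scale_fill_viridis_c labs facet_wrap
#'   geom_hline theme_minimal
#' @export
ggplot2::autoplot

#' Plot a free-energy surface
#'
#' 2D surfaces as a filled raster over the two CVs; 1D profiles as a
#' line.
#'
#' @param object A `fes`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fes <- function(object, ...) {
  df <- tidy(object)
  if (is.matrix(object$F)) {
    nm <- names(object$axes)
    ggplot(df, aes(.data[[nm[1]]], .data[[nm[2]]], fill = .data$free_energy)) +
      geom_raster() +
      scale_fill_viridis_c(name = "F (reduced)") +
      labs(x = nm[1], y = nm[2]) +
      theme_minimal()
  } else {
    nm <- names(object$axes)[1]
    ggplot(df, aes(.data[[nm]], .data$free_energy)) +
      geom_line() +
      labs(x = nm, y = "F (reduced)") +
      theme_minimal()
  }
}

#' Plot the collective-variable traces of a run
#'
#' Migration depth, end-to-end distance and conformation order against
#' time, faceted.
#'
#' @param object A `cg_trajectory` with a recorded CV series.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_trajectory <- function(object, ...) {
  cv <- object$cv
  long <- tidyr::pivot_longer(
    cv[, c("time", "z", "r_ee", "mu")],
    cols = c("z", "r_ee", "mu"),
    names_to = "variable", values_to = "value"
  )
  ggplot(long, aes(.data$time, .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~variable, scales = "free_y", ncol = 1) +
    labs(x = "time (reduced)", y = NULL) +
    theme_minimal()
}

#' Plot a stepwise pull
#'
#' COM displacement along the pull direction per force level.
#'
#' @param object A `pull_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pull_result <- function(object, ...) {
  segs <- purrr::imap(object$segments, function(s, lev) {
    d <- drift_fit(s, object$protocol$direction, 0)$data
    d$level <- lev
    d$force <- object$protocol$force_start +
      (lev - 1) * object$protocol$force_step
    d
  })
  df <- bind_rows(segs)
  ggplot(df, aes(.data$time, .data$disp)) +
    geom_line() +
    facet_wrap(~force, labeller = "label_both", scales = "free") +
    labs(x = "time in level (reduced)", y = "COM displacement (sigma)") +
    theme_minimal()
}

#' Plot strain LD geometry summaries
#'
#' Total LD volume and net surface area per cell, per strain.
#'
#' @param summaries Tibble of [strain_summary()] rows.
#' @return A ggplot.
#' @export
plot_ld_geometry <- function(summaries) {
  long <- tidyr::pivot_longer(
    as_tibble(summaries)[, c("strain", "v_total_um3", "s_total_um2")],
    cols = c("v_total_um3", "s_total_um2"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- c(
    v_total_um3 = "total LD volume (um^3/cell)",
    s_total_um2 = "net LD surface (um^2/cell)"
  )[long$quantity]
  ggplot(long, aes(.data$strain, .data$value)) +
    geom_col(fill = "grey35") +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a bead-density profile along z
#'
#' Diagnostic slab profile by bead class; shows the solvent | monolayer |
#' core layering of an assembled state.
#'
#' @param state A `cg_state`.
#' @param bin Bin width (sigma).
#' @return A ggplot.
#' @export
plot_density_profile <- function(state, bin = 0.5) {
  df <- tibble(
    z = state$positions[, 3],
    class = state$beads$molecule_class
  )
  df$zbin <- floor(df$z / bin) * bin + bin / 2
  dens <- df |>
    group_by(.data$class, .data$zbin) |>
    summarise(count = n(), .groups = "drop") |>
    mutate(density = .data$count / (state$box[1] * state$box[2] * bin))
  ggplot(dens, aes(.data$zbin, .data$density, colour = .data$class)) +
    geom_line() +
    labs(x = "z (sigma)", y = "bead density (sigma^-3)", colour = NULL) +
    theme_minimal()
}
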