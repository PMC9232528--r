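#' Lipid-droplet measurement table
#'
#' Validates a per-cell LD diameter table (columns `strain`, `cell_id`,
#' `ld_diameter_um`) or a per-strain summary table (columns `strain`,
#' `n_ld_per_cell`, `d_avg_um`). The two modes are mutually exclusive per
#' strain.
#'
#' @param x Data frame in one of the two schemas.
#' @return A validated tibble with attribute `mode` = `"per_cell"` or
#'   `"summary"`.
#' @export
ld_measurements <- function(x) {
  x <- as_tibble(x)
  per_cell <- all(c("strain", "cell_id", "ld_diameter_um") %in% names(x))
  summary_mode <- all(c("strain", "n_ld_per_cell", "d_avg_um") %in% names(x))
  if (per_cell && summary_mode) {
    abort("per-cell and summary columns are mutually exclusive")
  }
  if (!per_cell && !summary_mode) {
    abort(paste(
      "expected columns strain/cell_id/ld_diameter_um (per-cell) or",
      "strain/n_ld_per_cell/d_avg_um (summary)"
    ))
  }
  if (per_cell && any(x$ld_diameter_um <= 0)) {
    abort("LD diameters must be > 0")
  }
  if (summary_mode && any(x$n_ld_per_cell < 0 | x$d_avg_um <= 0)) {
    abort("summary rows need n_ld_per_cell >= 0 and d_avg_um > 0")
  }
  attr(x, "mode") <- if (per_cell) "per_cell" else "summary"
  x
}

#' Per-strain LD geometry summary
#'
#' Treats each LD as a sphere. With per-cell diameters the per-cell total
#' volume is `sum_i (pi/6) d_i^3` and the net surface `sum_i pi d_i^2`,
#' averaged over cells. In summary mode the mean-diameter approximation
#' `N (pi/6) D_avg^3` and `N pi D_avg^2` is used and flagged: because
#' `E[d^3] >= E[d]^3` it understates the volume of a dispersed population.
#'
#' @param table An [ld_measurements()] table (either schema).
#' @param strain Strain label to summarise.
#' @return A `strain_summary` tibble row: mean LD count per cell, mean
#'   diameter (um), `v_total_um3` and `s_total_um2` per cell, `n_cells`,
#'   and `mean_diameter_approximation` flag.
#' @export
#' @examples
#' t <- ld_measurements(data.frame(
#'   strain = "WT", cell_id = 1, ld_diameter_um = 1
#' ))
#' strain_summary(t, "WT") # V = pi/6, S = pi
strain_summary <- function(table, strain) {
  table <- ld_measurements(table)
  mode <- attr(table, "mode")
  rows <- table[table$strain == strain, ]
  if (!nrow(rows)) abort(sprintf("unknown strain: %s", strain))
  if (mode == "per_cell") {
    per_cell <- rows |>
      group_by(.data$cell_id) |>
      summarise(
        n_ld = n(),
        v = sum(pi / 6 * .data$ld_diameter_um^3),
        s = sum(pi * .data$ld_diameter_um^2),
        .groups = "drop"
      )
    out <- tibble(
      strain = strain,
      n_ld_per_cell = mean(per_cell$n_ld),
      d_avg_um = mean(rows$ld_diameter_um),
      v_total_um3 = mean(per_cell$v),
      s_total_um2 = mean(per_cell$s),
      n_cells = nrow(per_cell),
      mean_diameter_approximation = FALSE
    )
  } else {
    out <- tibble(
      strain = strain,
      n_ld_per_cell = rows$n_ld_per_cell[1],
      d_avg_um = rows$d_avg_um[1],
      v_total_um3 = rows$n_ld_per_cell[1] * pi / 6 * rows$d_avg_um[1]^3,
      s_total_um2 = rows$n_ld_per_cell[1] * pi * rows$d_avg_um[1]^2,
      n_cells = NA_integer_,
      mean_diameter_approximation = TRUE
    )
  }
  class(out) <- c("strain_summary", class(out))
  out
}

#' Percent change relative to a reference
#'
#' `(value_new - value_ref) / value_ref * 100`.
#'
#' @param value_new New value.
#' @param value_ref Reference value, > 0.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(13.93, 0.43) # ~3139.5
percent_change <- function(value_new, value_ref) {
  if (any(!is.finite(value_ref)) || any(value_ref <= 0)) {
    abort("value_ref must be > 0")
  }
  (value_new - value_ref) / value_ref * 100
}

#' Display-style rounding of percent changes
#'
#' Rounds to the nearest 10 percent above 1000 percent and the nearest 1
#' percent below, mirroring the "~" convention used when such changes are
#' quoted; exact values should be kept in data files.
#'
#' @param pct Percent value(s).
#' @return Rounded percent value(s).
#' @export
percent_change_display <- function(pct) {
  ifelse(abs(pct) >= 1000, round(pct / 100) * 100, round(pct))
}

#' Titer table schema check
#'
#' Columns: strain, lipid, time_h, titer_mg_per_l, sd, terbinafine.
#'
#' @param x Data frame.
#' @return Validated tibble.
#' @export
titer_table <- function(x) {
  x <- as_tibble(x)
  need <- c("strain", "lipid", "time_h", "titer_mg_per_l")
  if (!all(need %in% names(x))) {
    abort(sprintf("titer table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(x$titer_mg_per_l < 0) || any(x$time_h < 0)) {
    abort("titers and times must be >= 0")
  }
  if (!"sd" %in% names(x)) x$sd <- NA_real_
  if (!"terbinafine" %in% names(x)) x$terbinafine <- FALSE
  x
}

#' Storage-scaling classification of a lipid across strains
#'
#' Correlates the strain titers of one lipid with the strains' total LD
#' volume per cell and net LD surface area per cell (Spearman rank
#' correlation) and classifies the lipid as volume-scaled or
#' surface-scaled by the larger correlation, with a stated margin;
#' flexible chains that migrate into the core scale with volume, rigid
#' rods that stay at the monolayer scale with surface.
#'
#' @param summaries Tibble of [strain_summary()] rows (>= 3 strains).
#' @param titers A [titer_table()].
#' @param lipid Lipid to classify (e.g. `"squalene"`).
#' @param time_h Fermentation time to use (default: latest shared).
#' @param terbinafine Use the terbinafine arm (default `FALSE`).
#' @param margin Minimum correlation difference for a non-indeterminate
#'   call.
#' @return A `scaling_report`: `classification`, `cor_volume`,
#'   `cor_surface`, and the joined per-strain `table`.
#' @export
storage_scaling_report <- function(summaries, titers, lipid,
                                   time_h = NULL, terbinafine = FALSE,
                                   margin = 0.1) {
  titers <- titer_table(titers)
  t <- titers[titers$lipid == lipid & titers$terbinafine == terbinafine, ]
  if (is.null(time_h)) time_h <- max(t$time_h)
  t <- t[t$time_h == time_h, ]
  t <- t |>
    group_by(.data$strain) |>
    summarise(titer = mean(.data$titer_mg_per_l), .groups = "drop")
  joined <- dplyr::inner_join(as_tibble(summaries), t, by = "strain")
  joined <- joined[complete.cases(joined[, c("titer", "v_total_um3", "s_total_um2")]), ]
  if (nrow(joined) < 3) {
    return(structure(
      list(
        lipid = lipid, classification = "indeterminate",
        reason = sprintf(
          "only %d strain(s) with both geometry and titer; >= 3 required",
          nrow(joined)
        ),
        cor_volume = NA_real_, cor_surface = NA_real_, table = joined
      ),
      class = "scaling_report"
    ))
  }
  if (sd(joined$titer) == 0) {
    cls <- "indeterminate"
    cv <- cs <- NA_real_
  } else {
    cv <- cor(joined$titer, joined$v_total_um3, method = "spearman")
    cs <- cor(joined$titer, joined$s_total_um2, method = "spearman")
    cls <- if (!is.finite(cv) || !is.finite(cs)) {
      "indeterminate"
    } else if (cv - cs > margin) {
      "volume-scaled"
    } else if (cs - cv > margin) {
      "surface-scaled"
    } else {
      "indeterminate"
    }
  }
  structure(
    list(
      lipid = lipid, classification = cls, reason = NULL,
      cor_volume = cv, cor_surface = cs, margin = margin,
      time_h = time_h, table = joined
    ),
    class = "scaling_report"
  )
}

#' Percentile bootstrap confidence interval for a per-cell statistic
#'
#' @param x Per-cell values (>= 2).
#' @param statistic Function of a numeric vector (default mean).
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed (deterministic).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 2000, level = 0.95,
                         seed = 1) {
  if (length(x) < 2) abort("bootstrap_ci needs >= 2 observations")
  stats <- with_seed(seed, {
    vapply(
      seq_len(n_boot),
      function(i) statistic(sample(x, replace = TRUE)),
      numeric(1)
    )
  })
  a <- (1 - level) / 2
  setNames(quantile(stats, c(a, 1 - a), names = FALSE), c("low", "high"))
}

#' Write a morphometry report
#'
#' Machine-readable TSV plus a short human-readable text block.
#'
#' @param summaries Tibble of [strain_summary()] rows.
#' @param reports List of `scaling_report` objects (may be empty).
#' @param path Base path; writes `<path>.tsv` and `<path>.txt`.
#' @return Invisible named vector of the two file paths.
#' @export
write_morphometry_report <- function(summaries, reports, path) {
  tsv <- paste0(path, ".tsv")
  txt <- paste0(path, ".txt")
  readr::write_tsv(as_tibble(summaries), tsv)
  lines <- c("LD morphometry report", "")
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    lines <- c(lines, sprintf(
      "%s: %.2f LDs/cell, D_avg %.3f um, V_total %.4f um^3/cell, S_total %.4f um^2/cell%s",
      s$strain, s$n_ld_per_cell, s$d_avg_um, s$v_total_um3, s$s_total_um2,
      if (isTRUE(s$mean_diameter_approximation)) " (mean-diameter approximation)" else ""
    ))
  }
  for (r in reports) {
    lines <- c(lines, "", sprintf(
      "%s: %s (rho_volume = %.3f, rho_surface = %.3f)",
      r$lipid, r$classification, r$cor_volume, r$cor_surface
    ))
  }
  writeLines(lines, txt)
  invisible(c(tsv = tsv, txt = txt))
}
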