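#' Per-strain LD population model
#'
#' Counts per cell are Poisson (optionally negative binomial for
#' over-dispersion); diameters are lognormal, right-skewed and strictly
#' positive like observed LD size distributions.
#'
#' @param strain Strain label.
#' @param lambda Mean LD count per cell, > 0.
#' @param median_um Median LD diameter (um), > 0.
#' @param gsd Geometric standard deviation of the diameters, >= 1.
#' @param n_cells Number of cells to simulate.
#' @param dispersion NB size parameter; `Inf` (default) keeps Poisson.
#' @return An `ld_population_model` row (tibble).
#' @export
ld_population_model <- function(strain, lambda, median_um, gsd = 1.25,
                                n_cells = 6, dispersion = Inf) {
  stopifnot_scalar_number(lambda, "lambda", positive = TRUE)
  stopifnot_scalar_number(median_um, "median_um", positive = TRUE)
  if (gsd < 1) abort("gsd must be >= 1")
  out <- tibble(
    strain = strain, lambda = lambda, median_um = median_um, gsd = gsd,
    n_cells = as.integer(n_cells), dispersion = dispersion
  )
  class(out) <- c("ld_population_model", class(out))
  out
}

#' Preset LD population models for the three strains
#'
#' Wild type (~23 LDs/cell, median diameter 0.20 um), the large-droplet
#' strain (fewer, ~70% wider droplets, median 0.33 um) and the
#' many-droplet strain (51.67 LDs/cell at wild-type size).
#'
#' @param n_cells Cells per strain.
#' @param gsd Diameter geometric SD shared by the presets.
#' @return Tibble of [ld_population_model()] rows.
#' @export
ld_strain_presets <- function(n_cells = 6, gsd = 1.25) {
  bind_rows(
    ld_population_model("WT", 23, 0.20, gsd, n_cells),
    ld_population_model("LD-size", 16, 0.33, gsd, n_cells),
    ld_population_model("LD-number", 51.67, 0.20, gsd, n_cells)
  )
}

#' Generate a per-cell LD diameter table
#'
#' Seed-deterministic draws from the count and diameter distributions of
#' each model row, in the schema consumed by [strain_summary()].
#'
#' @param model Tibble of [ld_population_model()] rows.
#' @param seed Integer seed.
#' @return Per-cell [ld_measurements()] tibble (strain, cell_id,
#'   ld_diameter_um).
#' @export
#' @examples
#' tab <- generate_ld_table(ld_strain_presets(n_cells = 10), seed = 1)
generate_ld_table <- function(model, seed = 1) {
  rows <- with_seed(seed, {
    purrr::pmap(model, function(strain, lambda, median_um, gsd, n_cells,
                                dispersion, ...) {
      counts <- if (is.finite(dispersion)) {
        rnbinom(n_cells, size = dispersion, mu = lambda)
      } else {
        rpois(n_cells, lambda)
      }
      purrr::map2(seq_len(n_cells), counts, function(cell, k) {
        if (k == 0) {
          return(tibble(
            strain = strain, cell_id = cell, ld_diameter_um = double()
          ))
        }
        tibble(
          strain = strain, cell_id = cell,
          ld_diameter_um = rlnorm(k, meanlog = log(median_um),
                                  sdlog = log(gsd))
        )
      }) |> bind_rows()
    })
  })
  ld_measurements(bind_rows(rows))
}

#' Titer replicate model
#'
#' Per strain/lipid/time mean and SD (mg/L) with `n_rep` replicates drawn
#' as Gaussians truncated at zero.
#'
#' @param strain,lipid,time_h,mean_mg_per_l,sd_mg_per_l Model cells
#'   (vectorized).
#' @param terbinafine Logical flag per row.
#' @param n_rep Replicates per condition (biological triplicates by
#'   default).
#' @return A `titer_model` tibble.
#' @export
titer_model <- function(strain, lipid, time_h, mean_mg_per_l, sd_mg_per_l = 0,
                        terbinafine = FALSE, n_rep = 3) {
  if (any(mean_mg_per_l < 0) || any(sd_mg_per_l < 0)) {
    abort("titer means and sds must be >= 0")
  }
  out <- tibble(
    strain = strain, lipid = lipid, time_h = time_h,
    mean_mg_per_l = mean_mg_per_l, sd_mg_per_l = sd_mg_per_l,
    terbinafine = terbinafine, n_rep = as.integer(n_rep)
  )
  class(out) <- c("titer_model", class(out))
  out
}

#' Preset titer model carrying the 144-h endpoint means
#'
#' Squalene: 0.43 (WT), 13.93 (LD-size) mg/L with an intermediate
#' many-droplet value; zeaxanthin: 1.27 (WT), 2.16 (LD-size), 2.85
#' (LD-number) mg/L.
#'
#' @param sd_frac Replicate SD as a fraction of the mean.
#' @return A `titer_model` tibble.
#' @export
titer_presets <- function(sd_frac = 0.08) {
  m <- tibble(
    strain = rep(c("WT", "LD-size", "LD-number"), 2),
    lipid = rep(c("squalene", "zeaxanthin"), each = 3),
    time_h = 144,
    mean_mg_per_l = c(0.43, 13.93, 1.00, 1.27, 2.16, 2.85)
  )
  titer_model(m$strain, m$lipid, m$time_h, m$mean_mg_per_l,
              sd_frac * m$mean_mg_per_l)
}

#' Generate a titer replicate table
#'
#' @param model A [titer_model()] tibble.
#' @param seed Integer seed.
#' @return A [titer_table()] tibble with one row per replicate.
#' @export
generate_titer_table <- function(model, seed = 1) {
  rows <- with_seed(seed, {
    purrr::pmap(model, function(strain, lipid, time_h, mean_mg_per_l,
                                sd_mg_per_l, terbinafine, n_rep, ...) {
      tibble(
        strain = strain, lipid = lipid, time_h = time_h,
        titer_mg_per_l = pmax(0, rnorm(n_rep, mean_mg_per_l, sd_mg_per_l)),
        sd = sd_mg_per_l, terbinafine = terbinafine
      )
    })
  })
  titer_table(bind_rows(rows))
}

#' Unbiased overdamped trajectory on a toy landscape
#'
#' Overdamped Langevin dynamics on the analytic double-well (or separable
#' 2D) potential, without any bias; oracle input for free-energy and
#' sampling tests.
#'
#' @param potential `"double_well_1d"` or `"separable_2d"`.
#' @param h,a Barrier heights and well positions (length 1 or 2).
#' @param n_steps Steps.
#' @param dt Time step.
#' @param temperature Reduced temperature.
#' @param mobility_gamma Overdamped friction.
#' @param x0 Start point.
#' @param seed Integer seed.
#' @param stride Recording stride.
#' @return Tibble `time`, `x` (and `y` in 2D).
#' @export
generate_toy_landscape_trajectory <- function(potential = c("double_well_1d", "separable_2d"),
                                              h = 4, a = 1, n_steps = 1e5,
                                              dt = 5e-4, temperature = 1,
                                              mobility_gamma = 1, x0 = -1,
                                              seed = 1, stride = 20) {
  potential <- match.arg(potential)
  dim <- if (potential == "double_well_1d") 1L else 2L
  h <- rep_len(h, dim)
  a <- rep_len(a, dim)
  x0 <- rep_len(x0, dim)
  out <- cpp_toy_metad(
    dim, h, a, x0, dt, temperature, mobility_gamma, n_steps,
    derive_seed(seed, "toy-unbiased"), as.integer(stride),
    FALSE, 0, rep(1, dim), 0L, 10, rep(0, dim), rep(1, dim),
    rep(2L, dim), 0
  )
  traj <- as_tibble(out$trajectory, .name_repair = "minimal")
  names(traj) <- c("time", "x", "y")[seq_len(1 + dim)]
  traj
}

#' Write the synthetic CSV fixtures
#'
#' Emits `ld_measurements.csv` (per-cell) and `titers.csv` in the exact
#' schemas the morphometry readers consume, with a `# params:` comment
#' header logging the generating model and seed.
#'
#' @param dir Output directory.
#' @param preset `"wt"`, `"ld-size"`, `"ld-number"` or `"all"`.
#' @param n_cells Cells per strain.
#' @param seed Integer seed.
#' @return Named vector of file paths.
#' @export
write_synthetic_fixtures <- function(dir, preset = "all", n_cells = 6,
                                     seed = 1) {
  models <- ld_strain_presets(n_cells = n_cells)
  if (preset != "all") {
    keep <- c(wt = "WT", `ld-size` = "LD-size", `ld-number` = "LD-number")[preset]
    models <- models[models$strain == keep, ]
  }
  ld <- generate_ld_table(models, seed = seed)
  ti <- generate_titer_table(titer_presets(), seed = derive_seed(seed, "titer"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ld_path <- file.path(dir, "ld_measurements.csv")
  ti_path <- file.path(dir, "titers.csv")
  hdr <- sprintf("# params: preset=%s n_cells=%d seed=%d", preset, n_cells, seed)
  writeLines(hdr, ld_path)
  readr::write_csv(ld, ld_path, append = TRUE, col_names = TRUE)
  writeLines(hdr, ti_path)
  readr::write_csv(ti, ti_path, append = TRUE, col_names = TRUE)
  c(ld = ld_path, titers = ti_path)
}

#' Read a measurement CSV written with a parameter header
#'
#' @param path CSV path (comment lines start `#`).
#' @return Tibble.
#' @export
read_measurement_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
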