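paper_geometry <- function() {
  ld <- read_measurement_csv(
    system.file("extdata", "ld_summary.csv", package = "ldflex")
  )
  dplyr::bind_rows(lapply(unique(ld$strain), function(s) strain_summary(ld, s)))
}

test_that("sphere formulas are exact for a single droplet", {
  t <- ld_measurements(data.frame(
    strain = "WT", cell_id = 1, ld_diameter_um = 1
  ))
  s <- strain_summary(t, "WT")
  expect_equal(s$v_total_um3, pi / 6, tolerance = 1e-12)
  expect_equal(s$s_total_um2, pi, tolerance = 1e-12)
  expect_false(s$mean_diameter_approximation)
})

test_that("per-cell geometry matches a brute-force summation oracle", {
  tab <- generate_ld_table(ld_strain_presets(n_cells = 12), seed = 11)
  for (strain in unique(tab$strain)) {
    s <- strain_summary(tab, strain)
    rows <- tab[tab$strain == strain, ]
    v <- tapply(pi / 6 * rows$ld_diameter_um^3, rows$cell_id, sum)
    a <- tapply(pi * rows$ld_diameter_um^2, rows$cell_id, sum)
    expect_equal(s$v_total_um3, mean(v), tolerance = 1e-12)
    expect_equal(s$s_total_um2, mean(a), tolerance = 1e-12)
  }
})

test_that("summary mode reproduces the printed net surface area of the many-droplet strain", {
  g <- paper_geometry()
  ldn <- g[g$strain == "LD-number", ]
  expect_equal(ldn$s_total_um2, 51.67 * pi * 0.20^2, tolerance = 1e-12)
  expect_equal(round(ldn$s_total_um2, 3), 6.493, tolerance = 1e-3)
  expect_true(ldn$mean_diameter_approximation)
})

test_that("percent change reproduces the printed storage increases", {
  expect_equal(percent_change(13.93, 0.43), 3139.535, tolerance = 1e-4)
  expect_equal(percent_change_display(percent_change(13.93, 0.43)), 3100)
  expect_equal(percent_change(2.85, 2.16), 31.94444, tolerance = 1e-4)
  expect_equal(percent_change(2.85, 1.27), 124.4094, tolerance = 1e-4)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "value_ref")
})

test_that("percent change antisymmetry identity holds numerically", {
  for (seed in 1:20) {
    ab <- ldflex:::with_seed(seed, runif(2, 0.1, 50))
    lhs <- percent_change(ab[1], ab[2])
    rhs <- -percent_change(ab[2], ab[1]) * ab[1] / ab[2]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("storage scaling classifies squalene volume-scaled and zeaxanthin surface-scaled", {
  g <- paper_geometry()
  ti <- read_measurement_csv(
    system.file("extdata", "titers.csv", package = "ldflex")
  )
  sq <- storage_scaling_report(g, ti, "squalene")
  ze <- storage_scaling_report(g, ti, "zeaxanthin")
  expect_equal(sq$classification, "volume-scaled")
  expect_equal(ze$classification, "surface-scaled")
  # classification invariant under positive titer rescaling
  ti2 <- ti
  ti2$titer_mg_per_l <- ti2$titer_mg_per_l * 7.3
  expect_equal(storage_scaling_report(g, ti2, "squalene")$classification,
               "volume-scaled")
  # constant titers -> indeterminate
  ti3 <- ti
  ti3$titer_mg_per_l <- 2
  expect_equal(storage_scaling_report(g, ti3, "squalene")$classification,
               "indeterminate")
  # fewer than 3 strains -> indeterminate with explanation
  few <- storage_scaling_report(g[1:2, ], ti, "squalene")
  expect_equal(few$classification, "indeterminate")
  expect_match(few$reason, "3")
})

test_that("bootstrap CI is seed-deterministic, degenerate on constants, and covers the mean", {
  expect_equal(bootstrap_ci(rep(3, 6), seed = 1), c(low = 3, high = 3))
  x <- ldflex:::with_seed(5, rlnorm(6, 0, 0.4))
  ci1 <- bootstrap_ci(x, n_boot = 500, seed = 9)
  ci2 <- bootstrap_ci(x, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_error(bootstrap_ci(1), ">= 2")
  # coverage at nominal 95% stays above 90% for lognormal samples (n = 12)
  true_mean <- exp(0.3^2 / 2)
  hits <- 0
  reps <- 200
  sims <- ldflex:::with_seed(31, {
    lapply(seq_len(reps), function(i) rlnorm(12, 0, 0.3))
  })
  for (i in seq_len(reps)) {
    ci <- bootstrap_ci(sims[[i]], n_boot = 300, seed = i)
    if (ci["low"] <= true_mean && true_mean <= ci["high"]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("measurement table schema violations are caught", {
  expect_error(ld_measurements(data.frame(x = 1)), "expected columns")
  expect_error(
    ld_measurements(data.frame(strain = "a", cell_id = 1, ld_diameter_um = -1)),
    "diameters"
  )
  expect_error(strain_summary(
    data.frame(strain = "a", cell_id = 1, ld_diameter_um = 1), "missing"
  ), "unknown strain")
  expect_error(
    titer_table(data.frame(strain = "a", lipid = "squalene", time_h = 1,
                           titer_mg_per_l = -2)),
    "titers"
  )
})

test_that("morphometry report files carry the headline values", {
  g <- paper_geometry()
  ti <- read_measurement_csv(
    system.file("extdata", "titers.csv", package = "ldflex")
  )
  reports <- list(
    storage_scaling_report(g, ti, "squalene"),
    storage_scaling_report(g, ti, "zeaxanthin")
  )
  base <- withr_local_file("morph")
  paths <- write_morphometry_report(g, reports, base)
  txt <- readLines(paths["txt"])
  expect_true(any(grepl("6.49", txt)))
  expect_true(any(grepl("volume-scaled", txt)))
  expect_true(any(grepl("surface-scaled", txt)))
  tsv <- readr::read_tsv(paths["tsv"], show_col_types = FALSE)
  expect_equal(nrow(tsv), 3)
})
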