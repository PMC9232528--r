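test_that("LD table generation is seed-deterministic and respects degenerate parameters", {
  m <- ld_strain_presets(n_cells = 5)
  t1 <- generate_ld_table(m, seed = 42)
  t2 <- generate_ld_table(m, seed = 42)
  expect_identical(t1, t2)
  t3 <- generate_ld_table(m, seed = 43)
  expect_false(identical(t1, t3))
  # gsd = 1: every diameter equals the median
  m0 <- ld_population_model("X", lambda = 10, median_um = 0.25, gsd = 1,
                            n_cells = 4)
  t0 <- generate_ld_table(m0, seed = 1)
  expect_true(all(abs(t0$ld_diameter_um - 0.25) < 1e-12))
})

test_that("wild-type preset count mean falls in the Poisson confidence band at n = 200", {
  m <- ld_population_model("WT", lambda = 23, median_um = 0.20, n_cells = 200)
  tab <- generate_ld_table(m, seed = 7)
  counts <- tapply(tab$cell_id, tab$cell_id, length)
  # cells with zero droplets are absent from the per-LD rows
  n_zero <- 200 - length(counts)
  mean_count <- sum(counts) / 200
  expect_true(mean_count > 21.5 && mean_count < 24.5)
  expect_equal(n_zero, 0) # P(0 | lambda = 23) is negligible
})

test_that("model parameter validation rejects impossible populations", {
  expect_error(ld_population_model("X", -1, 0.2), "lambda")
  expect_error(ld_population_model("X", 5, 0.2, gsd = 0.8), "gsd")
  expect_error(titer_model("X", "squalene", 144, -1), ">= 0")
})

test_that("titer generation is seed-deterministic; sd = 0 returns the means", {
  m <- titer_presets(sd_frac = 0)
  t0 <- generate_titer_table(m, seed = 3)
  expect_equal(
    sort(unique(t0$titer_mg_per_l)),
    sort(unique(m$mean_mg_per_l))
  )
  m2 <- titer_presets(sd_frac = 0.1)
  expect_identical(generate_titer_table(m2, seed = 5),
                   generate_titer_table(m2, seed = 5))
})

test_that("noise-free preset titers reproduce the printed percent increases", {
  t0 <- generate_titer_table(titer_presets(sd_frac = 0), seed = 1)
  sq <- tapply(
    t0$titer_mg_per_l[t0$lipid == "squalene"],
    t0$strain[t0$lipid == "squalene"], mean
  )
  expect_equal(percent_change(sq["LD-size"], sq["WT"]),
               c(`LD-size` = 3139.535), tolerance = 1e-4)
  ze <- tapply(
    t0$titer_mg_per_l[t0$lipid == "zeaxanthin"],
    t0$strain[t0$lipid == "zeaxanthin"], mean
  )
  expect_equal(unname(percent_change(ze["LD-number"], ze["LD-size"])),
               31.944, tolerance = 1e-3)
  expect_equal(unname(percent_change(ze["LD-number"], ze["WT"])),
               124.409, tolerance = 1e-3)
})

test_that("morphometry round trip recovers the generating parameters at n_cells = 200", {
  m <- ld_strain_presets(n_cells = 200)
  tab <- generate_ld_table(m, seed = 21)
  for (i in seq_len(nrow(m))) {
    s <- strain_summary(tab, m$strain[i])
    expect_lt(abs(s$n_ld_per_cell - m$lambda[i]) / m$lambda[i], 0.05)
    rows <- tab[tab$strain == m$strain[i], ]
    expect_lt(
      abs(median(rows$ld_diameter_um) - m$median_um[i]) / m$median_um[i],
      0.05
    )
  }
})

test_that("unbiased toy double-well sampling matches Boltzmann occupancy", {
  tr <- generate_toy_landscape_trajectory(
    "double_well_1d", h = 1, a = 1, n_steps = 3e5, dt = 5e-4,
    temperature = 1, seed = 2
  )
  # symmetric wells: equal occupancy
  expect_lt(abs(mean(tr$x < 0) - 0.5), 0.08)
  # degenerate stiff well: series stays near the start basin minimum
  tr2 <- generate_toy_landscape_trajectory(
    "double_well_1d", h = 400, a = 1, n_steps = 2e4, dt = 1e-5,
    temperature = 0.05, seed = 3, x0 = -1
  )
  expect_lt(sd(tr2$x), 0.05)
  expect_lt(abs(mean(tr2$x) + 1), 0.05)
  # determinism
  expect_identical(
    generate_toy_landscape_trajectory(n_steps = 1e3, seed = 9),
    generate_toy_landscape_trajectory(n_steps = 1e3, seed = 9)
  )
})

test_that("synthetic fixture files carry schema and parameter headers", {
  dir <- file.path(tempdir(), "synthfix")
  paths <- write_synthetic_fixtures(dir, preset = "wt", n_cells = 4, seed = 2)
  on.exit(unlink(dir, recursive = TRUE))
  first <- readLines(paths["ld"], n = 1)
  expect_match(first, "# params:.*seed=2")
  ld <- read_measurement_csv(paths["ld"])
  expect_true(all(c("strain", "cell_id", "ld_diameter_um") %in% names(ld)))
  ti <- read_measurement_csv(paths["titers"])
  expect_true(all(c("strain", "lipid", "titer_mg_per_l") %in% names(ti)))
})
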