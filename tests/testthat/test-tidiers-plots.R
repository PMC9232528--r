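test_that("tidy and glance methods return well-formed tibbles", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.2),
                     grid = list(z = c(-2, 2, 41)))
  fes <- reconstruct_fes(deposit_hill(0, bias_state(params = mp), time = 1))
  td <- tidy(fes)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("z", "free_energy"))
  expect_equal(nrow(td), 41)
  g <- glance(fes)
  expect_equal(g$n_hills, 1)

  ld <- read_measurement_csv(
    system.file("extdata", "ld_summary.csv", package = "ldflex")
  )
  ti <- read_measurement_csv(
    system.file("extdata", "titers.csv", package = "ldflex")
  )
  summaries <- dplyr::bind_rows(
    lapply(unique(ld$strain), function(s) strain_summary(ld, s))
  )
  rep <- storage_scaling_report(summaries, ti, "squalene")
  expect_equal(glance(rep)$classification, "volume-scaled")
  expect_equal(nrow(tidy(rep)), 3)
})

test_that("autoplot methods return ggplot objects without evaluation errors", {
  mp <- metad_params(cvs = c("z", "mu"), sigma = c(z = 0.2, mu = 0.05),
                     grid = list(z = c(-2, 2, 21), mu = c(0, 1, 11)))
  fes <- reconstruct_fes(deposit_hill(c(0, 0.5), bias_state(params = mp),
                                      time = 1))
  p1 <- ggplot2::autoplot(fes)
  expect_s3_class(p1, "ggplot")
  built <- ggplot2::ggplot_build(p1)
  expect_gt(nrow(built$data[[1]]), 0)

  st <- make_fluid(10, 8, seed = 2)
  ld <- read_measurement_csv(
    system.file("extdata", "ld_summary.csv", package = "ldflex")
  )
  summaries <- dplyr::bind_rows(
    lapply(unique(ld$strain), function(s) strain_summary(ld, s))
  )
  p2 <- plot_ld_geometry(summaries)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_density_profile(st)
  expect_s3_class(p3, "ggplot")
})

test_that("unit mapping anchors the rigid contour to 2.4 nm and 300 K", {
  u <- unit_map(contour_sigma = 6.79)
  expect_equal(to_physical(6.79, u, "length"), 2.4, tolerance = 1e-12)
  expect_equal(u$K_per_T, 300)
  # 1 epsilon = k_B * 300 K in kcal/mol
  expect_equal(to_physical(1, u, "energy"), 0.59616, tolerance = 1e-4)
})
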