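test_that("bias potential obeys Gaussian arithmetic", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.2),
                     grid = list(z = c(-2, 2, 101)))
  b <- bias_state(params = mp)
  expect_equal(bias_potential(0.7, b), 0) # no hills -> 0 everywhere
  b <- deposit_hill(0.5, b, time = 1)
  expect_equal(bias_potential(0.5, b), 0.5, tolerance = 1e-12)
  expect_equal(bias_potential(0.5 + 0.2, b), 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_error(bias_potential(5, b), "outside the bias grid")
})

test_that("gridded bias matches direct summation within 1e-6 for random hill sets", {
  for (seed in 1:3) {
    mp <- metad_params(cvs = c("z", "mu"), sigma = c(z = 0.2, mu = 0.06),
                       grid = list(z = c(-4, 2, 121), mu = c(0, 1, 61)))
    hills <- ldflex:::with_seed(seed, tibble::tibble(
      time = 1:100,
      c1 = runif(100, -3.5, 1.5), c2 = runif(100, 0.05, 0.95),
      sigma1 = 0.2, sigma2 = 0.06,
      height = runif(100, 0.05, 0.5), walker = 1
    ))
    b <- bias_state(hills, mp)
    g <- ldflex:::hills_grid(b)
    # grid vector is laid out with the second CV varying fastest
    pts <- as.matrix(expand.grid(
      mu = seq(0, 1, length.out = 61), z = seq(-4, 2, length.out = 121)
    ))[, c("z", "mu")]
    direct <- bias_potential(pts, b)
    expect_lt(max(abs(g$V - direct)), 1e-6)
  }
})

test_that("well-tempered heights decay exactly and strictly at a revisited center", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.15), omega0 = 0.4,
                     gamma_wt = 8, grid = list(z = c(-2, 2, 201)))
  b <- bias_state(params = mp)
  v <- 0
  expected <- c()
  for (i in 1:6) {
    expected <- c(expected, 0.4 * exp(-v / (1 * (8 - 1))))
    v <- v + expected[i]
    b <- deposit_hill(0.3, b, time = i)
  }
  expect_equal(b$hills$height, expected, tolerance = 1e-12)
  expect_true(all(diff(b$hills$height) < 0))
  expect_equal(b$hills$height[1], 0.4) # first hill lands at full height
})

test_that("multiwalker sync is identity for one walker and additive across walkers", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.1),
                     grid = list(z = c(-2, 2, 101)))
  b1 <- deposit_hill(-0.5, bias_state(params = mp), time = 1)
  expect_equal(multiwalker_sync(list(b1))$hills, b1$hills)
  b2 <- deposit_hill(0.8, bias_state(params = mp), time = 2, walker = 2)
  merged <- multiwalker_sync(list(b1, b2))
  xs <- matrix(seq(-1.5, 1.5, length.out = 31))
  expect_equal(
    bias_potential(xs, merged),
    bias_potential(xs, b1) + bias_potential(xs, b2),
    tolerance = 1e-12
  )
  # merged FES equals the FES of the concatenated hill list
  direct <- bias_state(dplyr::bind_rows(b1$hills, b2$hills), mp)
  expect_equal(reconstruct_fes(merged)$F, reconstruct_fes(direct)$F,
               tolerance = 1e-9)
  # mismatched parameters refuse to merge
  mp2 <- metad_params(cvs = "z", sigma = c(z = 0.3),
                      grid = list(z = c(-2, 2, 101)))
  b3 <- deposit_hill(0, bias_state(params = mp2), time = 3)
  expect_error(multiwalker_sync(list(b1, b3)), "mismatched")
})

test_that("a single hill reconstructs as a scaled inverted Gaussian", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.25), omega0 = 0.5,
                     gamma_wt = 10, grid = list(z = c(-2, 2, 161)))
  b <- deposit_hill(0.2, bias_state(params = mp), time = 1)
  fes <- reconstruct_fes(b)
  xs <- fes$axes$z
  expected <- -10 / 9 * 0.5 * exp(-(xs - 0.2)^2 / (2 * 0.25^2))
  expected <- expected - min(expected)
  expect_equal(as.numeric(fes$F), expected, tolerance = 1e-6)
  expect_equal(min(fes$F), 0)
  expect_error(reconstruct_fes(bias_state(params = mp)), "empty bias")
})

test_that("the well-tempered FES recovers an analytic double-well barrier within 10%", {
  for (seed in 1:3) {
    res <- run_toy_metadynamics(
      "double_well_1d", h = 4, a = 1,
      metad = metad_params(cvs = "z", sigma = c(z = 0.1), omega0 = 0.5,
                           gamma_wt = 10, pace = 250,
                           grid = list(z = c(-2.2, 2.2, 221))),
      n_steps = 4e5, dt = 5e-4, seed = seed
    )
    bar <- barrier_height(res$fes, list(z = c(-1.3, -0.7)),
                          list(z = c(0.7, 1.3)))
    expect_lt(abs(bar - 4) / 4, 0.10)
  }
})

test_that("2D separable double-well marginals match independent 1D runs", {
  res2 <- run_toy_metadynamics(
    "separable_2d", h = c(3, 2), a = c(1, 1),
    metad = metad_params(
      cvs = c("z", "mu"), sigma = c(z = 0.1, mu = 0.1), omega0 = 0.5,
      gamma_wt = 10, pace = 200,
      grid = list(z = c(-2, 2, 81), mu = c(-2, 2, 81))
    ),
    n_steps = 5e5, dt = 5e-4, seed = 4, x0 = c(-1, -1)
  )
  marg <- fes_project(res2$fes, "z")
  bar2 <- barrier_height(marg, list(z = c(-1.3, -0.7)), list(z = c(0.7, 1.3)))
  res1 <- run_toy_metadynamics(
    "double_well_1d", h = 3, a = 1,
    metad = metad_params(cvs = "z", sigma = c(z = 0.1), omega0 = 0.5,
                         gamma_wt = 10, pace = 200,
                         grid = list(z = c(-2, 2, 81))),
    n_steps = 4e5, dt = 5e-4, seed = 5
  )
  bar1 <- barrier_height(res1$fes, list(z = c(-1.3, -0.7)),
                         list(z = c(0.7, 1.3)))
  expect_lt(abs(bar2 - bar1) / bar1, 0.25)
  expect_lt(abs(bar2 - 3) / 3, 0.2)
})

test_that("barrier heights are zero within a well, symmetric between equal basins", {
  # quadratic single well sampled analytically
  mp <- metad_params(cvs = "z", sigma = c(z = 0.1),
                     grid = list(z = c(-2, 2, 201)))
  fes <- structure(
    list(
      axes = list(z = seq(-2, 2, length.out = 201)),
      F = 2 * seq(-2, 2, length.out = 201)^2,
      metadata = list(gamma_wt = 10, n_hills = 1, n_walkers = 1,
                      temperature = 1)
    ),
    class = "fes"
  )
  expect_lt(
    barrier_height(fes, list(z = c(-0.5, -0.2)), list(z = c(0.2, 0.5))),
    1e-9
  )
  # symmetric double well: barrier(a,b) = barrier(b,a)
  fes$F <- 4 * ((fes$axes$z / 1)^2 - 1)^2
  ba <- barrier_height(fes, list(z = c(-1.2, -0.8)), list(z = c(0.8, 1.2)))
  bb <- barrier_height(fes, list(z = c(0.8, 1.2)), list(z = c(-1.2, -0.8)))
  expect_equal(ba, bb, tolerance = 1e-9)
  expect_error(
    barrier_height(fes, list(z = c(10, 11)), list(z = c(0.8, 1.2))),
    "unsampled|basin"
  )
})

test_that("HILLS and FES files round-trip through their TSV formats", {
  mp <- metad_params(cvs = "z", sigma = c(z = 0.15),
                     grid = list(z = c(-2, 2, 51)))
  b <- deposit_hill(0.3, bias_state(params = mp), time = 1)
  b <- deposit_hill(-0.4, b, time = 2)
  hp <- withr_local_file("HILLS")
  write_hills(b, hp)
  b2 <- read_hills(hp, params = mp)
  expect_equal(b2$hills$c1, b$hills$c1)
  expect_equal(b2$hills$height, b$hills$height)
  fp <- withr_local_file("fes.tsv")
  write_fes(reconstruct_fes(b), fp)
  lines <- readLines(fp)
  expect_match(lines[1], "^# fes gamma_wt=10")
  df <- utils::read.table(fp, skip = 1, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 51)
})
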