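#' Well-tempered metadynamics parameters
#'
#' Bias over the migration depth z and/or the conformation order mu.
#' Hill heights decay with the accumulated bias (well-tempered), giving a
#' convergent free-energy estimate scaled by `gamma_wt / (gamma_wt - 1)`.
#'
#' @param cvs Character subset of `c("z", "mu")`.
#' @param omega0 Initial hill height (reduced energy), default 0.5 k_BT.
#' @param sigma Named per-CV hill widths (defaults: z 0.25, mu 0.05).
#' @param pace Steps between depositions.
#' @param gamma_wt Bias factor, > 1.
#' @param n_walkers Number of replica walkers sharing the bias.
#' @param grid Named list of per-CV `(min, max, n_bins)` (defaults:
#'   z over \eqn{[-8, 4]} with 120 bins, mu over \eqn{[0, 1]} with 60).
#' @param sync_interval Steps between multiwalker bias merges.
#' @param temperature Reduced temperature of the biased run.
#' @param wall_k Stiffness of the reflective bias walls at grid edges.
#' @param seed Integer seed (walker streams are derived from it).
#' @return A `metad_params` list.
#' @export
metad_params <- function(cvs = c("z", "mu"), omega0 = 0.5,
                         sigma = c(z = 0.25, mu = 0.05), pace = 500,
                         gamma_wt = 10, n_walkers = 1,
                         grid = list(z = c(-8, 4, 120), mu = c(0, 1, 60)),
                         sync_interval = 10000, temperature = 1,
                         wall_k = 50, seed = 1) {
  cvs <- match.arg(cvs, c("z", "mu"), several.ok = TRUE)
  if (gamma_wt <= 1) abort("gamma_wt must be > 1")
  if (any(sigma[cvs] <= 0)) abort("hill widths must be > 0")
  if (n_walkers < 1) abort("n_walkers must be >= 1")
  structure(
    list(
      cvs = cvs, omega0 = omega0, sigma = sigma[cvs], pace = as.integer(pace),
      gamma_wt = gamma_wt, n_walkers = as.integer(n_walkers),
      grid = grid[cvs], sync_interval = as.integer(sync_interval),
      temperature = temperature, wall_k = wall_k, seed = as.integer(seed)
    ),
    class = "metad_params"
  )
}

# engine-facing list for one walker continuing from a shared grid
metad_engine_list <- function(params, temperature, walker_id = 1,
                              grid0 = NULL) {
  g <- params$grid
  out <- list(
    enabled = TRUE, ncv = length(params$cvs), omega0 = params$omega0,
    sigma = unname(params$sigma), gamma_wt = params$gamma_wt,
    kT = temperature, pace = params$pace, wall_k = params$wall_k,
    walker_id = as.numeric(walker_id),
    grid_min = vapply(g, `[`, numeric(1), 1),
    grid_max = vapply(g, `[`, numeric(1), 2),
    grid_n = as.integer(vapply(g, `[`, numeric(1), 3))
  )
  if (!is.null(grid0)) {
    out$V0 <- grid0$V
    out$G1 <- grid0$G1
    out$G2 <- grid0$G2 %||% numeric(1)
  }
  out
}

#' Bias state: deposited hills plus parameters
#'
#' @param hills Tibble with columns time, c1, c2, sigma1, sigma2, height,
#'   walker (c2/sigma2 NA for 1-CV biases).
#' @param params The [metad_params()] the hills were deposited under.
#' @return A `metad_bias` object.
#' @export
bias_state <- function(hills = NULL, params = metad_params()) {
  hills <- hills %||% tibble(
    time = double(), c1 = double(), c2 = double(), sigma1 = double(),
    sigma2 = double(), height = double(), walker = double()
  )
  structure(list(hills = as_tibble(hills), params = params),
            class = "metad_bias")
}

#' Evaluate the metadynamics bias potential by direct hill summation
#'
#' `V(s) = sum_hills h * exp(-sum_cv (s_cv - c_cv)^2 / (2 sigma_cv^2))`.
#' This is the exact (reference) evaluation; the engine's gridded bias
#' must match it at bin centers within 1e-6.
#'
#' @param s Numeric CV point (length = number of CVs) or a matrix of
#'   points (one row each).
#' @param bias A `metad_bias`.
#' @return Bias energy at each point.
#' @export
bias_potential <- function(s, bias) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  h <- bias$hills
  ncv <- length(bias$params$cvs)
  grid <- bias$params$grid
  for (c in seq_len(ncv)) {
    rng <- grid[[c]]
    if (any(s[, c] < rng[1] - 1e-9 | s[, c] > rng[2] + 1e-9)) {
      abort("CV point outside the bias grid")
    }
  }
  if (!nrow(h)) return(rep(0, nrow(s)))
  v <- numeric(nrow(s))
  for (p in seq_len(nrow(s))) {
    e <- (s[p, 1] - h$c1)^2 / (2 * h$sigma1^2)
    if (ncv == 2) e <- e + (s[p, 2] - h$c2)^2 / (2 * h$sigma2^2)
    v[p] <- sum(h$height * exp(-e))
  }
  v
}

#' Deposit a well-tempered hill
#'
#' Appends a hill of height `omega0 * exp(-V(s) / (k_B T (gamma_wt - 1)))`
#' at the current CV point; heights at a revisited center decay strictly.
#'
#' @param s CV point (length = number of CVs).
#' @param bias A `metad_bias`.
#' @param params [metad_params()] (defaults to those of `bias`).
#' @param time Deposition time stamp.
#' @param walker Walker id.
#' @return The updated `metad_bias`.
#' @export
deposit_hill <- function(s, bias, params = bias$params, time = NA_real_,
                         walker = 1) {
  if (any(!is.finite(s))) abort("non-finite CV at deposition")
  v <- bias_potential(s, bias)
  dT <- params$temperature * (params$gamma_wt - 1)
  h <- params$omega0 * exp(-v / dT)
  ncv <- length(params$cvs)
  bias$hills <- bind_rows(bias$hills, tibble(
    time = time, c1 = s[1], c2 = if (ncv == 2) s[2] else NA_real_,
    sigma1 = unname(params$sigma[1]),
    sigma2 = if (ncv == 2) unname(params$sigma[2]) else NA_real_,
    height = h, walker = as.numeric(walker)
  ))
  bias
}

#' Merge walker biases
#'
#' Union of all walkers' hills, time-ordered; every walker subsequently
#' sees the merged bias. Walkers must share identical parameters.
#'
#' @param biases List of `metad_bias` objects.
#' @return Merged `metad_bias`.
#' @export
multiwalker_sync <- function(biases) {
  if (!length(biases)) abort("no walker biases to merge")
  p0 <- biases[[1]]$params
  for (b in biases[-1]) {
    same <- identical(b$params$cvs, p0$cvs) &&
      identical(b$params$sigma, p0$sigma) &&
      b$params$gamma_wt == p0$gamma_wt && b$params$omega0 == p0$omega0
    if (!same) abort("mismatched metadynamics parameters across walkers")
  }
  hills <- bind_rows(lapply(biases, function(b) b$hills))
  hills <- hills[order(hills$time), ]
  bias_state(hills, p0)
}

# gridded bias (V plus gradients) of a hill set
hills_grid <- function(bias) {
  g <- bias$params$grid
  ncv <- length(bias$params$cvs)
  cpp_hills_to_grid(
    as.matrix(bias$hills[, c("time", "c1", "c2", "sigma1", "sigma2",
                             "height", "walker")]),
    ncv,
    vapply(g, `[`, numeric(1), 1), vapply(g, `[`, numeric(1), 2),
    as.integer(vapply(g, `[`, numeric(1), 3))
  )
}

#' Reconstruct the free-energy surface from a bias state
#'
#' Well-tempered estimator: `F(s) = -(gamma_wt / (gamma_wt - 1)) V(s)`,
#' shifted so the global minimum is zero, evaluated on the bias grid.
#'
#' @param bias A `metad_bias` with at least one hill.
#' @param params [metad_params()] (defaults to those of `bias`).
#' @return A `fes` object: per-CV `axes`, matrix (or vector) `F`, and
#'   metadata (gamma_wt, hill count, walkers).
#' @export
reconstruct_fes <- function(bias, params = bias$params) {
  if (!nrow(bias$hills)) abort("empty bias: no hills deposited")
  grid <- hills_grid(bias)
  g <- params$grid
  ncv <- length(params$cvs)
  axes <- lapply(g, function(r) seq(r[1], r[2], length.out = r[3]))
  f <- -params$gamma_wt / (params$gamma_wt - 1) * grid$V
  if (ncv == 2) {
    f <- matrix(f, nrow = g[[1]][3], ncol = g[[2]][3], byrow = TRUE)
  }
  f <- f - min(f)
  structure(
    list(
      axes = setNames(axes, params$cvs), F = f,
      metadata = list(
        gamma_wt = params$gamma_wt, n_hills = nrow(bias$hills),
        n_walkers = length(unique(bias$hills$walker)),
        temperature = params$temperature
      )
    ),
    class = "fes"
  )
}

#' Project a 2D free-energy surface onto one CV
#'
#' Boltzmann-weighted marginalization:
#' `F1(x) = -kT log sum_y exp(-F(x, y) / kT)`, min-shifted.
#'
#' @param fes A 2D `fes`.
#' @param cv Name of the CV to keep.
#' @return A 1D `fes`.
#' @export
fes_project <- function(fes, cv) {
  if (!is.matrix(fes$F)) abort("fes_project expects a 2D surface")
  kT <- fes$metadata$temperature
  keep <- match(cv, names(fes$axes))
  if (is.na(keep)) abort(sprintf("unknown CV: %s", cv))
  f <- if (keep == 1) fes$F else t(fes$F)
  f1 <- -kT * log(rowSums(exp(-f / kT)))
  f1 <- f1 - min(f1)
  structure(
    list(axes = fes$axes[keep], F = f1, metadata = fes$metadata),
    class = "fes"
  )
}

fes_bins_in_region <- function(fes, region) {
  ncv <- length(fes$axes)
  sel <- lapply(seq_len(ncv), function(c) {
    r <- region[[names(fes$axes)[c]]] %||% region[[c]]
    if (is.null(r)) rep(TRUE, length(fes$axes[[c]]))
    else fes$axes[[c]] >= r[1] & fes$axes[[c]] <= r[2]
  })
  if (ncv == 1) {
    which(sel[[1]])
  } else {
    as.matrix(expand.grid(i = which(sel[[1]]), j = which(sel[[2]])))
  }
}

#' Barrier height between two basins on a free-energy surface
#'
#' Minimax-path (saddle-point) estimate: the minimum over grid paths of
#' the maximum F along the path from basin A to basin B, minus the
#' minimum F inside basin A. Found by a rising-threshold flood fill.
#'
#' @param fes A `fes` (1D or 2D).
#' @param basin_a,basin_b Named lists of per-CV ranges, e.g.
#'   `list(z = c(-8, -5))`; unnamed CVs span their full range.
#' @return Barrier height (reduced energy).
#' @export
barrier_height <- function(fes, basin_a, basin_b) {
  f <- fes$F
  if (is.matrix(f)) {
    dims <- dim(f)
    idx_a <- fes_bins_in_region(fes, basin_a)
    idx_b <- fes_bins_in_region(fes, basin_b)
    lin <- function(ij) (ij[, 2] - 1) * dims[1] + ij[, 1]
    a_lin <- lin(idx_a)
    b_lin <- lin(idx_b)
  } else {
    dims <- c(length(f), 1L)
    a_lin <- fes_bins_in_region(fes, basin_a)
    b_lin <- fes_bins_in_region(fes, basin_b)
  }
  for (nm in c("A", "B")) {
    lin_set <- if (nm == "A") a_lin else b_lin
    if (!length(lin_set) || all(!is.finite(f[lin_set]))) {
      abort(sprintf("unsampled region: basin %s contains no finite bins", nm))
    }
  }
  fa <- min(f[a_lin])
  # rising water: binary search on threshold over sorted unique F values
  vals <- sort(unique(as.numeric(f[is.finite(f)])))
  reachable <- function(thr) {
    open <- is.finite(f) & (f <= thr)
    if (!any(open[a_lin])) return(FALSE)
    visited <- rep(FALSE, length(f))
    queue <- a_lin[open[a_lin]]
    visited[queue] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      if (cur %in% b_lin) return(TRUE)
      i <- (cur - 1) %% dims[1] + 1
      j <- (cur - 1) %/% dims[1] + 1
      nb <- c(
        if (i > 1) cur - 1, if (i < dims[1]) cur + 1,
        if (j > 1) cur - dims[1], if (j < dims[2]) cur + dims[1]
      )
      nb <- nb[open[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    FALSE
  }
  lo <- 1L
  hi <- length(vals)
  if (!reachable(vals[hi])) abort("basins are not connected on the grid")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (reachable(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo] - fa
}

#' Multiwalker well-tempered metadynamics on a slab system
#'
#' Runs `n_walkers` replicas of the state (independent thermostat streams
#' derived from the seed), each depositing hills into a shared bias that
#' is merged every `sync_interval` steps and broadcast back.
#'
#' @param walkers A single `cg_state` (replicated) or list of walker
#'   states (e.g. frames with different solute depths).
#' @param metad [metad_params()]; `n_walkers` is taken from here when a
#'   single state is given.
#' @param integrator [integrator_params()]; `n_steps` is the per-walker
#'   total.
#' @param solute_id Solute to bias (default first solute).
#' @param leaflet Head-plane reference leaflet.
#' @return List: `bias` (merged `metad_bias`), `fes`, per-walker `cv`
#'   tibble, final `walkers` states.
#' @export
run_metadynamics <- function(walkers, metad, integrator, solute_id = NULL,
                             leaflet = "upper") {
  if (inherits(walkers, "cg_state")) {
    walkers <- rep(list(walkers), metad$n_walkers)
  }
  nw <- length(walkers)
  total <- integrator$n_steps
  per_round <- min(metad$sync_interval, total)
  n_rounds <- ceiling(total / per_round)
  all_hills <- list()
  grid0 <- NULL
  cv_all <- list()
  for (round in seq_len(n_rounds)) {
    new_hills <- list()
    for (w in seq_len(nw)) {
      p <- integrator
      p$n_steps <- min(per_round, total - (round - 1) * per_round)
      p$seed <- derive_seed(metad$seed, paste0("w", w, "r", round))
      ml <- metad_engine_list(metad, integrator$temperature, w, grid0)
      cv <- list(enabled = TRUE, solute_id = solute_id, leaflet = leaflet)
      cvs <- cv_spec_for(walkers[[w]], solute_id, leaflet)
      out <- run_engine(
        walkers[[w]], p, reporter_config(stride_cv = max(1L, metad$pace %/% 5L)),
        pull = NULL, metad = ml, cv = cvs
      )
      st <- walkers[[w]]
      st$positions <- out$positions
      st$velocities <- out$velocities
      st$time <- out$time
      walkers[[w]] <- st
      nh <- as_tibble(out$hills)
      if (nrow(nh)) new_hills[[length(new_hills) + 1L]] <- nh
      cvt <- finish_cv_series(as_tibble(out$cv))
      cvt$walker <- w
      cv_all[[length(cv_all) + 1L]] <- cvt
    }
    all_hills <- c(all_hills, new_hills)
    merged <- bias_state(bind_rows(all_hills), metad)
    grid0 <- hills_grid(merged)
  }
  bias <- bias_state(bind_rows(all_hills), metad)
  bias$hills <- bias$hills[order(bias$hills$time), ]
  list(
    bias = bias, fes = reconstruct_fes(bias),
    cv = bind_rows(cv_all), walkers = walkers
  )
}

#' Well-tempered metadynamics on an analytic double-well landscape
#'
#' Overdamped Langevin dynamics on
#' `U(x) = h ((x/a)^2 - 1)^2` (optionally plus an independent y term)
#' with on-the-fly well-tempered deposition; the oracle-scale route for
#' validating free-energy-surface recovery.
#'
#' @param potential `"double_well_1d"` or `"separable_2d"`.
#' @param h Barrier height(s) (reduced energy; length 1 or 2).
#' @param a Well position(s) (+/- a; length 1 or 2).
#' @param metad [metad_params()] with `cvs` of length 1 or 2; grids are
#'   interpreted as the sampling coordinates.
#' @param n_steps Number of overdamped steps.
#' @param dt Time step.
#' @param mobility_gamma Friction of the overdamped propagator.
#' @param x0 Start point.
#' @param seed Integer seed.
#' @param stride Trajectory recording stride.
#' @return List: `bias`, `fes`, `trajectory` tibble.
#' @export
run_toy_metadynamics <- function(potential = c("double_well_1d", "separable_2d"),
                                 h = 4, a = 1, metad = metad_params(
                                   cvs = "z", sigma = c(z = 0.1),
                                   grid = list(z = c(-2.5, 2.5, 201)), pace = 250
                                 ),
                                 n_steps = 2e5, dt = 5e-4, mobility_gamma = 1,
                                 x0 = -1, seed = 1, stride = 50) {
  potential <- match.arg(potential)
  dim <- if (potential == "double_well_1d") 1L else 2L
  h <- rep_len(h, dim)
  a <- rep_len(a, dim)
  x0 <- rep_len(x0, dim)
  g <- metad$grid
  out <- cpp_toy_metad(
    dim, h, a, x0, dt, metad$temperature, mobility_gamma, n_steps,
    derive_seed(seed, "toy"), as.integer(stride),
    TRUE, metad$omega0, unname(metad$sigma), metad$pace, metad$gamma_wt,
    vapply(g, `[`, numeric(1), 1), vapply(g, `[`, numeric(1), 2),
    as.integer(vapply(g, `[`, numeric(1), 3)), metad$wall_k
  )
  bias <- bias_state(as_tibble(out$hills), metad)
  traj <- as_tibble(out$trajectory, .name_repair = "minimal")
  names(traj) <- c("time", names(metad$grid))[seq_len(1 + dim)]
  list(bias = bias, fes = reconstruct_fes(bias), trajectory = traj)
}

#' Write / read a HILLS file (TSV, append-safe)
#'
#' @param bias A `metad_bias`.
#' @param path File path.
#' @param append Append to an existing HILLS file.
#' @return `path` (write); a `metad_bias` with default params (read).
#' @export
write_hills <- function(bias, path, append = FALSE) {
  readr::write_tsv(bias$hills, path, append = append)
  invisible(path)
}

#' @rdname write_hills
#' @param params Parameters to attach on read.
#' @export
read_hills <- function(path, params = metad_params()) {
  h <- readr::read_tsv(
    path,
    col_names = c("time", "c1", "c2", "sigma1", "sigma2", "height", "walker"),
    skip = 1, show_col_types = FALSE
  )
  bias_state(h, params)
}

#' Write a free-energy surface as a TSV grid dump
#'
#' Metadata header lines are prefixed `#`.
#'
#' @param fes A `fes`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- fes$metadata
  writeLines(sprintf(
    "# fes gamma_wt=%g n_hills=%d n_walkers=%d temperature=%g",
    md$gamma_wt, md$n_hills, md$n_walkers, md$temperature
  ), con)
  df <- tidy(fes)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
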