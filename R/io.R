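#' Write a trajectory as extended XYZ
#'
#' One block per frame: atom count, then a comment line of `key=value`
#' pairs (`box`, `time`, `energy`), then `type x y z` rows. This dialect
#' is what [read_trajectory()] expects back.
#'
#' @param frames List of N x 3 coordinate matrices.
#' @param path Output path.
#' @param types Character bead labels (recycled per frame).
#' @param times Numeric frame times.
#' @param box Length-3 box vector.
#' @param energies Optional per-frame energies.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, types, times, box,
                             energies = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    writeLines(as.character(nrow(fr)), con)
    e <- if (!is.null(energies)) sprintf(" energy=%.10g", energies[f]) else ""
    writeLines(sprintf(
      "box=%.10g,%.10g,%.10g time=%.10g%s", box[1], box[2], box[3],
      times[f], e
    ), con)
    if (nrow(fr)) {
      writeLines(sprintf(
        "%s %.9f %.9f %.9f", rep_len(types, nrow(fr)),
        fr[, 1], fr[, 2], fr[, 3]
      ), con)
    }
  }
  invisible(path)
}

#' Read an extended XYZ trajectory written by this package
#'
#' @param path File path.
#' @return List with `frames`, `times`, `box`, `types`, `energies`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- c()
  energies <- c()
  box <- NULL
  types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) abort(sprintf("parse error at line %d: expected atom count", i))
    if (i + 1L > length(lines)) {
      abort(sprintf("parse error at line %d: missing comment line", i + 1L))
    }
    comment <- lines[i + 1L]
    kv <- regmatches(comment, gregexpr("[a-z]+=[^ ]+", comment))[[1]]
    keys <- sub("=.*", "", kv)
    vals <- sub("^[a-z]+=", "", kv)
    if (!"box" %in% keys || !"time" %in% keys) {
      abort(sprintf(
        "unsupported-dialect: frame at line %d lacks box/time metadata", i
      ))
    }
    box <- as.numeric(strsplit(vals[keys == "box"], ",")[[1]])
    times <- c(times, as.numeric(vals[keys == "time"]))
    energies <- c(
      energies,
      if ("energy" %in% keys) as.numeric(vals[keys == "energy"]) else NA_real_
    )
    if (n > 0) {
      rows <- lines[i + 1L + seq_len(n)]
      if (length(rows) < n || anyNA(rows)) {
        abort(sprintf("parse error: truncated frame starting at line %d", i))
      }
      parts <- strsplit(trimws(rows), "[[:space:]]+")
      bad <- which(vapply(parts, length, integer(1)) != 4L)
      if (length(bad)) {
        abort(sprintf("parse error at line %d: expected 'type x y z'",
                      i + 1L + bad[1]))
      }
      types <- vapply(parts, `[`, character(1), 1)
      xyz <- matrix(
        as.numeric(unlist(lapply(parts, `[`, 2:4))),
        ncol = 3, byrow = TRUE
      )
    } else {
      xyz <- matrix(0, 0, 3)
      types <- character()
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(frames = frames, times = times, box = box, types = types,
       energies = energies)
}

#' Write / read a plain-text checkpoint
#'
#' Self-describing TSV container with positions, velocities, box, time and
#' seed; restart-safe and diffable.
#'
#' @param state A `cg_state`.
#' @param path File path.
#' @param seed Seed to record for the continuation stream.
#' @return `path` (write); a list with the stored arrays (read).
#' @export
write_checkpoint <- function(state, path, seed = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ldflex checkpoint v1",
    sprintf("# box\t%.12g\t%.12g\t%.12g", state$box[1], state$box[2], state$box[3]),
    sprintf("# time\t%.12g", state$time),
    sprintf("# pbc_z\t%d", as.integer(state$pbc_z)),
    sprintf("# seed\t%s", seed),
    sprintf("# n\t%d", nrow(state$positions)),
    "x\ty\tz\tvx\tvy\tvz"
  ), con)
  utils::write.table(
    cbind(state$positions, state$velocities), con,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path, n = 6)
  get1 <- function(tag) {
    l <- lines[startsWith(lines, paste0("# ", tag))]
    strsplit(l, "\t")[[1]][-1]
  }
  d <- utils::read.table(path, skip = 7, sep = "\t")
  list(
    positions = unname(as.matrix(d[, 1:3])),
    velocities = unname(as.matrix(d[, 4:6])),
    box = as.numeric(get1("box")), time = as.numeric(get1("time")),
    pbc_z = as.integer(get1("pbc_z")) == 1L,
    seed = suppressWarnings(as.integer(get1("seed")))
  )
}

#' Restore checkpointed coordinates into a state
#'
#' @param state A `cg_state` built with the same composition.
#' @param checkpoint A [read_checkpoint()] result.
#' @return The state with positions/velocities/time restored.
#' @export
apply_checkpoint <- function(state, checkpoint) {
  if (nrow(checkpoint$positions) != nrow(state$positions)) {
    abort("checkpoint size does not match the state")
  }
  state$positions <- checkpoint$positions
  state$velocities <- checkpoint$velocities
  state$time <- checkpoint$time
  state
}

#' Load a structured-text run configuration
#'
#' YAML with nested sections: `system` (box, counts, seed), `solute`
#' entries (class, n_beads, contour_length, placement), plus optional
#' module parameter blocks (`integrator`, `metad`, `pull`).
#'
#' @param path YAML file path.
#' @return A named list with a `cg_config` under `$config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sys <- y$system %||% list()
  solutes <- lapply(y$solute %||% list(), function(s) {
    solute_descriptor(
      flexibility = s$class %||% s$flexibility %||% "flexible",
      n_beads = s$n_beads %||% 8,
      contour_length = s$contour_length %||% 6.79,
      placement = s$placement %||% "cytosol"
    )
  })
  cfg <- system_config(
    n_phospholipid = sys$n_phospholipid %||% 64,
    n_tag = sys$n_tag %||% 140,
    n_solvent = sys$n_solvent %||% 0,
    solutes = solutes,
    seed = sys$seed %||% 1
  )
  c(list(config = cfg), y[setdiff(names(y), c("system", "solute"))])
}

#' Write a run manifest
#'
#' Self-describing JSON run record: config echo, seed, package version
#' and input checksums, sufficient to reproduce the run.
#'
#' @param dir Run directory.
#' @param config Configuration list (echoed verbatim).
#' @param seed Master seed.
#' @param inputs Character vector of input file paths to checksum.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sums <- vapply(inputs, function(p) {
    as.character(sum(utf8ToInt(paste(readLines(p, warn = FALSE), collapse = "\n"))))
  }, character(1))
  manifest <- list(
    package = "ldflex",
    version = as.character(utils::packageVersion("ldflex")),
    seed = seed, config = config,
    input_checksums = as.list(sums)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
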