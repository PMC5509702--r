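# Trajectory and topology file IO, structured configuration, run manifests.
#
# Canonical trajectory format is extended XYZ (human readable, carries
# velocities); LAMMPS-style dump text is supported for interoperability.
# Neither format carries bonds portably, so bond topology lives in a sidecar
# text file. Particle and bond indices are 0-based in all files (stated in
# each header) and 1-based in memory.

SPECIES_LABELS <- c("F", "P")   # fluid, polymer bead

# map a dim-d position/velocity matrix to 3 columns (2D: x, 0, z)
to3d <- function(m) {
  if (ncol(m) == 3L) return(m)
  cbind(m[, 1], 0, m[, 2])
}
from3d <- function(m, dim) {
  if (dim == 3L) m else m[, c(1, 3), drop = FALSE]
}

#' Write a trajectory (or single system) as extended XYZ
#'
#' One extended-XYZ block per frame: the comment line carries the box
#' lattice, property layout, frame time and dimensionality. 2D systems are
#' written with y = 0.
#'
#' @param traj a `"trajectory"` or a `"particle_system"` (written as one
#'   frame at time 0).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "particle_system"))
    traj <- structure(list(frames = list(list(step = 0L, time = 0.0,
                                              pos = traj$pos, vel = traj$vel)),
                           box = traj$box, dim = traj$dim,
                           species = traj$species, mass = traj$mass),
                      class = "trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  box3 <- if (traj$dim == 3L) traj$box else c(traj$box[1], 0, traj$box[2])
  lat <- sprintf("%g 0 0 0 %g 0 0 0 %g", box3[1], box3[2], box3[3])
  sp <- SPECIES_LABELS[traj$species]
  for (f in traj$frames) {
    writeLines(as.character(length(sp)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:velo:R:3 Time=%.10g dim=%d',
      lat, f$time, traj$dim), con)
    p3 <- to3d(f$pos); v3 <- to3d(f$vel)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                       sp, p3[, 1], p3[, 2], p3[, 3],
                       v3[, 1], v3[, 2], v3[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as LAMMPS-style dump text
#'
#' `ITEM: ATOMS id type x y z vx vy vz` layout with 0-based ids, periodic
#' (`pp`) lateral bounds and fixed (`ff`) shock-axis bounds.
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(traj, path) {
  if (inherits(traj, "particle_system"))
    traj <- structure(list(frames = list(list(step = 0L, time = 0.0,
                                              pos = traj$pos, vel = traj$vel)),
                           box = traj$box, dim = traj$dim,
                           species = traj$species, mass = traj$mass),
                      class = "trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$species)
  box3 <- if (traj$dim == 3L) traj$box else c(traj$box[1], 0, traj$box[2])
  for (f in traj$frames) {
    writeLines(c("ITEM: TIMESTEP", as.character(f$step),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp ff",
                 sprintf("0 %.10g", box3[1]),
                 sprintf("0 %.10g", box3[2]),
                 sprintf("0 %.10g", box3[3]),
                 "ITEM: ATOMS id type x y z vx vy vz"), con)
    p3 <- to3d(f$pos); v3 <- to3d(f$vel)
    writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g %.10g %.10g",
                       seq_len(n) - 1L, traj$species,
                       p3[, 1], p3[, 2], p3[, 3],
                       v3[, 1], v3[, 2], v3[, 3]), con)
  }
  invisible(path)
}

#' Open a trajectory file as a streaming frame iterator
#'
#' Detects extended XYZ vs LAMMPS dump from the first line (unless `format`
#' is given) and returns an iterator that yields one frame per call without
#' loading the whole file: `it$next_frame()` returns a list (`step`, `time`,
#' `pos`, `vel`, `species`) or `NULL` at end of file; `it$close()` releases
#' the connection. Dump frames are re-sorted by atom id so both formats
#' yield the same particle order. Frames without velocity columns are an
#' error (the downstream analysis requires velocities).
#'
#' @param path trajectory file.
#' @param format `"auto"`, `"xyz"` or `"dump"`.
#' @return an iterator object (environment) with `next_frame()` / `close()`.
#' @export
open_trajectory <- function(path, format = c("auto", "xyz", "dump")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "r")
  lineno <- 0L
  rl <- function(n = 1L) {
    x <- readLines(con, n = n)
    lineno <<- lineno + length(x)
    x
  }
  if (format == "auto") {
    first <- readLines(con, n = 1L)
    close(con)
    con <- file(path, "r")
    format <- if (length(first) && grepl("^ITEM: TIMESTEP", first)) "dump"
              else "xyz"
  }
  bad <- function(msg) stop(sprintf("malformed %s frame near line %d: %s",
                                    format, lineno, msg), call. = FALSE)
  next_xyz <- function() {
    hdr <- rl(1L)
    if (!length(hdr)) return(NULL)
    n <- suppressWarnings(as.integer(trimws(hdr)))
    if (is.na(n) || n < 0) bad("expected particle count")
    cmt <- rl(1L)
    if (!length(cmt)) bad("missing comment line")
    tm <- regmatches(cmt, regexpr("Time=[-0-9.eE+]+", cmt))
    tm <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA_real_
    dm <- regmatches(cmt, regexpr("dim=[23]", cmt))
    dm <- if (length(dm)) as.integer(sub("dim=", "", dm)) else 3L
    if (!grepl("velo", cmt))
      bad("no velocity columns declared (analysis requires velocities)")
    rows <- rl(n)
    if (length(rows) < n) bad("truncated frame body")
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) < 7L)) bad("expected species + 3 pos + 3 vel columns")
    sp <- vapply(parts, `[`, "", 1L)
    num <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:7))), n, 6, byrow = TRUE)
    if (any(!is.finite(num))) bad("non-numeric coordinate/velocity")
    list(step = NA_integer_, time = tm,
         pos = from3d(num[, 1:3, drop = FALSE], dm),
         vel = from3d(num[, 4:6, drop = FALSE], dm),
         species = match(sp, SPECIES_LABELS))
  }
  next_dump <- function() {
    hdr <- rl(1L)
    if (!length(hdr)) return(NULL)
    if (!grepl("^ITEM: TIMESTEP", hdr)) bad("expected ITEM: TIMESTEP")
    step <- as.integer(rl(1L))
    if (!grepl("^ITEM: NUMBER OF ATOMS", rl(1L))) bad("expected NUMBER OF ATOMS")
    n <- as.integer(rl(1L))
    if (is.na(n) || n < 0) bad("bad atom count")
    if (!grepl("^ITEM: BOX BOUNDS", rl(1L))) bad("expected BOX BOUNDS")
    rl(3L)
    atoms_hdr <- rl(1L)
    if (!grepl("^ITEM: ATOMS", atoms_hdr)) bad("expected ITEM: ATOMS")
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", atoms_hdr), "\\s+")[[1]]
    need <- c("id", "type", "x", "y", "z", "vx", "vy", "vz")
    if (!all(c("vx", "vy", "vz") %in% cols))
      bad("no velocity columns (analysis requires velocities)")
    if (!all(need %in% cols)) bad("missing required atom columns")
    rows <- rl(n)
    if (length(rows) < n) bad("truncated frame body")
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) < length(cols))) bad("short atom row")
    num <- matrix(as.numeric(unlist(parts)), n, length(cols), byrow = TRUE)
    if (any(!is.finite(num))) bad("non-numeric atom field")
    colnames(num) <- cols
    o <- order(num[, "id"])
    num <- num[o, , drop = FALSE]
    pos3 <- unname(num[, c("x", "y", "z"), drop = FALSE])
    dm <- if (all(pos3[, 2] == 0)) 2L else 3L
    list(step = step[1], time = NA_real_,
         pos = from3d(pos3, dm),
         vel = from3d(unname(num[, c("vx", "vy", "vz"), drop = FALSE]), dm),
         species = as.integer(num[, "type"]))
  }
  it <- new.env(parent = emptyenv())
  it$format <- format
  it$next_frame <- if (format == "xyz") next_xyz else next_dump
  it$close <- function() close(con)
  class(it) <- "trajectory_iterator"
  it
}

#' Read a whole trajectory file
#'
#' Convenience wrapper over [open_trajectory()] collecting all frames into a
#' `"trajectory"` object. A zero-frame file yields an empty trajectory.
#'
#' @inheritParams open_trajectory
#' @param box box edge lengths (extended XYZ carries them in the header; for
#'   dump files they are read from the bounds block of the first frame if
#'   omitted).
#' @return a `"trajectory"`.
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "dump"), box = NULL) {
  it <- open_trajectory(path, format)
  on.exit(it$close())
  frames <- list()
  species <- NULL
  repeat {
    f <- it$next_frame()
    if (is.null(f)) break
    species <- f$species
    frames[[length(frames) + 1L]] <- f[c("step", "time", "pos", "vel")]
  }
  if (is.null(box) && length(frames)) {
    # recover the box from the file header
    hdr <- readLines(path, n = 10L)
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    if (length(lat)) {
      v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat[[1]]),
                               "\\s+")[[1]])
      box3 <- v[c(1, 5, 9)]
    } else {
      bi <- grep("^ITEM: BOX BOUNDS", hdr)
      box3 <- if (length(bi)) vapply(hdr[bi[1] + 1:3],
                                     function(s) as.numeric(strsplit(s, "\\s+")[[1]][2]),
                                     0.0) else rep(NA_real_, 3)
    }
    dm <- ncol(frames[[1]]$pos)
    box <- if (dm == 3L) box3 else box3[c(1, 3)]
  }
  structure(list(frames = frames, box = box,
                 dim = if (length(frames)) ncol(frames[[1]]$pos) else NA_integer_,
                 species = species,
                 mass = if (length(frames)) rep(1.0, nrow(frames[[1]]$pos)) else numeric(0),
                 dt = NA_real_),
            class = "trajectory")
}

#' Write / read the bond-topology sidecar file
#'
#' Plain text, one bond per line: `i j r0 r_break` with 0-based particle
#' indices (stated in the header comment).
#'
#' @param sys a `"particle_system"`.
#' @param path sidecar file path.
#' @return `path` invisibly / a list with `bonds` (1-based), `r0`, `r_break`.
#' @export
write_bonds <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bond list: i j r0 r_break (0-based particle indices)", con)
  if (nrow(sys$bonds))
    writeLines(sprintf("%d %d %.10g %.10g",
                       sys$bonds[, 1] - 1L, sys$bonds[, 2] - 1L,
                       sys$bond_r0, sys$bond_rbreak), con)
  invisible(path)
}

#' @rdname write_bonds
#' @export
read_bonds <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(list(bonds = matrix(integer(0), 0, 2), r0 = numeric(0),
                r_break = numeric(0)))
  m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
              length(lines), 4, byrow = TRUE)
  list(bonds = cbind(as.integer(m[, 1]) + 1L, as.integer(m[, 2]) + 1L),
       r0 = m[, 3], r_break = m[, 4])
}

# ---- structured experiment configuration -----------------------------------

#' Default desk-scale experiment configuration
#'
#' The study grid: bubble diameters 0 (no bubble), 6, 10 and 14 reduced
#' units crossed with piston velocities 1.0, 1.5 and 2.0, three replicates
#' each (chain rotated by 90 degrees per replicate). Geometry, chain,
#' potential and run-length defaults are the package's standard desk-scale
#' conditions; see the methods vignette for the rationale behind each value.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    box = list(lengths = c(30, 60), density = 0.8, temperature = 1.0),
    grids = list(D = c(0, 8, 11, 14), v_p = c(1.5, 2.25, 3.0)),
    replicates = 3L,
    bubble = list(z_center_frac = 0.67),
    chain = list(n_beads = 12L, r0 = 1.0, k = 80, r_break_factor = 1.7,
                 d = 1.0, amplitude = 0.1, pitch = 4, mass = 3.0,
                 r_excl = 1.0),
    potential = list(sigma = 1.0, epsilon = 1.0, rcut = 2.5),
    run = list(dt = 0.001, equil_steps = 2000L, shock_steps = 5500L,
               stride = 50L, h = 2.0, min_bin_count = 3L),
    seed = 1L
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_known_keys(as.list(cfg[[k]]), ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(defaults, cfg) {
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], cfg[[k]])
    else defaults[[k]] <- cfg[[k]]
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON; JSON is a YAML dialect) configuration, rejects
#' unknown keys (no silent typos), fills defaults from [default_config()],
#' and cross-validates the resulting geometry (largest bubble must fit the
#' box, chain must fit the cross-section, and so on); violations are
#' aggregated into a single error report.
#'
#' @param path configuration file, or a named list already in memory.
#' @return validated full configuration list (class `"cavijet_config"`).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  ref <- default_config()
  check_known_keys(cfg, ref)
  full <- merge_config(ref, cfg)
  full$replicates <- as.integer(full$replicates)
  full$seed <- as.integer(full$seed)
  problems <- character(0)
  L <- full$box$lengths
  if (length(L) < 2 || any(L <= 0))
    problems <- c(problems, "box.lengths must be >= 2 positive values")
  Dmax <- max(full$grids$D)
  if (length(L) >= 2 && Dmax >= min(L[-length(L)]))
    problems <- c(problems,
                  sprintf("grids.D max (%g) does not fit the box cross-section (box.lengths %g)",
                          Dmax, min(L[-length(L)])))
  if (length(L) >= 2 && Dmax >= L[length(L)])
    problems <- c(problems, "grids.D max exceeds the box shock-axis length")
  if ((full$chain$n_beads - 1) * full$chain$r0 >= L[1])
    problems <- c(problems,
                  "chain length ((n_beads-1)*r0) does not fit box.lengths[1]")
  if (any(full$grids$v_p < 0)) problems <- c(problems, "grids.v_p must be >= 0")
  if (full$replicates < 1L) problems <- c(problems, "replicates must be >= 1")
  if (full$run$dt <= 0) problems <- c(problems, "run.dt must be > 0")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  class(full) <- c("cavijet_config", "list")
  full
}

#' Write a configuration back to YAML
#' @param config a configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- run manifests ---------------------------------------------------------

#' Write a run manifest
#'
#' JSON manifest holding all specs, seeds, the package version, an inventory
#' of output files with md5 checksums, and the run status.
#'
#' @param dir run directory (created if needed).
#' @param specs named list of specs/parameters to record.
#' @param files character vector of output file paths to checksum.
#' @param status `"completed"`, `"failed"` or `"partial"`.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, specs, files = character(0),
                           status = c("completed", "failed", "partial")) {
  status <- match.arg(status)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inv <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  man <- list(package_version = as.character(utils::packageVersion("cavijet")),
              status = status, specs = specs, files = inv)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
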