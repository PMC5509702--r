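# Experiment orchestration: a single shock scenario (equilibrate -> carve ->
# insert chain -> shock -> record), shock-front speed measurement, and the
# full (bubble diameter x piston velocity x replicate) grid.

#' Assemble the initial system for one scenario
#'
#' Builds the fluid at the configured density, equilibrates it with the
#' weak-coupling thermostat, carves the bubble void (diameter `D`; `D = 0`
#' means no bubble) centred laterally at the configured fraction of the
#' shock axis, and inserts the breakable chain a gap `d` below the bubble
#' surface with the replicate's rotation angle.
#'
#' @param config validated configuration (see [load_config()]).
#' @param D bubble diameter, reduced units.
#' @param replicate replicate index (1-based; sets rotation angle
#'   `90 * (replicate - 1)` degrees and the velocity seed).
#' @param seed seed for this run.
#' @return equilibrated, carved `"particle_system"` ready for the shock.
#' @export
prepare_scenario_system <- function(config, D, replicate = 1L, seed = config$seed) {
  L <- config$box$lengths
  dim <- length(L)
  box <- box_spec(L, config$box$density, config$box$temperature, seed = seed,
                  dim = dim)
  pot <- do.call(potential_spec, config$potential)
  sys <- build_fluid(box, vel_seed = seed + 101L * (replicate - 1L))
  sys <- equilibrate(sys, pot, config$box$temperature,
                     steps = config$run$equil_steps, dt = config$run$dt * 2)
  center <- L / 2
  center[dim] <- config$bubble$z_center_frac * L[dim]
  bub <- bubble_spec(center, D)
  sys <- carve_bubble(sys, bub)
  ch <- config$chain
  ch$angle <- 90 * (replicate - 1L)
  chain <- do.call(chain_spec, ch)
  sys <- insert_chain(sys, chain, bub,
                      vel_seed = seed + 101L * (replicate - 1L) + 7L)
  sys
}

#' Run one shock scenario
#'
#' Full pipeline for a single (D, v_p, replicate) cell: prepare the system,
#' launch the shock with the momentum mirror, integrate NVE, and analyse:
#' shock-front speed from the pre-bubble window, maximum-local-velocity jet
#' series, and the chain damage report. Deterministic under a fixed seed.
#'
#' @param config validated configuration.
#' @param D bubble diameter (reduced units; 0 = no bubble).
#' @param v_p piston velocity (reduced units).
#' @param replicate replicate index.
#' @param seed run seed (defaults to the configured seed policy
#'   `seed + 1000 * scenario_index + replicate`; pass explicitly to
#'   override).
#' @param keep_traj keep the trajectory in the returned record.
#' @return a run record: list with `spec`, `summary` (one-row data.frame),
#'   `events`, `energy`, `jet`, `hugoniot`, `damage`, `outcome`, and
#'   (optionally) `traj`.
#' @export
run_scenario <- function(config, D, v_p, replicate = 1L, seed = NULL,
                         keep_traj = TRUE) {
  config <- if (inherits(config, "cavijet_config")) config else load_config(config)
  if (is.null(seed)) {
    si <- scenario_index(config, D, v_p)
    seed <- config$seed + 1000L * si + as.integer(replicate)
  }
  dim <- length(config$box$lengths)
  sys <- prepare_scenario_system(config, D, replicate, seed)
  n_part <- nrow(sys$pos)
  pot <- do.call(potential_spec, config$potential)
  sys <- apply_momentum_mirror(sys, v_p)
  res <- run_dynamics(sys, pot, dt = config$run$dt,
                      steps = config$run$shock_steps,
                      stride = config$run$stride)
  traj <- res$traj
  # map engine bond ids onto chain bond indices (chain bonds are the only
  # bonds in the system, in order)
  ev <- res$events
  dmg <- damage_report(
    if (nrow(ev)) data.frame(bond = ev$bond, time = ev$step * config$run$dt)
    else ev,
    n_beads = config$chain$n_beads)
  out <- classify_outcome(dmg, traj)
  hug <- tryCatch(
    measure_shock_speed(traj, v_p = v_p,
                        window = prebubble_window(config, D), h = 1.0),
    error = function(e) NULL)
  bubble_top <- config$bubble$z_center_frac * config$box$lengths[dim] + D / 2
  jet <- max_local_velocity_series(traj, h = config$run$h,
                                   min_count = config$run$min_bin_count,
                                   zlim = c(config$bubble$z_center_frac *
                                              config$box$lengths[dim] -
                                              max(D, 4) / 2 - 5,
                                            bubble_top))
  # the collapse jet can only exist after the front reaches the bubble;
  # earlier series entries are ambient piston drift plus thermal noise
  t_collapse <- NA_real_
  if (!is.null(hug)) {
    t_arr <- front_arrival_time(hug, bubble_top)
    sel <- jet$series$time >= t_arr - 0.2
    if (any(sel & is.finite(jet$series$max_speed))) {
      sub <- jet$series[sel, ]
      ipk <- which.max(sub$max_speed)
      jet$peak <- sub$max_speed[ipk]
      jet$t_peak <- sub$time[ipk]
      jet$t_front_at_bubble <- t_arr
      # collapse completion = jet formation: first time the smoothed series
      # reaches 90% of its maximum (single-frame extremes of sparse fast
      # bins are measurement noise, and the post-jet plateau drags the raw
      # argmax late)
      sm <- as.numeric(stats::filter(sub$max_speed, rep(1 / 5, 5), sides = 2))
      if (any(is.finite(sm))) {
        m <- max(sm, na.rm = TRUE)
        t_collapse <- sub$time[which(is.finite(sm) & sm >= 0.9 * m)[1]]
        jet$t_collapse <- t_collapse
      }
    }
  }
  en <- res$energy
  drift <- max(abs(en$total - en$total[1])) / abs(en$total[1])
  chain_z <- config$bubble$z_center_frac * config$box$lengths[dim] -
    D / 2 - config$chain$d
  summary <- data.frame(
    D = D, v_p = v_p, replicate = as.integer(replicate), seed = seed,
    n_particles = n_part,
    v_s = if (is.null(hug)) NA_real_ else hug$v_s,
    peak_jet_speed = jet$peak, t_peak_jet = jet$t_peak,
    t_collapse = t_collapse,
    t_front_at_chain = if (is.null(hug)) NA_real_
                       else front_arrival_time(hug, chain_z),
    broken = dmg$broken, n_broken_bonds = length(dmg$broken_bonds),
    fragment_count = dmg$fragment_count,
    break_sites = paste(sprintf("%.3f", dmg$break_sites), collapse = ","),
    max_deflection = out$max_deflection,
    energy_drift = drift,
    outcome = out$outcome,
    stringsAsFactors = FALSE)
  rec <- list(spec = list(D = D, v_p = v_p, replicate = replicate, seed = seed,
                          config = unclass(config),
                          units = unclass(units_map(dim = dim))),
              summary = summary, events = res$events, energy = en,
              jet = jet, hugoniot = hug, damage = dmg, outcome = out,
              chain_z = chain_z)
  if (keep_traj) rec$traj <- traj
  rec
}

scenario_index <- function(config, D, v_p) {
  iD <- match(D, config$grids$D)
  iv <- match(v_p, config$grids$v_p)
  if (is.na(iD) || is.na(iv))
    return(0L)  # off-grid exploratory run
  as.integer((iD - 1L) * length(config$grids$v_p) + iv)
}

# pre-bubble fit window along the shock axis: between the bubble top (plus a
# margin) and just below the mirror wall
prebubble_window <- function(config, D) {
  L <- config$box$lengths
  Lz <- L[length(L)]
  zc <- config$bubble$z_center_frac * Lz
  c(zc + D / 2 + 2, Lz - 2)
}

#' Measure the shock-front speed from a trajectory
#'
#' Tracks the compression front per frame as the half-amplitude crossing of
#' the axial mean-velocity step (linear interpolation between slab centres):
#' in the mirror frame the unshocked fluid drifts at the piston velocity
#' while the shocked layer behind the front is brought to rest, so the
#' front is the half-drift crossing of the slab-averaged axial velocity.
#' At desk scale this step (amplitude v_p) stands far above slab noise,
#' whereas the density jump of these moderately strong shocks does not.
#' Tracking is sequential: points must advance monotonically toward -z
#' inside the window (normally the pre-bubble region) and tracking stops
#' once the front leaves it. A least-squares line through front position vs
#' time gives the lab-frame front speed; the reported `v_s` adds back the
#' piston drift, i.e. it is the front speed relative to the unshocked fluid
#' (the Hugoniot shock speed).
#'
#' @param traj a `"trajectory"` with at least 4 frames.
#' @param v_p piston velocity (ambient drift). If `NULL`, estimated from
#'   the mean axial velocity of the first frame's window region.
#' @param window `c(z_lo, z_hi)` fit window along the shock axis.
#' @param h slab thickness for the axial profiles.
#' @param min_step minimum detectable drift amplitude (default 0.2 reduced
#'   velocity units); below it there is no measurable front.
#' @return object of class `"hugoniot_result"`: `v_s`, `v_s_lab`, `v_p`,
#'   `front` data.frame (time, z), `fit_window`, `r_squared`.
#' @export
measure_shock_speed <- function(traj, v_p = NULL, window = NULL, h = 1.0,
                                min_step = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 4L) stop("need at least 4 frames", call. = FALSE)
  dim <- traj$dim
  Lz <- traj$box[dim]
  if (is.null(window)) window <- c(0, Lz)
  nslab <- as.integer(ceiling(Lz / h - 1e-9))
  zc <- (seq_len(nslab) - 0.5) * h
  vz_of <- function(f) {
    iz <- pmin(pmax(floor(f$pos[, dim] / h), 0), nslab - 1L) + 1L
    m <- if (length(traj$mass) == nrow(f$pos)) traj$mass
         else rep(1.0, nrow(f$pos))   # variable-count external trajectories
    num <- rowsum_vec(m * f$vel[, dim], iz, nslab)
    den <- rowsum_vec(m, iz, nslab)
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  lo <- max(1L, as.integer(floor(window[1] / h)) + 1L)
  hi <- nslab
  if (is.null(v_p)) {
    vz0 <- vz_of(traj$frames[[1]])
    v_p <- mean(vz0[lo:hi], na.rm = TRUE)
  }
  if (!is.finite(v_p) || v_p < min_step)
    stop("no detectable axial drift; no front to track", call. = FALSE)
  thr <- v_p / 2
  front <- data.frame(time = numeric(0), z = numeric(0))
  last_z <- Inf
  miss <- 0L
  for (f in traj$frames) {
    vz <- vz_of(f)
    ok <- FALSE
    z_front <- NA_real_
    # contiguous decelerated (post-shock) run attached to the mirror wall
    if (!is.na(vz[hi]) && vz[hi] <= thr) {
      j <- hi
      while (j > lo && !is.na(vz[j - 1L]) && vz[j - 1L] <= thr) j <- j - 1L
      if (j > lo && hi - j >= 1L && !is.na(vz[j - 1L])) {
        z_front <- zc[j - 1L] +
          (thr - vz[j - 1L]) / (vz[j] - vz[j - 1L]) * h
        ok <- z_front >= window[1] && z_front <= window[2] &&
          z_front <= last_z + h
      }
    }
    if (ok) {
      front <- rbind(front, data.frame(time = f$time, z = z_front))
      last_z <- z_front
      miss <- 0L
    } else if (nrow(front)) {
      miss <- miss + 1L
      if (miss >= 3L) break      # front has left the window
    }
  }
  if (nrow(front) < 4L)
    stop("no detectable velocity step in the fit window (no front)",
         call. = FALSE)
  fit <- stats::lm(z ~ time, data = front)
  slope <- unname(coef(fit)[2])
  if (slope >= 0)
    stop("front does not advance toward -z; no propagating shock front",
         call. = FALSE)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((front$z - mean(front$z))^2)
  structure(list(v_s = -slope + v_p, v_s_lab = -slope, v_p = v_p,
                 front = front, fit_window = window,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 intercept = unname(coef(fit)[1])),
            class = "hugoniot_result")
}

#' @export
print.hugoniot_result <- function(x, ...) {
  cat(sprintf("hugoniot_result: v_s = %.3f (lab %.3f, v_p = %.3f), R^2 = %.4f, %d front points\n",
              x$v_s, x$v_s_lab, x$v_p, x$r_squared, nrow(x$front)))
  invisible(x)
}

# time at which the fitted front line reaches a given z (extrapolated)
front_arrival_time <- function(hug, z) {
  (z - hug$intercept) / (-hug$v_s_lab)
}

#' Run the full scenario grid
#'
#' Executes every (bubble diameter) x (piston velocity) x replicate cell of
#' the configured grids and collects one summary row per run. With an
#' output directory the per-run summaries are written as JSON next to a
#' manifest; re-running with the same directory reuses completed runs
#' instead of recomputing them (resume safety), and individual run failures
#' are recorded while the rest of the grid continues.
#'
#' @param config a configuration list, file path, or `NULL` for
#'   [default_config()].
#' @param outdir optional output directory for resumable runs and the
#'   summary TSV.
#' @param replicates override the configured replicate count.
#' @param quiet suppress per-run progress messages.
#' @return data.frame with one row per run (class `"grid_summary"`).
#' @export
run_grid <- function(config = NULL, outdir = NULL, replicates = NULL,
                     quiet = FALSE) {
  config <- load_config(if (is.null(config)) list() else config)
  if (!is.null(replicates)) config$replicates <- as.integer(replicates)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (D in config$grids$D) for (v_p in config$grids$v_p)
    for (r in seq_len(config$replicates)) {
      tag <- sprintf("D%g_vp%g_rep%d", D, v_p, r)
      cache <- if (!is.null(outdir)) file.path(outdir, paste0(tag, ".json"))
      if (!is.null(outdir) && file.exists(cache)) {
        row <- as.data.frame(jsonlite::read_json(cache, simplifyVector = TRUE))
        rows[[tag]] <- row
        if (!quiet) message("reusing completed run ", tag)
        next
      }
      row <- tryCatch({
        rec <- run_scenario(config, D, v_p, r, keep_traj = FALSE)
        rec$summary
      }, error = function(e) {
        data.frame(D = D, v_p = v_p, replicate = r, seed = NA_integer_,
                   n_particles = NA_integer_, v_s = NA_real_,
                   peak_jet_speed = NA_real_, t_peak_jet = NA_real_,
                   t_front_at_chain = NA_real_, broken = NA,
                   n_broken_bonds = NA_integer_, fragment_count = NA_integer_,
                   break_sites = "", max_deflection = NA_real_,
                   energy_drift = NA_real_,
                   outcome = paste("failed:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      if (!quiet) message(sprintf("run %s: %s", tag, row$outcome))
      if (!is.null(outdir))
        jsonlite::write_json(row, cache, auto_unbox = TRUE, digits = NA)
      rows[[tag]] <- row
    }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(outdir)) {
    write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_manifest(outdir,
                   specs = list(config = unclass(config)),
                   files = file.path(outdir, c("summary.tsv")),
                   status = if (any(grepl("^failed", summary$outcome)))
                     "partial" else "completed")
  }
  class(summary) <- c("grid_summary", "data.frame")
  summary
}
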