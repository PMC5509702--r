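# Continuum-field post-processing: cubic-bin density/velocity fields,
# maximum-local-velocity (jet) time series, axial velocity profiles with
# cross-replicate standard deviations, and polymer damage reports.

# resolve a frame argument: either a list(pos, vel) or a trajectory index
as_frame <- function(frame) {
  if (is.list(frame) && !is.null(frame$pos)) return(frame)
  stop("frame must be a list with $pos (and $vel)", call. = FALSE)
}

#' Bin a particle frame into continuum fields
#'
#' Divides the box into cubic (square in 2D) bins of side `h`, half-open
#' `[i*h, (i+1)*h)` on each axis with particles exactly on the upper box
#' edge assigned to the last bin, and accumulates per-bin particle count,
#' mass density and mass-weighted mean velocity. Empty bins carry `NA`
#' velocity (flagged, not zero). When `h` does not divide a box edge the
#' last bin along that axis is truncated and the grid is flagged.
#'
#' @param frame list with `pos` (n x dim) and `vel` (n x dim).
#' @param box box edge lengths.
#' @param h bin side length (> 0); default 1 reduced unit, the analogue of
#'   the 1 nm bins used for the reference analysis.
#' @param mass particle masses (default unit).
#' @return object of class `"field_grid"`: list with `h`, `nbins`,
#'   `truncated`, per-bin `count`, `mass`, `density` (arrays of dim
#'   `nbins`), `velocity` (prod(nbins) x dim matrix, mass-weighted mean,
#'   `NA` where empty), `speed`, `temperature` (kinetic, about the bin mean
#'   velocity; `NA` under 2 particles) and `pressure_kin` (ideal-gas part,
#'   density times temperature, a diagnostic only) arrays, and
#'   `bin_centers` (list per axis).
#' @export
bin_fields <- function(frame, box, h = 1.0, mass = NULL) {
  frame <- as_frame(frame)
  pos <- frame$pos
  if (is.null(pos) || nrow(pos) == 0L) stop("empty frame", call. = FALSE)
  if (!is.finite(h) || h <= 0) stop("bin side h must be > 0", call. = FALSE)
  dim <- ncol(pos)
  if (length(box) != dim) stop("box/frame dimensionality mismatch", call. = FALSE)
  if (is.null(mass)) mass <- rep(1.0, nrow(pos))
  nbins <- as.integer(ceiling(box / h - 1e-9))
  truncated <- any(abs(box / h - round(box / h)) > 1e-9)
  idx <- matrix(0L, nrow(pos), dim)
  for (k in seq_len(dim)) {
    ik <- floor(pos[, k] / h)
    ik[ik >= nbins[k]] <- nbins[k] - 1L   # upper box edge -> last bin
    ik[ik < 0L] <- 0L
    idx[, k] <- as.integer(ik)
  }
  # linear bin index (first axis fastest)
  lin <- idx[, 1]
  mult <- 1L
  for (k in seq_len(dim)[-1]) {
    mult <- mult * nbins[k - 1]
    lin <- lin + idx[, k] * mult
  }
  lin <- lin + 1L
  ncell <- prod(nbins)
  cnt <- tabulate(lin, nbins = ncell)
  msum <- rowsum_vec(mass, lin, ncell)
  vsum <- matrix(0.0, ncell, dim)
  for (k in seq_len(dim)) vsum[, k] <- rowsum_vec(mass * frame$vel[, k], lin, ncell)
  velocity <- vsum / msum
  velocity[msum == 0, ] <- NA_real_
  # kinetic temperature about the bin mean velocity (diagnostic; the
  # pressure reported is its ideal-gas part, density * T -- configurational
  # virial contributions are not binned)
  ke2 <- rowsum_vec(mass * rowSums(frame$vel^2), lin, ncell)
  temperature <- (ke2 - msum * rowSums(velocity^2)) / (dim * pmax(cnt, 1L))
  temperature[cnt < 2L] <- NA_real_
  # bin volumes (truncated last bins have smaller volume)
  widths <- lapply(seq_len(dim), function(k) {
    w <- rep(h, nbins[k]); w[nbins[k]] <- box[k] - (nbins[k] - 1) * h; w
  })
  volgrid <- Reduce(function(a, b) outer(a, b), widths)
  density <- array(msum, nbins) / volgrid
  structure(list(h = h, nbins = nbins, dim = dim, box = box,
                 truncated = truncated,
                 count = array(cnt, nbins),
                 mass = array(msum, nbins),
                 density = density,
                 velocity = velocity,
                 speed = array(sqrt(rowSums(velocity^2)), nbins),
                 temperature = array(temperature, nbins),
                 pressure_kin = density * array(temperature, nbins),
                 bin_centers = lapply(seq_len(dim), function(k)
                   (seq_len(nbins[k]) - 0.5) * h),
                 time = frame$time %||% NA_real_),
            class = "field_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# grouped sum without factor overhead
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: h = %g, bins [%s]%s, %d occupied\n",
              x$h, paste(x$nbins, collapse = " x "),
              if (x$truncated) " (last bin truncated)" else "",
              sum(x$count > 0)))
  invisible(x)
}

#' Maximum local velocity time series (jet report)
#'
#' For every frame of a trajectory, bins the particles and takes the
#' maximum over bins of the magnitude of the mass-weighted mean velocity,
#' ignoring bins holding fewer than `min_count` particles (sparse bins give
#' single-particle spikes that space-averaging is meant to suppress). The
#' collapse jet appears as a rise to a peak when the collapsing walls meet,
#' then a decay once the jet disperses.
#'
#' @param traj a `"trajectory"`.
#' @param h bin side.
#' @param min_count minimum bin occupancy for velocity statistics (default 3).
#' @param zlim optional `c(z_lo, z_hi)` restriction on bin centres along the
#'   shock axis (e.g. the bubble/chain region, excluding the wall stagnation
#'   layer and the far end of the tube).
#' @return object of class `"jet_report"`: `series` data.frame (time,
#'   max_speed), `peak` (value), `t_peak`, `direction` (unit vector of the
#'   peak bin's mean velocity), `t_half_decay` (first time after the peak at
#'   which the series falls below half the peak; `NA` if it never does).
#' @export
max_local_velocity_series <- function(traj, h = 1.0, min_count = 3L,
                                      zlim = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  times <- vapply(traj$frames, function(f) f$time, 0.0)
  maxv <- numeric(length(traj$frames))
  peak_dir <- NULL
  any_occupied <- FALSE
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    fg <- bin_fields(list(pos = f$pos, vel = f$vel), traj$box, h,
                     mass = traj$mass)
    ok <- as.vector(fg$count) >= min_count
    if (!is.null(zlim)) {
      zcent <- rep(fg$bin_centers[[traj$dim]],
                   each = prod(fg$nbins[-traj$dim]))
      ok <- ok & zcent >= zlim[1] & zcent <= zlim[2]
    }
    if (!any(ok)) { maxv[i] <- NA_real_; next }
    any_occupied <- TRUE
    sp <- sqrt(rowSums(fg$velocity^2))
    sp[!ok] <- -Inf
    j <- which.max(sp)
    maxv[i] <- sp[j]
    prior <- maxv[seq_len(i - 1L)]
    if (i == 1L || all(is.na(prior)) || maxv[i] >= max(prior, na.rm = TRUE))
      peak_dir <- fg$velocity[j, ] / sqrt(sum(fg$velocity[j, ]^2))
  }
  if (!any_occupied)
    stop("all bins under-occupied at every frame; lower min_count or raise h",
         call. = FALSE)
  ipk <- which.max(maxv)
  peak <- maxv[ipk]
  after <- which(seq_along(maxv) > ipk & maxv <= peak / 2)
  if (peak == 0) peak_dir <- rep(NA_real_, traj$dim)
  structure(list(series = data.frame(time = times, max_speed = maxv),
                 peak = peak, t_peak = times[ipk],
                 direction = peak_dir,
                 t_half_decay = if (length(after)) times[min(after)] else NA_real_),
            class = "jet_report")
}

#' @export
print.jet_report <- function(x, ...) {
  cat(sprintf("jet_report: peak local speed %.3f at t = %.3f (half-decay t = %s)\n",
              x$peak, x$t_peak,
              if (is.na(x$t_half_decay)) "never" else sprintf("%.3f", x$t_half_decay)))
  invisible(x)
}

#' Axial velocity profile with cross-replicate statistics
#'
#' Extracts the local speed along the chain axis (the row of bins at the
#' chain's z position) at requested times from each replicate trajectory,
#' and reports the cross-replicate mean and standard deviation per position,
#' the error bars of the reference analysis.
#'
#' @param trajs list of replicate `"trajectory"` objects sharing box and
#'   sampling times.
#' @param chain_z z coordinate of the chain axis (used to pick the bin row).
#' @param times times at which to extract profiles; must exist (within half
#'   a frame interval) in every replicate.
#' @param h bin side.
#' @return object of class `"axial_profile"`: data.frame `profile` with
#'   columns time, position, mean_speed, sd_speed, n_rep, plus the
#'   per-replicate array.
#' @export
axial_velocity_profile <- function(trajs, chain_z, times, h = 1.0) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  box <- trajs[[1]]$box
  nx <- as.integer(ceiling(box[1] / h - 1e-9))
  out <- list()
  per_rep <- array(NA_real_, c(length(times), nx, length(trajs)))
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    ft <- vapply(tr$frames, function(f) f$time, 0.0)
    for (ti in seq_along(times)) {
      j <- which.min(abs(ft - times[ti]))
      if (abs(ft[j] - times[ti]) > 1e-6 + 1e-9 * abs(times[ti]))
        stop(sprintf("replicate %d has no frame at time %g (nearest %g)",
                     r, times[ti], ft[j]), call. = FALSE)
      f <- tr$frames[[j]]
      fg <- bin_fields(list(pos = f$pos, vel = f$vel), box, h, mass = tr$mass)
      zbin <- min(max(floor(chain_z / h), 0), fg$nbins[tr$dim] - 1L) + 1L
      sp <- array(sqrt(rowSums(fg$velocity^2)), fg$nbins)
      per_rep[ti, , r] <- if (tr$dim == 2L) sp[, zbin] else {
        ybin <- min(max(floor(box[2] / 2 / h), 0), fg$nbins[2] - 1L) + 1L
        sp[, ybin, zbin]
      }
    }
  }
  mean_sp <- apply(per_rep, c(1, 2), function(v) mean(v, na.rm = TRUE))
  sd_sp <- if (length(trajs) > 1L)
    apply(per_rep, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  else matrix(0.0, length(times), nx)
  sd_sp[is.na(sd_sp)] <- 0
  prof <- data.frame(
    time = rep(times, each = nx),
    position = rep((seq_len(nx) - 0.5) * h, length(times)),
    mean_speed = as.vector(t(mean_sp)),
    sd_speed = as.vector(t(sd_sp)),
    n_rep = length(trajs))
  structure(list(profile = prof, per_replicate = per_rep, h = h,
                 chain_z = chain_z, times = times),
            class = "axial_profile")
}

#' Polymer damage report
#'
#' Maps rupture events onto the chain topology: which bonds broke and when,
#' the fragments of the residual bond graph (connected components found by
#' breadth-first traversal), and the break sites as normalized positions
#' along the chain (0 = first bead end, 1 = last bead end).
#'
#' @param events data.frame of break events with a `bond` column (chain bond
#'   index, 1-based: bond `b` joins beads `b` and `b+1`); an optional `step`
#'   or `time` column is carried through as the break time.
#' @param n_beads number of beads in the chain.
#' @return object of class `"damage_report"`: `broken` flag, `broken_bonds`,
#'   `break_times`, `break_sites` (normalized), `fragment_count`,
#'   `fragments` (list of bead-index vectors).
#' @export
damage_report <- function(events, n_beads) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2L)
  n_bonds <- n_beads - 1L
  broken <- integer(0)
  btime <- numeric(0)
  if (!is.null(events) && nrow(events)) {
    if (is.null(events$bond)) stop("events need a 'bond' column", call. = FALSE)
    if (any(events$bond < 1L | events$bond > n_bonds))
      stop("events reference unknown bonds (outside 1..n_bonds)", call. = FALSE)
    broken <- as.integer(events$bond)
    btime <- if (!is.null(events$time)) as.numeric(events$time)
             else if (!is.null(events$step)) as.numeric(events$step)
             else rep(NA_real_, length(broken))
    o <- order(btime, broken)
    broken <- broken[o]; btime <- btime[o]
  }
  # residual bond graph -> connected components by breadth-first traversal
  intact <- setdiff(seq_len(n_bonds), broken)
  adj <- vector("list", n_beads)
  for (b in intact) {
    adj[[b]] <- c(adj[[b]], b + 1L)
    adj[[b + 1L]] <- c(adj[[b + 1L]], b)
  }
  seen <- logical(n_beads)
  fragments <- list()
  for (s in seq_len(n_beads)) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    fragments[[length(fragments) + 1L]] <- sort(comp)
  }
  structure(list(broken = length(broken) > 0L,
                 broken_bonds = broken,
                 break_times = btime,
                 break_sites = (broken - 0.5) / n_bonds,
                 fragment_count = length(fragments),
                 fragments = fragments,
                 n_beads = n_beads),
            class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  if (x$broken)
    cat(sprintf("damage_report: RUPTURED, %d broken bond(s) at site(s) %s, %d fragments\n",
                length(x$broken_bonds),
                paste(sprintf("%.2f", x$break_sites), collapse = ", "),
                x$fragment_count))
  else cat("damage_report: intact (1 fragment)\n")
  invisible(x)
}

#' Classify the run outcome: ruptured vs deformed-intact
#'
#' A chain with any broken bond is `"ruptured"`; an intact chain is
#' `"deformed-intact"`, with the maximum transverse deflection of the chain
#' along the shock axis reported (max over frames of the largest bead
#' z-excursion from the chain's instantaneous mean z).
#'
#' @param report a [damage_report()].
#' @param traj the run `"trajectory"` (polymer beads identified by species).
#' @return list with `outcome` (`"ruptured"` or `"deformed-intact"`) and
#'   `max_deflection`.
#' @export
classify_outcome <- function(report, traj = NULL) {
  stopifnot(inherits(report, "damage_report"))
  defl <- NA_real_
  if (!is.null(traj)) {
    beads <- which(traj$species == 2L)
    if (length(beads)) {
      zax <- traj$dim
      defl <- max(vapply(traj$frames, function(f) {
        z <- f$pos[beads, zax]
        max(abs(z - mean(z)))
      }, 0.0))
    }
  }
  list(outcome = if (report$broken) "ruptured" else "deformed-intact",
       max_deflection = defl)
}
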