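# Velocity-Verlet NVE engine wrappers around the compiled core: pair/bond
# forces, integration with breakable bonds, equilibration thermostat, and
# the momentum-mirror shock launcher.

#' Pair-potential specification
#'
#' Truncated-and-shifted 12-6 (Lennard-Jones) pair potential applied to all
#' non-bonded pairs (fluid-fluid, fluid-bead, bead-bead); directly bonded
#' bead pairs are permanently excluded from the pair interaction, their
#' cohesion coming from the harmonic bond alone.
#'
#' @param sigma pair length scale (reduced units).
#' @param epsilon pair well depth.
#' @param rcut cutoff radius (must be >= sigma); the potential is shifted to
#'   zero at the cutoff.
#' @return object of class `"potential_spec"`.
#' @export
potential_spec <- function(sigma = 1.0, epsilon = 1.0, rcut = 2.5) {
  if (sigma <= 0 || epsilon <= 0) stop("sigma and epsilon must be positive", call. = FALSE)
  if (rcut < sigma) stop("cutoff must be >= sigma", call. = FALSE)
  structure(list(sigma = sigma, epsilon = epsilon, rcut = rcut),
            class = "potential_spec")
}

#' Compute forces and potential energy
#'
#' Evaluates pair forces (cell-list accelerated by default) plus harmonic
#' bond forces. The `"brute"` method is an independent all-pairs evaluation
#' kept as a cross-check oracle for the cell-list path.
#'
#' @param sys a `"particle_system"`.
#' @param pot a [potential_spec()].
#' @param method `"cell"` (default) or `"brute"`.
#' @return list with `forces` (n x dim matrix) and `pe` (potential energy).
#' @export
compute_forces <- function(sys, pot, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(sys, "particle_system"), inherits(pot, "potential_spec"))
  cpp_forces(sys$pos, sys$box, pot$sigma, pot$epsilon, pot$rcut,
             sys$bonds, as.numeric(sys$bond_r0), as.numeric(sys$bond_k),
             sys$bond_alive, method = if (method == "cell") 1L else 0L)
}

#' Advance the system by NVE (or thermostatted) dynamics
#'
#' Velocity-Verlet integration with periodic lateral boundaries, elastic
#' reflective walls at both ends of the shock axis, and an irreversible
#' bond-break check after every step (every bond stretched beyond its break
#' extension is removed; the elastic energy it held at the break instant is
#' accounted in an energy sink so that total energy bookkeeping remains
#' closed). With `thermo_T > 0` a weak-coupling velocity-rescale thermostat
#' with coupling time `thermo_tau` acts every step; with `thermo_T = NULL`
#' the run is strictly NVE.
#'
#' @param sys a `"particle_system"`.
#' @param pot a [potential_spec()].
#' @param dt timestep, reduced time units.
#' @param steps number of steps (> 0).
#' @param stride frame-recording stride (`0` records only bounding frames,
#'   `NA`/negative disables frames).
#' @param thermo_T thermostat target temperature or `NULL` for NVE.
#' @param thermo_tau thermostat coupling time.
#' @param energy_stride energy-bookkeeping stride.
#' @return list with updated `sys`, `traj` (class `"trajectory"`), `events`
#'   (data.frame: step, bond, bead_i, bead_j) and `energy` (data.frame:
#'   step, ke, pe, sink, total).
#' @export
run_dynamics <- function(sys, pot, dt, steps, stride = 50L,
                         thermo_T = NULL, thermo_tau = 0.5,
                         energy_stride = 25L) {
  stopifnot(inherits(sys, "particle_system"), inherits(pot, "potential_spec"))
  if (!is.finite(dt) || dt <= 0) stop("timestep must be positive", call. = FALSE)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  record <- !is.na(stride) && stride >= 0
  res <- cpp_run_md(sys$pos, sys$vel, sys$mass, sys$box,
                    pot$sigma, pot$epsilon, pot$rcut,
                    sys$bonds, as.numeric(sys$bond_r0),
                    as.numeric(sys$bond_k), as.numeric(sys$bond_rbreak),
                    sys$bond_alive,
                    dt, as.integer(steps),
                    as.integer(if (record && stride > 0) stride else steps + 1L),
                    if (is.null(thermo_T)) -1.0 else thermo_T, thermo_tau,
                    as.integer(energy_stride), record)
  sys$pos <- res$pos
  sys$vel <- res$vel
  sys$bond_alive <- as.logical(res$bond_alive)
  ev <- as.data.frame(res$events)
  if (nrow(ev)) {
    ev$bead_i <- sys$bonds[ev$bond, 1]
    ev$bead_j <- sys$bonds[ev$bond, 2]
  } else {
    ev$bead_i <- integer(0); ev$bead_j <- integer(0)
  }
  en <- as.data.frame(res$energy)
  en$total <- en$ke + en$pe + en$sink
  traj <- structure(list(frames = res$frames, box = sys$box, dim = sys$dim,
                         species = sys$species, mass = sys$mass, dt = dt),
                    class = "trajectory")
  list(sys = sys, traj = traj, events = ev, energy = en)
}

#' Single NVE step
#'
#' Convenience wrapper: one velocity-Verlet step of [run_dynamics()].
#' @inheritParams run_dynamics
#' @return as [run_dynamics()].
#' @export
step_nve <- function(sys, pot, dt) run_dynamics(sys, pot, dt, steps = 1L, stride = 0L)

#' Equilibrate to a target temperature
#'
#' Runs thermostatted dynamics (weak-coupling velocity rescale) and checks
#' that the mean instantaneous temperature over the last 10% of steps is
#' within 5% of the target; a miss produces a warning carrying the final
#' temperature, not an error.
#'
#' @inheritParams run_dynamics
#' @param T_target target reduced temperature (> 0).
#' @param steps thermostatted steps.
#' @param tau coupling time.
#' @return the equilibrated `"particle_system"` with
#'   `meta$equilibration` holding the temperature trace summary.
#' @export
equilibrate <- function(sys, pot, T_target, steps, dt = 0.002, tau = 0.2) {
  if (!is.finite(T_target) || T_target <= 0) stop("T_target must be > 0", call. = FALSE)
  if (steps <= 0) stop("steps must be > 0", call. = FALSE)
  res <- run_dynamics(sys, pot, dt, steps, stride = NA,
                      thermo_T = T_target, thermo_tau = tau,
                      energy_stride = max(1L, as.integer(steps %/% 100)))
  en <- res$energy
  dof <- sys$dim * nrow(sys$pos)
  temps <- 2 * en$ke / dof
  lastw <- temps[en$step >= 0.9 * steps]
  T_final <- mean(lastw)
  if (abs(T_final - T_target) > 0.05 * T_target)
    warning(sprintf("equilibration missed target: final T = %.4f vs target %.4f",
                    T_final, T_target), call. = FALSE)
  out <- res$sys
  out$meta$equilibration <- list(T_target = T_target, T_final = T_final,
                                 steps = steps, dt = dt, tau = tau,
                                 temperature_trace = data.frame(step = en$step,
                                                                T = temps))
  out
}

#' Launch a shock with the momentum mirror
#'
#' Adds a uniform piston velocity `v_p` to every particle along the shock
#' axis, directed toward the fixed reflective wall at the far (+z) end of
#' the box. The wall reflection then piles up a compressed layer whose front
#' travels back through the fluid (in the -z direction), i.e. the shock
#' propagates from the +z side toward the -z side where the bubble and the
#' polymer sit. This is the reflective-boundary (momentum-mirror) shock
#' generation method: `v_p` is the post-shock particle velocity.
#'
#' @param sys a `"particle_system"`.
#' @param v_p piston velocity, reduced units (>= 0).
#' @return the system with shifted velocities; `meta$shock` records `v_p`.
#' @export
apply_momentum_mirror <- function(sys, v_p) {
  stopifnot(inherits(sys, "particle_system"))
  if (!is.finite(v_p) || v_p < 0)
    stop("piston velocity v_p must be >= 0", call. = FALSE)
  sys$vel[, sys$dim] <- sys$vel[, sys$dim] + v_p
  sys$meta$shock <- list(v_p = v_p, axis = sys$dim, direction = -1)
  sys
}

#' Check bonds for rupture
#'
#' Applies the irreversible break rule outside the integrator: every intact
#' bond whose current length exceeds its break extension is removed.
#'
#' @param sys a `"particle_system"`.
#' @return list with updated `sys` and `events` data.frame
#'   (bond, bead_i, bead_j, length).
#' @export
check_bonds <- function(sys) {
  stopifnot(inherits(sys, "particle_system"))
  if (!nrow(sys$bonds))
    return(list(sys = sys, events = data.frame(bond = integer(0),
                                               bead_i = integer(0),
                                               bead_j = integer(0),
                                               length = numeric(0))))
  dvec <- sys$pos[sys$bonds[, 1], , drop = FALSE] -
    sys$pos[sys$bonds[, 2], , drop = FALSE]
  # minimum image on periodic (non-last) axes
  for (k in seq_len(sys$dim - 1L)) {
    L <- sys$box[k]
    dvec[, k] <- dvec[, k] - L * round(dvec[, k] / L)
  }
  len <- sqrt(rowSums(dvec^2))
  breaking <- which(sys$bond_alive & len > sys$bond_rbreak)
  sys$bond_alive[breaking] <- FALSE
  list(sys = sys,
       events = data.frame(bond = breaking,
                           bead_i = sys$bonds[breaking, 1],
                           bead_j = sys$bonds[breaking, 2],
                           length = len[breaking]))
}

#' Instantaneous reduced temperature
#' @param sys a `"particle_system"`.
#' @return kinetic temperature 2*KE/(dim*N).
#' @export
temperature <- function(sys) {
  2 * sum(0.5 * sys$mass * rowSums(sys$vel^2)) / (sys$dim * nrow(sys$pos))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d particles, %dD box [%s]\n",
              length(x$frames), length(x$species), x$dim,
              paste(signif(x$box, 4), collapse = " x ")))
  invisible(x)
}
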