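# Synthetic system construction: dense fluid slab, carved bubble void,
# breakable bead-spring polymer, seeded replicate builds.
#
# Conventions: reduced Lennard-Jones units throughout; the shock axis is the
# LAST coordinate (called z), reflective at both ends; all other axes are
# periodic. The box spans [0, L_k) on each axis.

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation box specification
#'
#' @param lengths edge lengths per axis, reduced units; the last axis is the
#'   shock axis and must be the longest (ties allowed).
#' @param density target number density (particles per reduced area/volume).
#' @param temperature target reduced temperature for generated velocities.
#' @param seed integer seed controlling lattice site selection and jitter.
#' @param dim dimensionality, 2 or 3 (inferred from `lengths` if omitted).
#' @return object of class `"box_spec"`.
#' @export
box_spec <- function(lengths, density, temperature = 1.0, seed = 1L,
                     dim = length(lengths)) {
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3", call. = FALSE)
  if (length(lengths) != dim || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be ", dim, " positive finite edge lengths", call. = FALSE)
  if (max(lengths[-dim]) > lengths[dim])
    stop("the shock axis (last) must be the longest box axis", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  # hard cap: lattice spacing below ~0.8 sigma means badly overlapping sites
  if (density^(-1 / dim) < 0.8)
    stop("density too high: lattice spacing below 0.8 sigma", call. = FALSE)
  if (!is.finite(temperature) || temperature < 0)
    stop("temperature must be >= 0", call. = FALSE)
  structure(list(lengths = as.numeric(lengths), density = density,
                 temperature = temperature, seed = as.integer(seed),
                 dim = dim),
            class = "box_spec")
}

#' Bubble (void) specification
#'
#' @param center void centre coordinates (length = box dim).
#' @param D void diameter in reduced units; `D = 0` means no bubble.
#' @return object of class `"bubble_spec"`.
#' @export
bubble_spec <- function(center, D) {
  if (!is.finite(D) || D < 0) stop("bubble D must be >= 0", call. = FALSE)
  if (any(!is.finite(center))) stop("bubble center must be finite", call. = FALSE)
  structure(list(center = as.numeric(center), D = D), class = "bubble_spec")
}

#' Breakable bead-spring chain specification
#'
#' The chain is a coarse-grained stand-in for a hyaluronan filament: a linear
#' chain of beads joined by harmonic bonds that rupture irreversibly beyond a
#' critical extension. Because a perfectly straight chain is invariant under
#' rotation about its own axis, the beads carry a shallow helical transverse
#' offset (amplitude `amplitude`, period `pitch` beads); the replicate
#' rotation angle is the phase of that helix, so 0/90/180 degree builds
#' differ geometrically and a 360 degree rotation reproduces the 0 degree
#' build exactly.
#'
#' @param n_beads number of beads (>= 2); default 12, mirroring the 12-fold
#'   filament of the reference system.
#' @param r0 axial bead spacing, reduced units (per-bond rest lengths are set
#'   to the as-built bead separations so the chain starts relaxed).
#' @param k harmonic bond stiffness (reduced energy / length^2).
#' @param r_break_factor bonds rupture when stretched beyond
#'   `r_break_factor` times their rest length (must exceed 1).
#' @param d gap from the bubble surface to the chain axis, reduced units.
#' @param angle rotation about the chain axis, degrees.
#' @param amplitude,pitch helical offset amplitude (reduced units) and period
#'   (beads).
#' @param mass bead mass.
#' @param r_excl fluid exclusion radius around the chain axis capsule
#'   (amplitude is added internally).
#' @return object of class `"chain_spec"`.
#' @export
chain_spec <- function(n_beads = 12L, r0 = 1.0, k = 80, r_break_factor = 1.7,
                       d = 1.0, angle = 0, amplitude = 0.1, pitch = 4,
                       mass = 3.0, r_excl = 1.0) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 2L) stop("chain needs at least 2 beads", call. = FALSE)
  if (r0 <= 0 || k <= 0 || mass <= 0 || r_excl <= 0 || amplitude < 0 ||
      pitch <= 0)
    stop("chain geometry/stiffness parameters must be positive", call. = FALSE)
  if (r_break_factor <= 1)
    stop("r_break_factor must exceed 1 (break extension > rest length)",
         call. = FALSE)
  if (d < 0) stop("gap d must be >= 0", call. = FALSE)
  structure(list(n_beads = n_beads, r0 = r0, k = k,
                 r_break_factor = r_break_factor, d = d, angle = angle,
                 amplitude = amplitude, pitch = pitch, mass = mass,
                 r_excl = r_excl),
            class = "chain_spec")
}

new_particle_system <- function(pos, vel, mass, species, box, dim,
                                bonds = matrix(integer(0), 0, 2),
                                bond_r0 = numeric(0),
                                bond_k = numeric(0),
                                bond_rbreak = numeric(0),
                                meta = list()) {
  stopifnot(nrow(pos) == nrow(vel), nrow(pos) == length(mass),
            nrow(pos) == length(species), ncol(pos) == dim)
  structure(list(pos = pos, vel = vel, mass = mass,
                 species = as.integer(species), box = box, dim = as.integer(dim),
                 bonds = bonds, bond_r0 = bond_r0, bond_k = bond_k,
                 bond_rbreak = bond_rbreak,
                 bond_alive = rep(TRUE, nrow(bonds)),
                 meta = meta),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d particles (%d fluid, %d polymer), %dD box [%s]\n",
              nrow(x$pos), sum(x$species == 1L), sum(x$species == 2L),
              x$dim, paste(signif(x$box, 4), collapse = " x ")))
  nb <- nrow(x$bonds)
  if (nb) cat(sprintf("  bonds: %d (%d intact)\n", nb, sum(x$bond_alive)))
  invisible(x)
}

# species codes
SPECIES_FLUID   <- 1L
SPECIES_POLYMER <- 2L

#' Build an equilibratable dense fluid slab
#'
#' Particles are placed on a jittered simple lattice at the requested number
#' density (the particle count is `round(density * volume)` exactly; surplus
#' lattice sites are dropped at random under the position seed). Velocities
#' are Maxwell-Boltzmann at the target temperature, shifted to zero net
#' momentum and rescaled to the exact target temperature.
#'
#' @param box a [box_spec()].
#' @param vel_seed seed for the velocity draw (defaults to the box seed);
#'   replicate builds share positions but differ in velocity seed.
#' @return a `"particle_system"` of fluid particles (unit mass).
#' @export
build_fluid <- function(box, vel_seed = box$seed) {
  stopifnot(inherits(box, "box_spec"))
  dim <- box$dim; L <- box$lengths
  vol <- prod(L)
  n_target <- round(box$density * vol)
  if (n_target < 1) stop("box too small: zero particles at this density", call. = FALSE)
  s <- box$density^(-1 / dim)                 # ideal lattice spacing
  m <- pmax(1L, ceiling(L / s))               # sites per axis (spacing <= s)
  spacing <- L / m
  axes <- lapply(seq_len(dim), function(k) (seq_len(m[k]) - 0.5) * spacing[k])
  sites <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(sites) <- NULL
  n_sites <- nrow(sites)
  if (n_sites < n_target)
    stop("internal lattice under-fill", call. = FALSE)  # cannot happen: spacing <= s
  pos <- with_seed(box$seed, {
    keep <- if (n_sites > n_target) sort(sample.int(n_sites, n_target)) else seq_len(n_sites)
    p <- sites[keep, , drop = FALSE]
    jit <- matrix(stats::runif(length(p), -0.1, 0.1), nrow(p), dim) *
      rep(spacing, each = nrow(p))
    p + jit
  })
  vel <- with_seed(vel_seed + 104729L, {
    matrix(stats::rnorm(n_target * dim), n_target, dim)
  })
  mass <- rep(1.0, n_target)
  if (box$temperature > 0) {
    vel <- sweep(vel, 2, colSums(vel * mass) / sum(mass))   # zero net momentum
    dof <- dim * (n_target - 1L)
    T_inst <- sum(mass * rowSums(vel^2)) / dof
    vel <- vel * sqrt(box$temperature / T_inst)
  } else vel[] <- 0
  new_particle_system(pos, vel, mass, rep(SPECIES_FLUID, n_target),
                      box = L, dim = dim,
                      meta = list(box_spec = box, vel_seed = vel_seed,
                                  mass_initial = sum(mass)))
}

#' Carve a bubble void out of the fluid
#'
#' Removes every fluid particle strictly closer than `D/2` to the void
#' centre, emulating the manual removal of a fluid sphere to seed a
#' cavitation bubble. The void is pure vacuum: no gas particles are placed
#' (at this scale a real cavity holds too little gas to affect the collapse).
#' Polymer beads are never removed; a bubble overlapping the chain is a
#' geometry conflict and an error.
#'
#' @param sys a `"particle_system"`.
#' @param bubble a [bubble_spec()]. `D = 0` leaves the system unchanged.
#' @return the carved system; `meta$removed_bubble` holds the removal count
#'   and `meta$bubble_spec` the spec.
#' @export
carve_bubble <- function(sys, bubble) {
  stopifnot(inherits(sys, "particle_system"), inherits(bubble, "bubble_spec"))
  sys$meta$bubble_spec <- bubble
  if (bubble$D == 0) { sys$meta$removed_bubble <- 0L; return(sys) }
  if (length(bubble$center) != sys$dim)
    stop("bubble center dimensionality mismatch", call. = FALSE)
  R <- bubble$D / 2
  if (any(bubble$center - R < 0) || any(bubble$center + R > sys$box))
    stop("bubble void extends outside the box", call. = FALSE)
  d2 <- rowSums((sys$pos - rep(bubble$center, each = nrow(sys$pos)))^2)
  inside <- d2 < R^2
  if (any(inside & sys$species == SPECIES_POLYMER))
    stop("bubble void overlaps the polymer chain (geometry conflict)", call. = FALSE)
  drop_idx <- which(inside & sys$species == SPECIES_FLUID)
  sys <- drop_particles(sys, drop_idx)
  sys$meta$removed_bubble <- length(drop_idx)
  sys
}

# remove particles by index, remapping bond indices
drop_particles <- function(sys, idx) {
  if (!length(idx)) return(sys)
  keep <- setdiff(seq_len(nrow(sys$pos)), idx)
  remap <- integer(nrow(sys$pos)); remap[keep] <- seq_along(keep)
  if (nrow(sys$bonds) && any(sys$bonds %in% idx))
    stop("cannot drop bonded particles", call. = FALSE)
  sys$pos <- sys$pos[keep, , drop = FALSE]
  sys$vel <- sys$vel[keep, , drop = FALSE]
  sys$mass <- sys$mass[keep]
  sys$species <- sys$species[keep]
  if (nrow(sys$bonds)) sys$bonds[] <- remap[sys$bonds]
  sys
}

# bead coordinates of a chain: axis along the first coordinate, transverse
# helical offset of given phase. Returns n_beads x dim matrix of offsets
# relative to the axis anchor (axis midpoint at origin).
chain_bead_offsets <- function(chain, dim) {
  i <- seq_len(chain$n_beads) - 1L
  ax <- (i - (chain$n_beads - 1) / 2) * chain$r0
  theta <- 2 * pi * i / chain$pitch + (chain$angle %% 360) * pi / 180
  if (dim == 2L) {
    cbind(ax, chain$amplitude * cos(theta))
  } else {
    cbind(ax, chain$amplitude * sin(theta), chain$amplitude * cos(theta))
  }
}

#' Insert the breakable chain downstream of the bubble
#'
#' Places the bead-spring chain with its axis perpendicular to the shock
#' axis, centred laterally, on the downstream (low-z) side of the bubble so
#' that the collapse jet lands on it: the chain axis sits a gap `d` below
#' the bubble surface (distance from bubble surface to chain axis = `d`).
#' Fluid particles inside a capsule of radius `r_excl + amplitude` around
#' the chain axis segment are removed; the capsule does not depend on the
#' rotation phase, so replicate builds keep identical particle counts.
#'
#' @param sys a `"particle_system"` (fluid, possibly already carved).
#' @param chain a [chain_spec()].
#' @param bubble the [bubble_spec()] used for placement (with `D = 0` the
#'   chain sits `d` below the reference centre point).
#' @param vel_seed seed for the bead thermal velocities.
#' @return the system with polymer beads, bonds and exclusion applied.
#' @export
insert_chain <- function(sys, chain, bubble, vel_seed = 2L) {
  stopifnot(inherits(sys, "particle_system"), inherits(chain, "chain_spec"),
            inherits(bubble, "bubble_spec"))
  dim <- sys$dim; L <- sys$box
  chain_len <- (chain$n_beads - 1) * chain$r0
  if (chain_len >= L[1])
    stop("chain longer than the box cross-section", call. = FALSE)
  anchor <- numeric(dim)
  anchor[1] <- L[1] / 2
  if (dim == 3L) anchor[2] <- L[2] / 2
  z_axis <- bubble$center[dim] - bubble$D / 2 - chain$d
  anchor[dim] <- z_axis
  if (z_axis - chain$amplitude <= 0)
    stop("chain placement below the box floor; increase bubble z or box length",
         call. = FALSE)
  off <- chain_bead_offsets(chain, dim)
  beads <- sweep(off, 2, anchor, "+")
  # rotation-independent fluid exclusion: capsule around the axis segment
  r_cap <- chain$r_excl + chain$amplitude
  ax_lo <- anchor[1] - chain_len / 2; ax_hi <- anchor[1] + chain_len / 2
  tx <- pmin(pmax(sys$pos[, 1], ax_lo), ax_hi)   # clamp to segment
  rest <- sys$pos[, -1, drop = FALSE]
  ax_rest <- anchor[-1]
  d2 <- (sys$pos[, 1] - tx)^2 +
    rowSums(sweep(rest, 2, ax_rest)^2)
  drop_idx <- which(d2 < r_cap^2 & sys$species == SPECIES_FLUID)
  sys <- drop_particles(sys, drop_idx)
  n0 <- nrow(sys$pos)
  bvel <- with_seed(vel_seed + 15485863L, {
    Tt <- if (!is.null(sys$meta$box_spec)) sys$meta$box_spec$temperature else 1
    matrix(stats::rnorm(chain$n_beads * dim, sd = sqrt(max(Tt, 0) / chain$mass)),
           chain$n_beads, dim)
  })
  sys$pos <- rbind(sys$pos, beads)
  sys$vel <- rbind(sys$vel, bvel)
  sys$mass <- c(sys$mass, rep(chain$mass, chain$n_beads))
  sys$species <- c(sys$species, rep(SPECIES_POLYMER, chain$n_beads))
  bonds <- cbind(n0 + seq_len(chain$n_beads - 1L),
                 n0 + seq_len(chain$n_beads - 1L) + 1L)
  r0_built <- sqrt(rowSums((beads[-1, , drop = FALSE] -
                            beads[-chain$n_beads, , drop = FALSE])^2))
  sys$bonds <- rbind(sys$bonds, bonds)
  sys$bond_r0 <- c(sys$bond_r0, r0_built)
  sys$bond_k <- c(sys$bond_k, rep(chain$k, nrow(bonds)))
  sys$bond_rbreak <- c(sys$bond_rbreak, chain$r_break_factor * r0_built)
  sys$bond_alive <- rep(TRUE, nrow(sys$bonds))
  sys$meta$chain_spec <- chain
  sys$meta$removed_chain <- length(drop_idx)
  sys$meta$chain_first_bead <- n0 + 1L
  sys$meta$chain_axis_z <- z_axis
  sys$meta$chain_anchor <- anchor
  sys
}

#' Build seeded replicate systems
#'
#' Produces `n` systems that share the same fluid positions and bubble/chain
#' geometry and differ only in the chain rotation about its own axis
#' (0, 90, 180, ... degrees) and in the velocity seed, emulating independent
#' replicate simulations of the same scenario.
#'
#' @param box a [box_spec()].
#' @param bubble a [bubble_spec()].
#' @param chain a [chain_spec()] (its `angle` is overridden per replicate).
#' @param n replicate count (default 3).
#' @return list of `"particle_system"` objects.
#' @export
build_replicates <- function(box, bubble, chain, n = 3L) {
  n <- as.integer(n)
  if (n < 1L) stop("replicate count must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(k) {
    ch <- chain; ch$angle <- 90 * (k - 1L)
    sys <- build_fluid(box, vel_seed = box$seed + 101L * (k - 1L))
    sys <- carve_bubble(sys, bubble)
    insert_chain(sys, ch, bubble, vel_seed = box$seed + 101L * (k - 1L) + 7L)
  })
}
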