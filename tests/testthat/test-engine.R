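# Forces, integration, boundaries, thermostat, bond breaking.

make_system <- function(pos, vel = NULL, box = c(10, 10), mass = NULL,
                        bonds = matrix(integer(0), 0, 2), bond_r0 = numeric(0),
                        bond_k = numeric(0), bond_rbreak = numeric(0)) {
  n <- nrow(pos)
  structure(list(pos = pos,
                 vel = if (is.null(vel)) matrix(0, n, ncol(pos)) else vel,
                 mass = if (is.null(mass)) rep(1, n) else mass,
                 species = rep(1L, n), box = box, dim = ncol(pos),
                 bonds = bonds, bond_r0 = bond_r0, bond_k = bond_k,
                 bond_rbreak = bond_rbreak,
                 bond_alive = rep(TRUE, nrow(bonds)), meta = list()),
            class = "particle_system")
}

test_that("an isolated particle feels no force", {
  sys <- make_system(matrix(c(5, 5), 1, 2))
  f <- compute_forces(sys, potential_spec())
  expect_equal(f$forces, matrix(0, 1, 2))
  expect_equal(f$pe, 0)
})

test_that("a pair at the 12-6 minimum feels only the cutoff force shift", {
  # the potential is force-shifted at the cutoff, so the force at the
  # unshifted minimum equals the (small) shift constant, not exactly zero
  r <- 2^(1 / 6)
  sys <- make_system(rbind(c(4, 5), c(4 + r, 5)), box = c(12, 12))
  f <- compute_forces(sys, potential_spec())$forces
  expect_lt(max(abs(f)), 0.05)
  expect_equal(f[1, ], -f[2, ])   # Newton's third law
})

test_that("cell-list forces equal brute-force all-pairs forces", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:100, 1)
    box <- c(9, 12)
    pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
    # thin out overlapping pairs to keep forces finite
    sys <- make_system(pos, box = box)
    fc <- tryCatch(compute_forces(sys, potential_spec(), "cell"),
                   error = function(e) NULL)
    fb <- tryCatch(compute_forces(sys, potential_spec(), "brute"),
                   error = function(e) NULL)
    if (is.null(fc) || is.null(fb)) next   # overlap rejected by both paths
    expect_lt(max(abs(fc$forces - fb$forces)), 1e-10)
    expect_lt(abs(fc$pe - fb$pe), 1e-9)
    # total force on a laterally periodic system sums to zero in x
    expect_lt(abs(sum(fc$forces[, 1])), 1e-9)
  }
})

test_that("near-zero pair separation is reported as an overlap error", {
  sys <- make_system(rbind(c(5, 5), c(5.01, 5)))
  expect_error(compute_forces(sys, potential_spec()), "overlap")
})

test_that("free flight is ballistic and walls reflect elastically", {
  sys <- make_system(matrix(c(5, 5), 1, 2), vel = matrix(c(0.3, -0.4), 1, 2),
                     box = c(10, 10))
  r <- run_dynamics(sys, potential_spec(), dt = 0.01, steps = 100, stride = NA)
  expect_equal(r$sys$pos[1, ], c(5 + 0.3, 5 - 0.4), tolerance = 1e-12)
  # drive the particle into the lower z wall: speed preserved, z-velocity flips
  sys2 <- make_system(matrix(c(5, 0.5), 1, 2), vel = matrix(c(0, -1), 1, 2),
                      box = c(10, 10))
  r2 <- run_dynamics(sys2, potential_spec(), dt = 0.01, steps = 100, stride = NA)
  expect_equal(r2$sys$vel[1, ], c(0, 1), tolerance = 1e-12)
  expect_equal(r2$sys$pos[1, 2], 0.5, tolerance = 1e-12)  # bounced back up
})

test_that("a bonded pair oscillates with conserved energy", {
  # bonded pairs are excluded from the pair potential, so this is a pure
  # harmonic oscillator; small amplitude, 10,000 steps
  sys <- make_system(rbind(c(4, 5), c(5.1, 5)), box = c(10, 10),
                     bonds = matrix(c(1L, 2L), 1, 2), bond_r0 = 1.0,
                     bond_k = 50, bond_rbreak = 10)
  r <- run_dynamics(sys, potential_spec(), dt = 0.0001, steps = 10000,
                    stride = NA, energy_stride = 100)
  en <- r$energy
  expect_lt(max(abs(en$total - en$total[1])) / abs(en$total[1]), 1e-6)
  # amplitude preserved: the pair stays bound at its initial extension scale
  rel <- r$sys$pos[1, 1] - r$sys$pos[2, 1]
  expect_lte(abs(abs(rel) - 1.0), 0.11)
})

test_that("NVE drift of an equilibrated fluid is at the conservation floor", {
  sys <- equilibrate(small_fluid(seed = 3), potential_spec(), 1.0, 800,
                     dt = 0.002)
  steps <- 2000
  r <- run_dynamics(sys, potential_spec(), dt = 0.00025, steps = steps,
                    stride = NA, energy_stride = 100)
  en <- r$energy
  expect_lt(max(abs(en$total - en$total[1])) / abs(en$total[1]),
            1e-5 * steps / 1000)
})

test_that("equilibration reaches and holds the target temperature", {
  sys <- small_fluid(seed = 5)
  out <- equilibrate(sys, potential_spec(), 1.0, 1200, dt = 0.002)
  expect_lt(abs(out$meta$equilibration$T_final - 1.0), 0.05)
  # an already-thermal system stays in band (no warning)
  expect_no_warning(equilibrate(out, potential_spec(), 1.0, 1200, dt = 0.002,
                                tau = 0.1))
})

test_that("a cold start heats monotonically toward the target", {
  sys <- small_fluid(seed = 8)
  sys$vel[] <- 0
  out <- equilibrate(sys, potential_spec(), 1.0, 2000, dt = 0.002, tau = 0.3)
  tr <- out$meta$equilibration$temperature_trace
  quarters <- split(tr$T, cut(tr$step, 4))
  qm <- vapply(quarters, mean, 0)
  expect_true(all(diff(qm) > -0.02))          # non-decreasing in the mean
  expect_lt(abs(out$meta$equilibration$T_final - 1.0), 0.1)
})

test_that("the momentum mirror shifts the axial velocity uniformly", {
  sys <- small_fluid(seed = 2)
  before <- mean(sys$vel[, 2])
  after <- apply_momentum_mirror(sys, 1.5)
  expect_equal(mean(after$vel[, 2]), before + 1.5, tolerance = 1e-12)
  expect_identical(after$vel[, 1], sys$vel[, 1])
  same <- apply_momentum_mirror(sys, 0)
  expect_identical(same$vel, sys$vel)
  expect_error(apply_momentum_mirror(sys, -1), "v_p")
})

test_that("bond rupture is threshold-exact and irreversible", {
  mk <- function(stretch) make_system(
    rbind(c(4, 5), c(4 + stretch, 5)), box = c(12, 12),
    bonds = matrix(c(1L, 2L), 1, 2), bond_r0 = 1.0, bond_k = 5,
    bond_rbreak = 1.5)
  ok <- check_bonds(mk(1.0))
  expect_identical(nrow(ok$events), 0L)
  gone <- check_bonds(mk(1.5 * 1.01))
  expect_identical(gone$events$bond, 1L)
  expect_false(gone$sys$bond_alive[1])
  # irreversibility inside the integrator: once broken the beads separate
  # (or rebound) without the bond re-forming
  sys <- mk(1.52)
  r <- run_dynamics(sys, potential_spec(), dt = 0.001, steps = 500, stride = NA)
  expect_false(r$sys$bond_alive[1])
  expect_identical(r$events$bond, 1L)
  r2 <- run_dynamics(r$sys, potential_spec(), dt = 0.001, steps = 200,
                     stride = NA)
  expect_false(r2$sys$bond_alive[1])
})

test_that("an oversized timestep is rejected as unstable", {
  sys <- make_system(matrix(c(5, 5), 1, 2), vel = matrix(c(0, 500), 1, 2))
  expect_error(run_dynamics(sys, potential_spec(), dt = 0.01, steps = 10,
                            stride = NA),
               "smaller timestep")
})

test_that("lateral momentum is conserved in NVE between wall contacts", {
  sys <- suppressWarnings(equilibrate(small_fluid(seed = 13), potential_spec(),
                                      1.0, 400, dt = 0.002))
  px0 <- sum(sys$mass * sys$vel[, 1])
  r <- run_dynamics(sys, potential_spec(), dt = 0.001, steps = 1500, stride = NA)
  expect_equal(sum(r$sys$mass * r$sys$vel[, 1]), px0, tolerance = 1e-8)
})
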