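# Fluid slab construction, bubble carving, chain insertion, replicates.

test_that("fluid particle count is density times volume, rounded", {
  sys <- build_fluid(box_spec(c(10, 10), density = 0.8, seed = 3))
  expect_identical(nrow(sys$pos), 80L)
  expect_true(all(sys$pos >= 0 & sys$pos <= rep(c(10, 10), each = 80)))
  sys3 <- build_fluid(box_spec(c(6, 6, 8), density = 0.7, seed = 3))
  expect_identical(nrow(sys3$pos), as.integer(round(0.7 * 6 * 6 * 8)))
})

test_that("builds are bit-identical under a fixed seed", {
  a <- build_fluid(box_spec(c(14, 20), 0.8, seed = 11))
  b <- build_fluid(box_spec(c(14, 20), 0.8, seed = 11))
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  c <- build_fluid(box_spec(c(14, 20), 0.8, seed = 12))
  expect_false(identical(a$pos, c$pos))
})

test_that("generated velocities carry zero net momentum at the target temperature", {
  sys <- small_fluid(seed = 7)
  expect_equal(colSums(sys$vel * sys$mass), c(0, 0), tolerance = 1e-12)
  expect_equal(sum(sys$mass * rowSums(sys$vel^2)) / (2 * (nrow(sys$pos) - 1)),
               1.0, tolerance = 1e-12)
})

test_that("box validation enforces geometry and density caps", {
  expect_error(box_spec(c(30, 20), 0.8), "longest")
  expect_error(box_spec(c(10, 20), 3.0), "density")
  expect_error(box_spec(c(10, -1), 0.8), "positive")
})

test_that("bubble carving removes exactly the particles a distance check finds", {
  sys <- build_fluid(box_spec(c(20, 30), 0.8, seed = 5))
  bub <- bubble_spec(c(10, 15), D = 8)
  carved <- carve_bubble(sys, bub)
  # independent brute-force oracle on the original build
  d2 <- rowSums(sweep(sys$pos, 2, bub$center)^2)
  expect_identical(carved$meta$removed_bubble, sum(d2 < 16))
  expect_identical(nrow(carved$pos), nrow(sys$pos) - sum(d2 < 16))
  # removed count is close to density * void area
  expect_equal(carved$meta$removed_bubble, 0.8 * pi * 16, tolerance = 0.15)
  # no survivor inside the void
  expect_true(all(rowSums(sweep(carved$pos, 2, bub$center)^2) >= 16))
})

test_that("a zero-diameter bubble is a no-op and bad geometry errors", {
  sys <- small_fluid()
  same <- carve_bubble(sys, bubble_spec(c(6, 9), 0))
  expect_identical(same$pos, sys$pos)
  expect_identical(same$meta$removed_bubble, 0L)
  expect_error(carve_bubble(sys, bubble_spec(c(1, 9), 6)), "outside")
  withchain <- insert_chain(sys, chain_spec(n_beads = 6), bubble_spec(c(6, 12), 0))
  expect_error(carve_bubble(withchain, bubble_spec(c(6, 10), 6)),
               "polymer")
})

test_that("chain insertion places the axis a gap d below the bubble surface", {
  sys <- build_fluid(box_spec(c(20, 30), 0.8, seed = 2))
  bub <- bubble_spec(c(10, 20), D = 8)
  sys <- carve_bubble(sys, bub)
  ch <- chain_spec(n_beads = 12, d = 1.5)
  out <- insert_chain(sys, ch, bub)
  gap <- (bub$center[2] - bub$D / 2) - out$meta$chain_axis_z
  expect_equal(gap, 1.5, tolerance = 1e-9)
  # 12 beads -> 11 bonds, all alive, valid indices
  expect_identical(nrow(out$bonds), 11L)
  expect_true(all(out$bond_alive))
  expect_true(all(out$bonds >= 1 & out$bonds <= nrow(out$pos)))
  expect_identical(sum(out$species == 2L), 12L)
  # bonds start at their rest length (relaxed build)
  blen <- sqrt(rowSums((out$pos[out$bonds[, 1], ] - out$pos[out$bonds[, 2], ])^2))
  expect_equal(blen, out$bond_r0, tolerance = 1e-12)
})

test_that("rotating the chain a full turn reproduces the zero-degree build", {
  sys <- build_fluid(box_spec(c(20, 30), 0.8, seed = 2))
  bub <- bubble_spec(c(10, 20), D = 6)
  a <- insert_chain(carve_bubble(sys, bub), chain_spec(angle = 0), bub)
  b <- insert_chain(carve_bubble(sys, bub), chain_spec(angle = 360), bub)
  expect_identical(a$pos, b$pos)
  c90 <- insert_chain(carve_bubble(sys, bub), chain_spec(angle = 90), bub)
  expect_false(identical(a$pos, c90$pos))
})

test_that("chains that cannot fit are rejected", {
  sys <- small_fluid()
  expect_error(insert_chain(sys, chain_spec(n_beads = 30, r0 = 1),
                            bubble_spec(c(6, 12), 0)),
               "longer than the box")
})

test_that("replicates differ only in rotation and velocity seed", {
  box <- box_spec(c(20, 30), 0.8, seed = 9)
  bub <- bubble_spec(c(10, 20), D = 6)
  reps <- build_replicates(box, bub, chain_spec(), n = 3)
  expect_length(reps, 3)
  counts <- vapply(reps, function(s) nrow(s$pos), 0L)
  expect_identical(counts, rep(counts[1], 3))
  angles <- vapply(reps, function(s) s$meta$chain_spec$angle, 0)
  expect_identical(angles, c(0, 90, 180))
  # fluid positions identical across replicates; velocities differ
  nf <- sum(reps[[1]]$species == 1L)
  expect_identical(reps[[1]]$pos[1:nf, ], reps[[2]]$pos[1:nf, ])
  expect_false(identical(reps[[1]]$vel[1:nf, ], reps[[2]]$vel[1:nf, ]))
  # a single replicate equals the direct build
  one <- build_replicates(box, bub, chain_spec(), n = 1)[[1]]
  direct <- insert_chain(carve_bubble(build_fluid(box, vel_seed = box$seed), bub),
                         chain_spec(angle = 0), bub,
                         vel_seed = box$seed + 7L)
  expect_identical(one$pos, direct$pos)
})

test_that("mass bookkeeping is conserved through carve and insert", {
  box <- box_spec(c(20, 30), 0.8, seed = 4)
  sys0 <- build_fluid(box)
  m0 <- sum(sys0$mass)
  bub <- bubble_spec(c(10, 20), D = 8)
  sys1 <- carve_bubble(sys0, bub)
  ch <- chain_spec(n_beads = 12)
  sys2 <- insert_chain(sys1, ch, bub)
  removed <- sys2$meta$removed_bubble + sys2$meta$removed_chain
  expect_equal(sum(sys2$mass), m0 - removed * 1.0 + 12 * ch$mass)
})
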