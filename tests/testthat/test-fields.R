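# Binned continuum fields, jet series, axial profiles, damage reports.

test_that("a lone particle defines its bin's density and velocity", {
  frame <- list(pos = matrix(c(2.5, 3.5), 1, 2),
                vel = matrix(c(0.7, -0.2), 1, 2))
  fg <- bin_fields(frame, box = c(8, 8), h = 1, mass = 2.5)
  expect_identical(fg$count[3, 4], 1L)
  expect_equal(fg$density[3, 4], 2.5)         # m / h^2
  lin <- 3 + (4 - 1) * 8                       # bin (3,4), first axis fastest
  expect_equal(fg$velocity[lin, ], c(0.7, -0.2))
  expect_true(all(is.na(fg$velocity[-lin, ])))  # empty bins flagged, not zero
})

test_that("bin kinetic temperature measures velocity spread about the bin mean", {
  frame <- list(pos = rbind(c(0.5, 0.5), c(0.6, 0.4)),
                vel = rbind(c(0.8, 0), c(-0.8, 0)))
  fg <- bin_fields(frame, box = c(4, 4), h = 1)
  # two unit-mass particles at +-u: mean 0, T = sum m u^2 / (dim n)
  expect_equal(fg$temperature[1, 1], 2 * 0.8^2 / (2 * 2))
  expect_equal(fg$pressure_kin[1, 1], fg$density[1, 1] * fg$temperature[1, 1])
  expect_true(is.na(fg$temperature[3, 3]))   # empty bin flagged
})

test_that("binning conserves mass and momentum exactly", {
  fr <- random_frame(700, c(12, 20), seed = 21)
  mass <- runif(700, 0.5, 2)
  fg <- bin_fields(fr, c(12, 20), h = 2, mass = mass)
  expect_identical(sum(fg$mass), sum(mass))
  # sum over bins of mass * mean velocity equals total particle momentum
  mom <- colSums(fg$velocity * as.vector(fg$mass), na.rm = TRUE)
  expect_equal(mom, colSums(mass * fr$vel), tolerance = 1e-12)
})

test_that("binning matches a naive per-particle assignment oracle", {
  for (seed in c(2, 9)) {
    fr <- random_frame(500, c(10, 14), seed = seed)
    fg <- bin_fields(fr, c(10, 14), h = 1)
    oracle <- naive_binning(fr, c(10, 14), h = 1)
    expect_identical(fg$count, oracle$count)
    expect_equal(fg$mass, oracle$mass)
    vel_sum <- fg$velocity * as.vector(fg$mass)
    vel_sum[is.na(vel_sum)] <- 0
    expect_equal(array(vel_sum, c(dim(oracle$count), 2)), oracle$mom)
  }
})

test_that("bins are half-open with the upper box edge folded into the last bin", {
  frame <- list(pos = rbind(c(0, 0), c(1, 2), c(6, 8)),  # on edges
                vel = matrix(0, 3, 2))
  fg <- bin_fields(frame, box = c(6, 8), h = 1)
  expect_identical(fg$count[1, 1], 1L)   # origin in first bin
  expect_identical(fg$count[2, 3], 1L)   # interior boundary goes up
  expect_identical(fg$count[6, 8], 1L)   # box edge folded into last bin
  expect_false(fg$truncated)
  expect_true(bin_fields(frame, box = c(6.5, 8), h = 1)$truncated)
  expect_error(bin_fields(list(pos = matrix(0, 0, 2), vel = matrix(0, 0, 2)),
                          c(6, 8), 1), "empty")
})

test_that("a static system yields an identically zero jet series", {
  sys <- small_fluid(seed = 1)
  traj <- structure(list(frames = list(
    list(step = 0L, time = 0, pos = sys$pos, vel = sys$vel * 0),
    list(step = 1L, time = 1, pos = sys$pos, vel = sys$vel * 0)),
    box = sys$box, dim = 2L, species = sys$species, mass = sys$mass, dt = 1),
    class = "trajectory")
  jr <- max_local_velocity_series(traj, h = 3, min_count = 3)
  expect_true(all(jr$series$max_speed == 0))
  expect_identical(jr$peak, 0)
})

test_that("a constructed fast bin sets the jet peak at the right frame", {
  set.seed(4)
  pos <- cbind(runif(200, 0, 10), runif(200, 0, 10))
  vel0 <- matrix(0, 200, 2)
  vel1 <- vel0
  hot <- which(pos[, 1] < 2 & pos[, 2] < 2)
  vel1[hot, 1] <- 5                           # one corner bin moves at speed 5
  traj <- structure(list(frames = list(
    list(step = 0L, time = 0, pos = pos, vel = vel0),
    list(step = 1L, time = 0.5, pos = pos, vel = vel1),
    list(step = 2L, time = 1, pos = pos, vel = vel0)),
    box = c(10, 10), dim = 2L, species = rep(1L, 200), mass = rep(1, 200),
    dt = 0.5), class = "trajectory")
  jr <- max_local_velocity_series(traj, h = 2, min_count = 3)
  expect_equal(jr$peak, 5)
  expect_equal(jr$t_peak, 0.5)
  expect_equal(jr$direction, c(1, 0))
  expect_equal(jr$t_half_decay, 1)
  expect_error(max_local_velocity_series(traj, h = 2, min_count = 1000),
               "under-occupied")
})

test_that("axial profiles report zero spread for identical replicates", {
  fr <- random_frame(400, c(10, 20), seed = 6)
  mk <- function() structure(list(frames = list(
    list(step = 0L, time = 0, pos = fr$pos, vel = fr$vel),
    list(step = 1L, time = 1, pos = fr$pos, vel = fr$vel)),
    box = c(10, 20), dim = 2L, species = rep(1L, 400), mass = rep(1, 400),
    dt = 1), class = "trajectory")
  one <- axial_velocity_profile(mk(), chain_z = 10, times = c(0, 1), h = 2)
  expect_true(all(one$profile$sd_speed == 0))
  three <- axial_velocity_profile(list(mk(), mk(), mk()), chain_z = 10,
                                  times = c(0, 1), h = 2)
  expect_true(all(three$profile$sd_speed == 0))
  expect_equal(three$profile$mean_speed, one$profile$mean_speed)
  expect_error(axial_velocity_profile(list(mk(), mk()), chain_z = 10,
                                      times = 0.37, h = 2),
               "no frame at time")
})

test_that("damage reports map events onto fragments and break sites", {
  none <- damage_report(data.frame(bond = integer(0)), n_beads = 12)
  expect_false(none$broken)
  expect_identical(none$fragment_count, 1L)
  one <- damage_report(data.frame(bond = 5L, time = 2.5), n_beads = 12)
  expect_true(one$broken)
  expect_identical(one$fragment_count, 2L)
  expect_equal(one$break_sites, 4.5 / 11)
  expect_equal(one$break_times, 2.5)
  two <- damage_report(data.frame(bond = c(3L, 7L)), n_beads = 12)
  expect_identical(two$fragment_count, 3L)
  expect_identical(lengths(two$fragments), c(3L, 4L, 5L))
  expect_error(damage_report(data.frame(bond = 15L), n_beads = 12), "unknown")
})

test_that("fragment counts agree with an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(4:40, 1)
    nb <- sample(0:(n - 1), 1)
    broken <- sort(sample(seq_len(n - 1), min(nb, n - 1)))
    rep_ <- damage_report(if (length(broken)) data.frame(bond = broken)
                          else data.frame(bond = integer(0)), n_beads = n)
    intact <- setdiff(seq_len(n - 1), broken)
    g <- igraph::graph_from_edgelist(
      cbind(intact, intact + 1L), directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    expect_identical(rep_$fragment_count, as.integer(igraph::components(g)$no))
    # linear-chain identity: fragments = broken bonds + 1
    expect_identical(rep_$fragment_count, length(broken) + 1L)
  }
})

test_that("outcomes split into ruptured and deformed-intact", {
  broken <- damage_report(data.frame(bond = 2L), n_beads = 8)
  expect_identical(classify_outcome(broken)$outcome, "ruptured")
  intact <- damage_report(data.frame(bond = integer(0)), n_beads = 8)
  pos <- cbind(seq(2, 9), c(5, 5, 5, 7, 7, 5, 5, 5))  # deflected middle
  traj <- structure(list(frames = list(
    list(step = 0L, time = 0, pos = pos, vel = pos * 0)),
    box = c(12, 12), dim = 2L, species = rep(2L, 8), mass = rep(1, 8), dt = 1),
    class = "trajectory")
  out <- classify_outcome(intact, traj)
  expect_identical(out$outcome, "deformed-intact")
  expect_gt(out$max_deflection, 1)
})
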