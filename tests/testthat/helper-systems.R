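# Shared fixtures, all built in code.

# small thermalised 2D fluid, fast to build
small_fluid <- function(seed = 1L, lengths = c(12, 18), density = 0.8,
                        temperature = 1.0) {
  build_fluid(box_spec(lengths, density, temperature, seed = seed))
}

# a tiny but complete shock-tube configuration for fast pipeline tests
tiny_config <- function(seed = 1L) {
  load_config(list(
    box = list(lengths = c(16, 30), density = 0.8, temperature = 1.0),
    grids = list(D = c(0, 5), v_p = c(1.5, 2.5)),
    replicates = 1L,
    chain = list(n_beads = 8L),
    run = list(equil_steps = 600L, shock_steps = 2200L, stride = 50L),
    seed = seed))
}

# synthetic trajectory with an analytic front: ambient fluid (density rho0,
# axial drift v_p) below the front, compressed fluid (rho1, at rest) above;
# the front advances toward -z at lab speed c_lab
synthetic_front_traj <- function(c_lab = 7, v_p = 2, rho0 = 0.8, rho1 = 1.2,
                                 box = c(20, 60), z0 = 56, times = seq(0, 2, 0.1),
                                 seed = 42L) {
  set.seed(seed)
  frames <- lapply(times, function(t) {
    zf <- z0 - c_lab * t
    n_lo <- round(rho0 * box[1] * zf)
    n_hi <- round(rho1 * box[1] * (box[2] - zf))
    pos <- rbind(
      cbind(runif(n_lo, 0, box[1]), runif(n_lo, 0, zf)),
      cbind(runif(n_hi, 0, box[1]), runif(n_hi, zf, box[2])))
    vel <- rbind(
      cbind(numeric(n_lo), rep(v_p, n_lo)),
      matrix(0, n_hi, 2))
    list(step = NA_integer_, time = t, pos = pos, vel = vel)
  })
  n1 <- nrow(frames[[1]]$pos)
  structure(list(frames = frames, box = box, dim = 2L,
                 species = rep(1L, n1), mass = rep(1.0, n1), dt = NA_real_),
            class = "trajectory")
}

# random frame for binning oracles
random_frame <- function(n, box, seed = 1L, dim = length(box)) {
  set.seed(seed)
  list(pos = matrix(runif(n * dim), n, dim) %*% diag(box, dim),
       vel = matrix(rnorm(n * dim), n, dim),
       time = 0)
}

# brute-force per-particle binning oracle (independent of bin_fields)
naive_binning <- function(frame, box, h, mass = rep(1, nrow(frame$pos))) {
  dim <- ncol(frame$pos)
  nb <- as.integer(ceiling(box / h - 1e-9))
  cnt <- array(0L, nb)
  msum <- array(0, nb)
  vsum <- array(0, c(nb, dim))
  for (i in seq_len(nrow(frame$pos))) {
    idx <- integer(dim)
    for (k in seq_len(dim)) {
      b <- floor(frame$pos[i, k] / h) + 1
      if (b > nb[k]) b <- nb[k]
      if (b < 1) b <- 1
      idx[k] <- b
    }
    im <- matrix(idx, 1)
    cnt[im] <- cnt[im] + 1L
    msum[im] <- msum[im] + mass[i]
    for (k in seq_len(dim))
      vsum[cbind(im, k)] <- vsum[cbind(im, k)] + mass[i] * frame$vel[i, k]
  }
  list(count = cnt, mass = msum, mom = vsum)
}
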