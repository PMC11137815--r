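test_that("presets carry the published hyperparameters", {
  m <- gradnav_config(preset = "muller")
  expect_equal(m$beta, 0.75); expect_equal(m$k, 100)
  expect_equal(m$outer_frames, 500); expect_equal(m$inner_frames, 50)
  expect_equal(m$total_frames, 10000)
  mm <- gradnav_config(preset = "modified_muller")
  expect_equal(mm$beta, 1); expect_equal(mm$k, 20)
  expect_equal(mm$outer_frames, 500); expect_equal(mm$inner_frames, 50)
  fs <- gradnav_config(preset = "fs_peptide")
  expect_equal(fs$beta, 0.1); expect_equal(fs$k, 100)
  expect_equal(fs$outer_frames, 300); expect_equal(fs$inner_frames, 40)
})

test_that("explicit arguments override preset values", {
  cfg <- gradnav_config(preset = "muller", beta = 0.5, total_frames = 2000)
  expect_equal(cfg$beta, 0.5)
  expect_equal(cfg$k, 100)
  expect_equal(cfg$total_frames, 2000)
})

test_that("invalid configurations are rejected", {
  expect_error(gradnav_config(beta = 0))
  expect_error(gradnav_config(k = -1))
  expect_error(gradnav_config(inner_frames = 600, outer_frames = 500))
  expect_error(gradnav_config(total_frames = 100, outer_frames = 500))
  expect_error(gradnav_config(preset = "nope"), "unknown preset")
})

test_that("density estimation requires at least two points", {
  expect_error(estimate_density(matrix(c(0, 0), ncol = 2)), "at least 2")
})

test_that("density is maximal with zero gradient at an identical-point cluster", {
  pts <- matrix(rep(c(0.3, -0.2), each = 20), ncol = 2)
  d <- estimate_density(pts, bandwidth = 0.1)
  at <- density_value(d, c(0.3, -0.2))
  expect_gt(at, density_value(d, c(0.5, -0.2)))
  expect_equal(density_gradient(d, c(0.3, -0.2)), c(0, 0))
})

test_that("gradient vanishes at the midpoint of two symmetric clusters", {
  pts <- rbind(matrix(rep(c(-1, 0), each = 10), ncol = 2),
               matrix(rep(c(1, 0), each = 10), ncol = 2))
  d <- estimate_density(pts, bandwidth = 0.5)
  expect_equal(density_gradient(d, c(0, 0)), c(0, 0), tolerance = 1e-12)
})

test_that("KDE approximates a known Gaussian density at its mean", {
  set.seed(123)
  pts <- cbind(rnorm(1000, 0, 0.5), rnorm(1000, 0, 0.5))
  d <- estimate_density(pts, bandwidth = "auto")
  expect_equal(density_value(d, c(0, 0)), 1 / (2 * pi * 0.25),
               tolerance = 0.15)
})

test_that("KDE integrates to ~1 over the plane", {
  set.seed(4)
  pts <- cbind(rnorm(200), rnorm(200))
  d <- estimate_density(pts, bandwidth = "auto")
  g <- seq(-6, 6, by = 0.1)
  vals <- outer(g, g, Vectorize(function(x, y) density_value(d, c(x, y))))
  expect_equal(sum(vals) * 0.1^2, 1, tolerance = 0.01)
})

test_that("analytic density gradient matches finite differences", {
  set.seed(31)
  pts <- cbind(runif(200, -1, 1), runif(200, -1, 1))
  d <- estimate_density(pts, bandwidth = "auto")
  f <- function(p) density_value(d, p)
  for (i in 1:25) {
    p <- runif(2, -1.2, 1.2)
    expect_lt(rel_err(density_gradient(d, p), fd_gradient(f, p)), 1e-5)
  }
})

test_that("boundaries contain every point they were built from", {
  set.seed(8)
  pts <- cbind(runif(40), runif(40))
  for (mode in c("bbox", "hull")) {
    b <- observation_boundary(pts, mode)
    for (i in seq_len(nrow(pts)))
      expect_true(boundary_contains(b, pts[i, ]))
  }
})

test_that("bbox of the unit square corners is the unit square", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  b <- observation_boundary(pts, "bbox")
  expect_true(boundary_contains(b, c(0.5, 0.5)))
  expect_true(boundary_contains(b, c(0, 0)))     # boundary point is inside
  expect_false(boundary_contains(b, c(1.1, 0.5)))
})

test_that("hull containment excludes points bbox would accept", {
  pts <- rbind(c(0, 0), c(2, 0), c(1, 2))        # a triangle
  b <- observation_boundary(pts, "hull")
  expect_equal(b$mode, "hull")
  expect_true(boundary_contains(b, c(1, 0.5)))
  expect_false(boundary_contains(b, c(0.1, 1.9)))  # inside bbox, outside hull
  bb <- observation_boundary(pts, "bbox")
  expect_true(boundary_contains(bb, c(0.1, 1.9)))
})

test_that("degenerate hulls fall back to bbox geometry", {
  pts <- rbind(c(0, 0), c(1, 1), c(2, 2))        # collinear
  b <- observation_boundary(pts, "hull")
  expect_equal(b$mode, "bbox")
  expect_true(boundary_contains(b, c(1, 1)))
})

test_that("a single point makes a degenerate boundary containing only itself", {
  b <- observation_boundary(matrix(c(0.5, 0.5), ncol = 2), "bbox")
  expect_true(boundary_contains(b, c(0.5, 0.5)))
  expect_false(boundary_contains(b, c(0.5001, 0.5)))
})

test_that("centroid is the arithmetic mean", {
  expect_equal(traj_centroid(matrix(c(1, 2), ncol = 2)), c(1, 2))
  expect_equal(traj_centroid(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))), c(1, 1))
  expect_equal(traj_centroid(rbind(c(-1, -3), c(1, 3))), c(0, 0))
})

test_that("update rate follows the gated linear rule", {
  m <- gradnav_config(preset = "muller")
  mm <- gradnav_config(preset = "modified_muller")
  expect_equal(update_rate(5, m, gamma = 0), 0)
  expect_equal(update_rate(0, m, gamma = 1), 0.75)
  expect_equal(update_rate(20, mm, gamma = 1), 2.0)
  expect_error(update_rate(-1, m, 1))
  expect_error(update_rate(1, m, 0.5))
})

test_that("next_start moves by exactly rate, away from observation mass", {
  pts <- matrix(rep(c(-1, 0), each = 30), ncol = 2) +
    matrix(rnorm(60, 0, 0.01), ncol = 2)
  d <- estimate_density(pts, bandwidth = 0.2)
  x <- c(0, 0)
  nx <- next_start(x, d, rate = 0.5)
  expect_equal(sqrt(sum((nx - x)^2)), 0.5, tolerance = 1e-12)
  expect_gt(nx[1], 0)                    # pushed right, away from the cluster
  expect_identical(next_start(x, d, 0), x)
})

test_that("next_start falls back to a seeded random direction on flat density", {
  pts <- matrix(rep(c(0, 0), each = 5), ncol = 2)
  d <- estimate_density(pts, bandwidth = 0.01)
  far <- c(50, 50)                       # gradient numerically zero out here
  set.seed(77)
  a <- next_start(far, d, 1)
  set.seed(77)
  b <- next_start(far, d, 1)
  expect_identical(a, b)
  expect_equal(sqrt(sum((a - far)^2)), 1, tolerance = 1e-12)
})

test_that("a budget of exactly one outer segment yields one segment", {
  cfg <- gradnav_config(preset = "muller", total_frames = 500)
  r <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = 1)
  expect_equal(nrow(r$segments), 1)
  expect_equal(r$segments$kind, "outer")
  expect_equal(n_frames(r$trajectory), 500)
})

test_that("with an all-containing boundary the stride escalates linearly", {
  # a bank whose points blanket the region: bbox contains every centroid, so
  # gamma stays 1 and v increments by exactly 1 per inner segment
  set.seed(5)
  blanket <- cbind(runif(4000, -50, 50), runif(4000, -50, 50))
  bank <- bank_from_trajectories(list(blanket), cutoff = 5)
  cfg <- gradnav_config(beta = 0.1, k = 100, outer_frames = 100,
                        inner_frames = 10, total_frames = 400)
  r <- gradnav_run(bank_engine(bank), cfg, c(0, 0), seed = 2)
  inner <- r$segments[r$segments$kind == "inner", ]
  expect_true(all(inner$gamma == 1))
  # the uniform rule v_{n+1} = gamma_n (v_n + 1) also counts the outer
  # segment (gamma = 1), so the first probe launches at stride 1
  expect_equal(inner$stride_at_launch, seq_len(nrow(inner)))
})

test_that("stride bookkeeping: v resets after escapes, else increments", {
  cfg <- gradnav_config(preset = "muller", total_frames = 5000)
  r <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = 3)
  sg <- r$segments
  # v_{n+1} = gamma_n (v_n + 1), uniformly over outer and inner segments
  for (i in seq_len(nrow(sg) - 1)) {
    expected <- sg$gamma[i] * (sg$stride_at_launch[i] + 1)
    expect_equal(sg$stride_at_launch[i + 1], expected)
  }
  # every outer segment launches with stride 0 except the continuation case
  expect_true(all(sg$stride_at_launch[sg$kind == "outer"] == 0))
})

test_that("escape flag equals 'centroid outside the governing boundary'", {
  cfg <- gradnav_config(preset = "muller", total_frames = 5000)
  r <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = 6)
  sg <- r$segments
  expect_true(all(sg$escaped == (sg$gamma == 0)))
  expect_true(all(!sg$escaped[sg$kind == "outer"]))
  # re-derive each probe's gamma from the recorded frames: boundary of all
  # prior frames plus the probe's launch point
  obs <- NULL
  for (i in seq_len(nrow(sg))) {
    pts <- segment_frames(r, i)
    if (sg$kind[i] == "inner") {
      b <- observation_boundary(rbind(obs, c(sg$start_x[i], sg$start_y[i])),
                                cfg$boundary_mode)
      expect_equal(sg$gamma[i],
                   as.integer(boundary_contains(b, colMeans(pts))))
    }
    obs <- rbind(obs, pts)
  }
})

test_that("the frame budget is never exceeded and spans are contiguous", {
  for (seed in 1:3) {
    cfg <- gradnav_config(preset = "muller", total_frames = 3000)
    r <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = seed)
    sg <- r$segments
    expect_lte(n_frames(r$trajectory), cfg$total_frames)
    expect_equal(sum(sg$n_frames), n_frames(r$trajectory))
    expect_equal(sg$frame_first[1], 0)
    expect_true(all(diff(sg$frame_first) == sg$n_frames[-nrow(sg)]))
    expect_equal(sg$frame_last, sg$frame_first + sg$n_frames - 1)
  }
})

test_that("runs are deterministic in the run seed", {
  cfg <- gradnav_config(preset = "muller", total_frames = 2000)
  a <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = 10)
  b <- gradnav_run(MULLER, cfg, c(-0.55, 1.45), seed = 10)
  expect_identical(a$trajectory$points, b$trajectory$points)
  expect_identical(a$segments, b$segments)
})

test_that("no-bias: every segment replays bit-identically through plain LD", {
  cfg <- gradnav_config(preset = "muller", total_frames = 4000)
  eng <- langevin_engine(MULLER)
  r <- gradnav_run(eng, cfg, c(-0.55, 1.45), seed = 14)
  for (i in r$segments$segment) {
    replayed <- replay_gradnav_segment(eng, r, i)
    expect_identical(unname(replayed$points), unname(segment_frames(r, i)))
  }
})

test_that("restart tempering keeps proposals out of repulsive walls", {
  # a proposal deep inside the wall is pulled back to the cap energy
  cap <- min(MULLER_WELLS$energies) + 450
  x_from <- c(-0.55, 1.45)
  x_to <- c(3, 3)                        # V >> cap out here
  t <- temper_start(MULLER, x_from, x_to, cap)
  expect_lte(pes_evaluate(MULLER, t), cap)
  # the tempered point stays on the segment
  lam <- (t - x_from) / (x_to - x_from)
  expect_equal(lam[1], lam[2], tolerance = 1e-6)
  expect_true(lam[1] >= 0 && lam[1] <= 1)
  # accessible proposals pass through unchanged
  expect_identical(temper_start(MULLER, x_from, c(0.6, 0.03), cap),
                   c(0.6, 0.03))
})

test_that("update magnitude is non-decreasing within an unbroken gamma=1 run", {
  cfg <- gradnav_config(preset = "modified_muller", total_frames = 6000)
  r <- gradnav_run(MODIFIED, cfg, c(0.7087, 0.0012), seed = 2)
  sg <- r$segments
  rates <- ifelse(sg$gamma == 1, cfg$beta + sg$stride_at_launch / cfg$k, 0)
  for (i in 2:nrow(sg)) {
    if (sg$gamma[i - 1] == 1 && sg$gamma[i] == 1 && sg$kind[i] == "inner" &&
        sg$kind[i - 1] == "inner")
      expect_gte(rates[i], rates[i - 1])
  }
})

test_that("a pathological configuration aborts at max_stride", {
  set.seed(5)
  blanket <- cbind(runif(4000, -50, 50), runif(4000, -50, 50))
  bank <- bank_from_trajectories(list(blanket), cutoff = 5)
  cfg <- gradnav_config(beta = 0.1, k = 100, outer_frames = 100,
                        inner_frames = 10, total_frames = 1000, max_stride = 5)
  expect_error(gradnav_run(bank_engine(bank), cfg, c(0, 0), seed = 2),
               "max_stride")
})
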