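# independent closed-form oracles
hypot_oracle <- function(x1, y1, x2, y2)
  vapply(seq_along(x1), function(i) sqrt((x1[i] - x2[i])^2 + (y1[i] - y2[i])^2), 0)

acos_angle_oracle <- function(p0, p1, p2) {
  u <- p1 - p0; v <- p2 - p0
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

rand_beak_track <- function(n, seed) {
  set.seed(seed)
  labels <- c("beak_upper", "beak_lower", "beak_fulcrum")
  x <- matrix(runif(3 * n, -50, 50), n, 3, dimnames = list(NULL, labels))
  y <- matrix(runif(3 * n, -50, 50), n, 3)
  pose_track("r", x, y, matrix(1, n, 3))
}

test_that("beak distance matches hand values and the per-frame hypot oracle", {
  tr <- make_gap_track(c(0, 5))
  tr$x[1, "beak_upper"] <- 100; tr$y[1, "beak_upper"] <- 100
  tr$x[1, "beak_lower"] <- 103; tr$y[1, "beak_lower"] <- 104  # 3-4-5 triangle
  v <- bind_scheme(tr, toy_scheme())
  d <- beak_distance(v)
  expect_equal(d$values, c(5, 5))
  expect_equal(d$unit, "px")

  rt <- rand_beak_track(500, seed = 2)
  dv <- beak_distance(bind_scheme(rt, toy_scheme()))$values
  expect_equal(dv, hypot_oracle(rt$x[, 1], rt$y[, 1], rt$x[, 2], rt$y[, 2]))
})

test_that("beak distance is symmetric in the two landmarks and missing-propagating", {
  rt <- rand_beak_track(100, seed = 3)
  rt <- mask_cells(rt, "beak_upper", c(4L, 10L))
  sw <- bodypart_scheme(beak_upper = "beak_lower", beak_lower = "beak_upper",
                        beak_fulcrum = "beak_fulcrum")
  d1 <- beak_distance(bind_scheme(rt, toy_scheme()))$values
  d2 <- beak_distance(bind_scheme(rt, sw))$values
  expect_identical(d1, d2)
  expect_true(all(is.na(d1[c(5, 11)])))
})

test_that("beak angle reproduces right angles, rays and the clamped-arccos oracle", {
  mk <- function(p0, p1, p2) {
    labels <- c("beak_upper", "beak_lower", "beak_fulcrum")
    x <- matrix(c(p1[1], p2[1], p0[1]), 1, 3, dimnames = list(NULL, labels))
    y <- matrix(c(p1[2], p2[2], p0[2]), 1, 3)
    beak_angle(bind_scheme(pose_track("a", x, y, matrix(1, 1, 3)),
                           toy_scheme()))$values
  }
  expect_equal(mk(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(mk(c(0, 0), c(2, 1), c(4, 2)), 0)         # same ray
  expect_equal(mk(c(0, 0), c(2, 1), c(-4, -2)), 180)     # opposite rays
  expect_equal(mk(c(0, 0), c(10, 0), c(0, 30)), 90)      # scale invariance
  expect_true(is.na(mk(c(1, 1), c(1, 1), c(2, 2))))      # P1 at P0: undefined

  rt <- rand_beak_track(400, seed = 4)
  a <- beak_angle(bind_scheme(rt, toy_scheme()))$values
  oracle <- vapply(seq_len(400), function(i)
    acos_angle_oracle(c(rt$x[i, 3], rt$y[i, 3]),
                      c(rt$x[i, 1], rt$y[i, 1]),
                      c(rt$x[i, 2], rt$y[i, 2])), 0)
  expect_lt(max(abs(a - oracle)), 1e-9)
  expect_true(all(a >= 0 & a <= 180))
})

test_that("movement is the consecutive-frame displacement, strictly adjacent", {
  labels <- c("beak_upper", "beak_lower", "beak_fulcrum", "eye")
  x <- cbind(1, 1, 1, c(0, 3, 3, 3))
  y <- cbind(1, 2, 3, c(0, 4, 4, 4))
  colnames(x) <- colnames(y) <- labels
  tr <- pose_track("m", x, y, matrix(1, 4, 4, dimnames = list(NULL, labels)))
  sc <- bodypart_scheme("beak_upper", "beak_lower", "beak_fulcrum", eye_corner = "eye")
  mv <- movement(bind_scheme(tr, sc), "eye_corner")
  expect_equal(mv$values, c(5, 0, 0))
  expect_length(mv$values, n_frames(tr) - 1L)

  # masking frame 1 (0-based) kills both adjacent steps, no gap skipping
  tr2 <- mask_cells(tr, "eye", 1L)
  mv2 <- movement(bind_scheme(tr2, sc), "eye_corner")
  expect_true(all(is.na(mv2$values[1:2])))
  expect_equal(mv2$values[3], 0)
})

test_that("kinematics are translation-invariant; distance and movement scale, angle does not", {
  rt <- rand_beak_track(50, seed = 6)
  shift <- rt; shift$x <- rt$x + 123.5; shift$y <- rt$y - 42.25
  scaled <- rt; scaled$x <- rt$x * 3; scaled$y <- rt$y * 3
  v0 <- bind_scheme(rt, toy_scheme())
  vs <- bind_scheme(shift, toy_scheme())
  vk <- bind_scheme(scaled, toy_scheme())
  expect_equal(beak_distance(vs)$values, beak_distance(v0)$values)
  expect_equal(beak_angle(vs)$values, beak_angle(v0)$values)
  expect_equal(movement(vs, "beak_upper")$values, movement(v0, "beak_upper")$values)
  expect_equal(beak_distance(vk)$values, 3 * beak_distance(v0)$values)
  expect_equal(movement(vk, "beak_upper")$values, 3 * movement(v0, "beak_upper")$values)
  expect_equal(beak_angle(vk)$values, beak_angle(v0)$values, tolerance = 1e-12)
})

test_that("reference-point movement on noise-free synthetic data is identically zero", {
  p <- sim_params(n_embryos = 1, noise_sd = 0, embryo_sd = 0, dropout_rate = 0,
                  burst_rate = 0, outlier_rate = 0, bout_amp = 0)
  d <- sim_trial_design(p, "e01")
  sim <- simulate_trial(p, d, seed = 1)
  v <- bind_scheme(sim$track, sim_scheme(p), d)
  expect_true(all(movement(v, "egg_reference")$values == 0))
})
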