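test_that("post intervals start at clamp release and tile 30 s at the frame rate", {
  d <- trial_design("e01", 16,
                    data.frame(kind = c("Pinch", "Touch"),
                               onset_frame = c(8950, 30000),
                               release_frame = c(9000, 30050)),
                    baseline_duration = 120)
  seg <- segment_intervals(d, frame_rate = 50, n_frames = 40000)
  post <- seg[seg$stimulus == "Pinch" & seg$window == "Post", ]
  expect_equal(post$start_frame, c(9000, 10500, 12000, 13500))
  expect_equal(post$end_frame, c(10500, 12000, 13500, 15000))
  expect_equal(post$interval, c("0-30", "30-60", "60-90", "90-120"))
  # 120 s baseline -> exactly 4 pre-stimulus intervals, ending at onset
  pre <- seg[seg$stimulus == "Pinch" & seg$window == "Baseline", ]
  expect_equal(nrow(pre), 4L)
  expect_equal(pre$end_frame[4], 8950)
  expect_equal(pre$start_frame[1], 8950 - 4 * 1500)

  # generalizes to other frame rates: 750-frame intervals at 25 fps
  seg25 <- segment_intervals(d, frame_rate = 25, n_frames = 40000)
  expect_true(all(seg25$end_frame - seg25$start_frame == 750))

  expect_error(segment_intervals(d, 50, n_frames = 14000), "e01.*past the last frame")
})

test_that("a 3-min baseline yields six tiles but the baseline uses the last four", {
  p <- sim_params(n_embryos = 1, embryonic_day = 13)
  expect_equal(p$baseline_duration, 180)
  d <- sim_trial_design(p, "e01")
  seg <- segment_intervals(d, 50, sim_n_frames(p, d))
  expect_equal(sum(seg$stimulus == "Pinch" & seg$window == "Baseline"), 6L)
})

test_that("the >5% exclusion rule is strict at the boundary", {
  v <- rep(1, 1500)
  v75 <- v; v75[seq_len(75)] <- NA
  v76 <- v; v76[seq_len(76)] <- NA
  expect_false(is_interval_excluded(v75))
  expect_true(is_interval_excluded(v76))
  expect_false(is_interval_excluded(v))
})

test_that("imputation fills gaps with the pooled median of half-the-gap neighbours", {
  expect_equal(impute_interval(c(10, 20, NA, 30, 40)), c(10, 20, 25, 30, 40))
  # leading gap of 2: k = 1, one-sided -> nearest right value
  expect_equal(impute_interval(c(NA, NA, 7, 9, 11)), c(7, 7, 7, 9, 11))
  # gap of 3: k = 2 per side, pooled median of (2, 4, 100, 200)
  expect_equal(impute_interval(c(1, 2, 4, NA, NA, NA, 100, 200, 300))[4:6],
               rep(52, 3))
  # identity on complete data
  x <- c(5, 1, 4)
  expect_identical(impute_interval(x), x)
  expect_error(impute_interval(rep(NA_real_, 5)), "excluded")
})

test_that("imputation never alters observed values and leaves no missing", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    v <- rnorm(n)
    holes <- sample(n, sample.int(floor(n / 3), 1))
    vm <- v; vm[holes] <- NA
    if (all(is.na(vm))) next
    out <- impute_interval(vm)
    expect_false(anyNA(out))
    expect_identical(out[-holes], v[-holes])
  }
})

test_that("interval sums match a brute-force loop and refuse missing input", {
  expect_equal(interval_sum(rep(1, 1500)), 1500)
  set.seed(8)
  v <- runif(1500)
  brute <- 0; for (x in v) brute <- brute + x
  expect_equal(interval_sum(v), brute)
  expect_error(interval_sum(c(1, NA)), "missing")
})

test_that("the baseline is the median of the four pre-stimulus sums, dropping exclusions", {
  expect_equal(baseline_value(c(2, 4, 6, 100)), 5)
  expect_equal(baseline_value(c(2, 4, 6, NA)), 4)
  expect_equal(baseline_value(c(2, 4, 6, 100), excluded = c(FALSE, FALSE, FALSE, TRUE)), 4)
  expect_equal(baseline_value(rep(7, 4)), 7)
  expect_true(is.na(baseline_value(rep(NA_real_, 4))))
})

test_that("interval_summary excludes over-missing intervals and emits BL rows", {
  fr <- 50; L <- 1500
  d <- make_toy_design()
  n <- 30100
  gap <- rep(2, n)
  tr <- make_gap_track(gap, frame_rate = fr)
  # knock out 76 frames (>5%) of the Pinch 0-30 interval, 75 of 30-60
  rel <- d$stimuli$release_frame[d$stimuli$kind == "Pinch"]
  tr <- mask_cells(tr, "beak_upper", rel + 0:75)
  tr <- mask_cells(tr, "beak_upper", rel + L + 0:74)
  isum <- interval_summary(beak_distance(bind_scheme(tr, toy_scheme())), d, fr)
  p030 <- isum[isum$stimulus == "Pinch" & isum$interval == "0-30", ]
  p3060 <- isum[isum$stimulus == "Pinch" & isum$interval == "30-60", ]
  expect_true(p030$excluded)
  expect_true(is.na(p030$sum))
  expect_false(p3060$excluded)
  expect_equal(p3060$sum, 2 * L)  # imputed from a constant series
  bl <- isum[isum$interval == "BL", ]
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$sum, c(2 * L, 2 * L))
})

test_that("step-type series aggregate over the steps inside each interval", {
  fr <- 50
  d <- make_toy_design()
  n <- 30100
  labels <- c("beak_upper", "beak_lower", "beak_fulcrum", "eye")
  x <- matrix(rep(c(1, 1, 1, 5), each = n), n, 4, dimnames = list(NULL, labels))
  y <- x
  # eye moves 1 px per frame in x
  x[, "eye"] <- seq_len(n)
  tr <- pose_track("e01", x, y, matrix(1, n, 4, dimnames = list(NULL, labels)))
  sc <- bodypart_scheme("beak_upper", "beak_lower", "beak_fulcrum", eye_corner = "eye")
  mv <- movement(bind_scheme(tr, sc), "eye_corner")
  isum <- interval_summary(mv, d, fr)
  full <- isum[isum$interval != "BL", ]
  expect_true(all(full$sum == 1500))
})
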