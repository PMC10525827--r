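test_that("a well-formed three-header CSV parses into a complete track", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,beak_upper,beak_upper,beak_upper,beak_lower,beak_lower,beak_lower",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,1.5,2.5,0.9,3.5,4.5,0.8",
    "1,1.6,2.6,0.95,3.6,4.6,0.85"), path)
  tr <- read_pose_csv(path)
  expect_s3_class(tr, "pose_track")
  expect_equal(n_frames(tr), 2L)
  expect_equal(part_labels(tr), c("beak_upper", "beak_lower"))
  expect_false(any(missing_mask(tr)))
  expect_equal(tr$x[, "beak_lower"], c(3.5, 3.6))
  expect_equal(attr(tr, "parse_report")$malformed_cells, c(0L, 0L))
})

test_that("malformed and empty cells become masked entries, counted in the parse report", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net",
    "bodyparts,p1,p1,p1",
    "coords,x,y,likelihood",
    "0,1.0,2.0,0.9",
    "1,oops,2.0,0.9",
    "2,,,0"), path)
  tr <- read_pose_csv(path)
  expect_equal(n_frames(tr), 3L)
  expect_equal(unname(missing_mask(tr)[, 1]), c(FALSE, TRUE, TRUE))
  expect_equal(tr$likelihood[2:3, 1], c(0, 0))
  expect_equal(attr(tr, "parse_report")$malformed_cells, 1L)
})

test_that("format violations are rejected with informative errors", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bodyparts,p1,p1,p1", "coords,x,y,likelihood", "0,1,2,0.9"), p1)
  expect_error(read_pose_csv(p1), "header rows")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,n,n,n,n", "bodyparts,p1,p1,p1,p2",
               "coords,x,y,likelihood,x", "0,1,2,0.9,1"), p2)
  expect_error(read_pose_csv(p2), "triplet")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,n,n,n", "bodyparts,p1,p1,p1",
               "coords,x,y,likelihood", "0,1,2,1.2"), p3)
  expect_error(read_pose_csv(p3), "likelihood.*p1.*frame 0")
})

test_that("write then read is the identity, including masked cells and 0 frames", {
  tr <- make_toy_track(5)
  tr <- mask_cells(tr, "UpperBeakTip", c(1L, 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(tr, path)
  back <- read_pose_csv(path, trial_id = "toy")
  expect_true(isTRUE(all.equal(tr, back, check.attributes = FALSE)))
  expect_identical(missing_mask(tr), missing_mask(back))

  empty <- pose_track("none", matrix(numeric(), 0, 1, dimnames = list(NULL, "p1")),
                      matrix(numeric(), 0, 1), matrix(numeric(), 0, 1))
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(empty, p0)
  expect_length(readLines(p0), 3L)
  expect_equal(n_frames(read_pose_csv(p0)), 0L)
})

test_that("simulated cohort files round-trip field-for-field and are byte-stable", {
  params <- sim_params(n_embryos = 2, parts = c("beak_upper", "beak_lower",
                                                "beak_fulcrum"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(params, seed = 11, dir = file.path(d1, "c"))
  co2 <- simulate_cohort(params, seed = 11, dir = file.path(d2, "c"))
  f1 <- file.path(d1, "c", co1$manifest$pose_file[1])
  f2 <- file.path(d2, "c", co2$manifest$pose_file[1])
  expect_identical(readLines(f1), readLines(f2))
  back <- read_pose_csv(f1, trial_id = co1$tracks[[1]]$trial_id)
  expect_true(isTRUE(all.equal(co1$tracks[[1]], back, check.attributes = FALSE)))
})

test_that("trial designs survive a YAML round trip and enforce their invariants", {
  d <- make_toy_design()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_designs(list(d), path)
  back <- read_trial_designs(path)[[1]]
  expect_equal(back$stimuli, d$stimuli)
  expect_equal(back$baseline_duration, d$baseline_duration)

  expect_error(trial_design("e", 16, data.frame(
    kind = c("Pinch", "Pinch"), onset_frame = c(0, 10), release_frame = c(1, 11))),
    "one Pinch and one Touch")
  expect_error(trial_design("e", 16, data.frame(
    kind = c("Pinch", "Touch"), onset_frame = c(10, 20), release_frame = c(5, 21))),
    "release_frame")
  expect_error(trial_design("e", 10, data.frame(
    kind = c("Pinch", "Touch"), onset_frame = c(0, 10), release_frame = c(1, 11))),
    "embryonic_day")
})

test_that("schemes resolve roles, reject duplicates and enforce the ED9 tarsus rule", {
  tr <- make_toy_track(4)
  sc <- bodypart_scheme(beak_upper = "UpperBeakTip", beak_lower = "LowerBeakTip",
                        beak_fulcrum = "UpperBeakTip2")
  expect_error(bind_scheme(tr, sc), "UpperBeakTip2")

  expect_error(bodypart_scheme(beak_upper = "a", beak_lower = "a",
                               beak_fulcrum = "b"), "distinct")

  labels <- c("up", "lo", "ful", "meta")
  x <- matrix(1, 3, 4, dimnames = list(NULL, labels))
  tr2 <- pose_track("t", x, x, x * 0 + 1)
  sc2 <- bodypart_scheme("up", "lo", "ful", leg = "meta", leg_site = "metatarsus")
  expect_error(bind_scheme(tr2, sc2, embryonic_day = 9), "tarsus")
  sc3 <- bodypart_scheme("up", "lo", "ful", leg = "meta", leg_site = "tarsus")
  v <- bind_scheme(tr2, sc3, embryonic_day = 9)
  expect_equal(role_xy(v, "beak_upper")$x, tr2$x[, "up"])
})
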