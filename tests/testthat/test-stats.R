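test_that("the mixed model recovers constructed cell means and refuses one embryo", {
  ivs <- c("BL", "0-30", "30-60", "60-90", "90-120")
  means <- stats::setNames(seq(100, 190, by = 10), c(paste0("Pinch:", ivs),
                                                     paste0("Touch:", ivs)))
  two <- expand.grid(embryo_id = c("a", "b"), stimulus = c("Pinch", "Touch"),
                     interval = ivs, stringsAsFactors = FALSE)
  two$sum <- means[paste(two$stimulus, two$interval, sep = ":")]
  fit <- suppressWarnings(suppressMessages(fit_interval_model(two)))
  expect_equal(sort(coef(fit)), sort(means), tolerance = 1e-8,
               ignore_attr = "names")
  expect_equal(unname(coef(fit)[names(means)[1]]), unname(means[1]),
               tolerance = 1e-8)

  one <- two[two$embryo_id == "a", ]
  expect_error(fit_interval_model(one), "degenerate")
})

test_that("embryo-level offsets load on the random intercept, noise on the residual", {
  d <- make_interval_table(n_embryos = 24, noise_sd = 1, embryo_sd = 5,
                           effect = 0, seed = 42)
  fit <- fit_interval_model(d)
  s <- summary(fit)
  expect_gt(s$sd_embryo, 2.5)
  expect_equal(s$sd_residual, 1, tolerance = 0.25)
})

test_that("with zero effect, cell-mean differences stay within their confidence bands", {
  # 40 null cohorts: the 95% CI of each contrast should cover 0 ~95% of the time
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    d <- make_interval_table(n_embryos = 16, noise_sd = 1, embryo_sd = 2,
                             effect = 0, seed = 1000 + s)
    fit <- fit_interval_model(d)
    mc <- marginal_contrasts(fit, comparisons = list(c("Pinch:0-30", "Pinch:BL")),
                             adjust = "none")
    ci <- mc$estimate + c(-1, 1) * stats::qt(0.975, mc$df) * mc$SE
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
    total <- total + 1L
  }
  expect_gt(hits / total, 0.8)
})

test_that("marginal contrasts adjust over the family and flag at alpha", {
  d <- make_interval_table(n_embryos = 16, noise_sd = 1, embryo_sd = 2,
                           effect = 6, effect_intervals = "0-30", seed = 7)
  fit <- fit_interval_model(d)
  single <- marginal_contrasts(fit, comparisons = list(c("Pinch:0-30", "Pinch:BL")))
  expect_equal(single$p_adjusted, single$p_value, tolerance = 1e-6)

  fam <- marginal_contrasts(fit)
  expect_true(all(fam$p_adjusted >= fam$p_value - 1e-12))
  expect_true(all(fam$p_adjusted >= 0 & fam$p_adjusted <= 1))
  expect_identical(fam$significant, fam$p_adjusted < 0.05)
  hit <- fam[fam$comparison == "Pinch 0-30 vs Pinch BL", ]
  expect_true(hit$significant)
  expect_equal(hit$estimate, 6, tolerance = 1.5)
  # the adjusted p of that same comparison grows with the family size
  expect_gte(fam$p_adjusted[fam$comparison == "Pinch 0-30 vs Pinch BL"],
             single$p_adjusted - 1e-9)
  expect_error(marginal_contrasts(fit, comparisons = list(c("Pinch:0-30", "nope"))),
               "nope")
})

test_that("contrast results are invariant to embryo order and affine response rescaling", {
  d <- make_interval_table(n_embryos = 12, effect = 4, seed = 3)
  comps <- list(A = c("Pinch:0-30", "Pinch:BL"), B = c("Pinch:0-30", "Touch:0-30"))
  f1 <- marginal_contrasts(fit_interval_model(d), comps)
  d_shuf <- d[sample(nrow(d)), ]
  f2 <- marginal_contrasts(fit_interval_model(d_shuf), comps)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-6)
  d_aff <- d; d_aff$sum <- 3.5 * d$sum + 200
  f3 <- marginal_contrasts(fit_interval_model(d_aff), comps)
  expect_equal(f3$p_value, f1$p_value, tolerance = 1e-5)
  expect_equal(f3$estimate, 3.5 * f1$estimate, tolerance = 1e-6)

  p1 <- permutation_contrast(d, comps$A, n_perm = 500, seed = 9)
  p3 <- permutation_contrast(d_aff, comps$A, n_perm = 500, seed = 9)
  expect_identical(p1$p, p3$p)
})

test_that("permutation contrast handles degenerate input and validates n_perm", {
  d <- make_interval_table(n_embryos = 10, seed = 5)
  expect_error(permutation_contrast(d, c("Pinch:0-30", "Pinch:BL"), n_perm = 50),
               "at least 100")
  # identical condition vectors -> all differences zero -> p = 1
  d0 <- d
  d0$sum <- ave(d0$sum, d0$embryo_id, FUN = function(z) z[1])
  res <- permutation_contrast(d0, c("Pinch:0-30", "Pinch:BL"), n_perm = 200, seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$estimate, 0)
})

test_that("permutation power is high at effect = 3x noise SD with 16 embryos", {
  rejections <- 0L
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    d <- make_interval_table(n_embryos = 16, noise_sd = 1, embryo_sd = 2,
                             effect = 3, effect_intervals = "0-30",
                             seed = 2000 + s)
    res <- permutation_contrast(d, c("Pinch:0-30", "Pinch:BL"),
                                n_perm = 399, seed = s)
    rejections <- rejections + (res$p < 0.05)
  }
  expect_gt(rejections / n_rep, 0.9)
})

test_that("mixed-model and permutation routes agree on the sign of each difference", {
  d <- make_interval_table(n_embryos = 16, noise_sd = 1, embryo_sd = 2,
                           effect = 5, effect_intervals = c("0-30", "30-60"),
                           seed = 77)
  comps <- default_contrasts()
  mm <- marginal_contrasts(fit_interval_model(d), comps)
  pp <- permutation_contrast(d, comps, n_perm = 199, seed = 4)
  expect_identical(sign(mm$estimate), sign(pp$estimate))
  expect_true(all(pp$p_adjusted >= pp$p_value))
})
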