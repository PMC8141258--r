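mk_pd <- function(neg = 10, pos = 110, treated = 60,
                  endpoint = "IL-17", group = "treated:3") {
  pd_table(animal_id = sprintf("a%d", 1:3),
           group = c("negative_control", "positive_control", group),
           endpoint = endpoint,
           value = c(neg, pos, treated),
           trough_exposure = c(NA, NA, 120))
}

test_that("percent inhibition matches the control-anchored formula", {
  expect_equal(percent_inhibition(mk_pd(treated = 10), "IL-17",
                                  "treated:3")$percent_inhibition, 100)
  expect_equal(percent_inhibition(mk_pd(treated = 110), "IL-17",
                                  "treated:3")$percent_inhibition, 0)
  res <- percent_inhibition(mk_pd(treated = 60), "IL-17", "treated:3")
  expect_equal(res$percent_inhibition, 50)
  expect_equal(res$K1, 100)
  expect_equal(res$Y, 50)
  # overshoot below the negative control exceeds 100% and is not clipped
  expect_equal(percent_inhibition(mk_pd(treated = 0), "IL-17",
                                  "treated:3")$percent_inhibition, 110)
})

test_that("percent inhibition errors on degenerate controls or groups", {
  expect_error(percent_inhibition(mk_pd(neg = 10, pos = 10), "IL-17",
                                  "treated:3"), "K1 = 0")
  expect_error(percent_inhibition(mk_pd(), "IL-17", "treated:99"),
               "no group")
  expect_error(percent_inhibition(mk_pd(), "IL-99", "treated:3"),
               "no rows for endpoint")
})

test_that("percent inhibition is invariant to affine endpoint rescaling", {
  tab <- mk_pd(neg = 7, pos = 93, treated = 41)
  base <- percent_inhibition(tab, "IL-17", "treated:3")$percent_inhibition
  scaled <- pd_table(tab$animal_id, tab$group, tab$endpoint,
                     2.3 * tab$value + 17, tab$trough_exposure)
  expect_equal(percent_inhibition(scaled, "IL-17",
                                  "treated:3")$percent_inhibition, base)
})

test_that("noise-free Hill data is recovered exactly across a grid", {
  exposures <- c(5, 15, 40, 120, 350, 1000, 3000, 9000)
  for (ec50 in c(10, 120, 1000)) {
    for (h in c(0.5, 1, 2)) {
      inh <- 100 * exposures^h / (ec50^h + exposures^h)
      fit <- fit_hill(exposures, inh)
      expect_equal(fit$EC50, ec50, tolerance = 1e-6)
      expect_equal(fit$h, h, tolerance = 1e-6)
      expect_equal(fit$I_max, 100)
    }
  }
})

test_that("free-ceiling fits recover I_max too", {
  exposures <- c(10, 30, 100, 300, 1000)
  inh <- 80 * exposures^1.2 / (150^1.2 + exposures^1.2)
  fit <- fit_hill(exposures, inh, fix_imax = FALSE)
  expect_equal(fit$I_max, 80, tolerance = 1e-4)
  expect_equal(fit$EC50, 150, tolerance = 1e-4)
})

test_that("noisy Hill fits recover EC50 within 10% in the median", {
  exposures <- rep(c(10, 30, 60, 120, 240, 480, 1000, 2000), each = 1)
  truth <- 100 * exposures^1.5 / (120^1.5 + exposures^1.5)
  set.seed(123)
  est <- vapply(1:100, function(i) {
    fit_hill(exposures, truth + rnorm(length(truth), 0, 5))$EC50
  }, 0)
  expect_lt(abs(median(est) - 120) / 120, 0.10)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_hill(c(10, 10, 10), c(1, 2, 3)), "distinct exposures")
  expect_error(fit_hill(c(10, 20, 30), c(5, 5, 5)), "all inhibition")
  expect_error(fit_hill(c(-1, 10, 20), c(1, 2, 3)), "positive")
  expect_error(fit_hill(c(10, 20, 30), c(1, 2, 3), fix_imax = FALSE),
               ">= 4 distinct")
})

test_that("inhibition_at and exposure_at are mutual inverses", {
  exposures <- c(10, 50, 120, 500, 2000)
  inh <- 100 * exposures^1.5 / (120^1.5 + exposures^1.5)
  fit <- fit_hill(exposures, inh)
  expect_equal(inhibition_at(fit, fit$EC50), fit$I_max / 2,
               tolerance = 1e-9)
  for (c0 in c(3, 40, 120, 777, 5000)) {
    expect_equal(exposure_at(fit, inhibition_at(fit, c0)), c0,
                 tolerance = 1e-9)
  }
  expect_error(exposure_at(fit, 100), "strictly between")
  expect_error(inhibition_at(fit, -5), "positive")
  # monotone non-decreasing in exposure
  grid <- inhibition_at(fit, seq(1, 5000, length.out = 200))
  expect_true(all(diff(grid) >= 0))
})

test_that("the left-shifted two-curve landmark matches the closed form", {
  # IL-17 EC50 120, IL-22 EC50 600 (1:5), h = 1.5 for both
  exposures <- c(20, 60, 120, 300, 600, 1500, 4000)
  f17 <- fit_hill(exposures, 100 * exposures^1.5 / (120^1.5 + exposures^1.5))
  f22 <- fit_hill(exposures, 100 * exposures^1.5 / (600^1.5 + exposures^1.5))
  c90 <- exposure_at(f17, 90)
  # closed form: IL-22 inhibition at the IL-17 90% exposure
  expected <- 100 * c90^1.5 / (600^1.5 + c90^1.5)
  expect_equal(inhibition_at(f22, c90), expected, tolerance = 1e-6)
  expect_gt(inhibition_at(f22, c90), 40)  # still substantially inhibited
  expect_lt(inhibition_at(f22, c90), inhibition_at(f17, c90))
})

test_that("efficacy profiles floor negatives for display, keep raw", {
  sim <- gen_pd_table(1)
  prof <- efficacy_profile(sim$table)
  expect_equal(dim(prof), c(4L, 4L))
  expect_true(all(prof >= 0))
  raw <- attr(prof, "raw")
  expect_equal(dim(raw), dim(prof))

  # treated arm identical to the positive control -> 0% everywhere
  tab <- pd_table(sprintf("a%d", 1:3),
                  c("negative_control", "positive_control", "treated:1"),
                  "IL-17", c(10, 110, 110), c(NA, NA, 40))
  expect_equal(unname(efficacy_profile(tab)[1, 1]), 0)
})

test_that("planted suppression ordering IL-17 > IL-22 > Th2 is reproduced", {
  sim <- gen_pd_table(5, cv = 0.03)
  prof <- attr(efficacy_profile(sim$table), "raw")
  top <- "treated:30"
  expect_gt(prof["IL-17", top], prof["IL-22", top])
  expect_gt(prof["IL-22", top], prof["eosinophils", top])
})
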