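test_that("dcq input validation catches degenerate problems", {
  mx <- gen_mixture_foldchange(1)
  expect_s3_class(as.data.frame(dcq(mx$input, seed = 1)), "data.frame")

  fc <- setNames(rnorm(5), sprintf("G%05d", 1:5))
  expect_error(dcq_input(fc, mx$compendium), "fewer than 10")

  comp_const <- unclass(mx$compendium)
  comp_const[, 2] <- 1.0
  expect_error(dcq_input(mx$input$fold_change,
                         cell_compendium(comp_const)),
               "celltype02")
})

test_that("null fold changes give zero quantities; seeds reproduce", {
  mx <- gen_mixture_foldchange(2)
  fc0 <- setNames(numeric(length(mx$input$fold_change)),
                  names(mx$input$fold_change))
  q0 <- dcq(dcq_input(fc0, mx$compendium), seed = 5)
  expect_true(all(q0$quantity == 0))

  q1 <- dcq(mx$input, seed = 42)
  q2 <- dcq(mx$input, seed = 42)
  expect_identical(q1$quantity, q2$quantity)
  expect_identical(attr(q1, "per_repeat"), attr(q2, "per_repeat"))
})

test_that("noise-free 2-sparse mixtures are recovered", {
  mx <- gen_mixture_foldchange(7, n_genes = 500, n_cell_types = 10)
  q <- dcq(mx$input, repeats = 3, lambda_min_ratio = 0.2, seed = 11)
  est <- setNames(q$quantity, q$cell_type)
  supp_true <- names(mx$w_true)[mx$w_true != 0]
  supp_est <- names(est)[abs(est) > 1e-8]
  expect_setequal(supp_est, supp_true)
  rel_err <- abs(est[supp_true] - mx$w_true[supp_true]) /
    abs(mx$w_true[supp_true])
  expect_true(all(rel_err < 0.2))
})

test_that("raw penalized coefficients keep support but shrink", {
  mx <- gen_mixture_foldchange(7)
  q <- dcq(mx$input, seed = 11, debias = FALSE)
  est <- setNames(q$quantity, q$cell_type)
  supp_true <- names(mx$w_true)[mx$w_true != 0]
  expect_setequal(names(est)[abs(est) > 1e-8], supp_true)
  expect_true(all(abs(est[supp_true]) < abs(mx$w_true[supp_true])))
  expect_true(all(sign(est[supp_true]) == sign(mx$w_true[supp_true])))
})

test_that("quantities scale linearly with the fold-change vector", {
  mx <- gen_mixture_foldchange(8)
  q1 <- dcq(mx$input, seed = 3)$quantity
  scaled <- dcq_input(2.5 * mx$input$fold_change, mx$compendium)
  q2 <- dcq(scaled, seed = 3)$quantity
  expect_equal(q2, 2.5 * q1, tolerance = 1e-6)
})

test_that("support recovery stays good under noise (F1 >= 0.8)", {
  mx0 <- gen_mixture_foldchange(31, noise_sd = 0)
  signal_sd <- stats::sd(mx0$input$fold_change)
  mx <- gen_mixture_foldchange(31, noise_sd = 0.25 * signal_sd)
  q <- dcq(mx$input, seed = 13)
  est <- setNames(q$quantity, q$cell_type)
  supp_true <- names(mx$w_true)[mx$w_true != 0]
  supp_est <- names(est)[abs(est) > 1e-8]
  tp <- length(intersect(supp_est, supp_true))
  f1 <- 2 * tp / (length(supp_est) + length(supp_true))
  expect_gte(f1, 0.8)
})

test_that("repeat averaging reduces quantity dispersion across seeds", {
  mx <- gen_mixture_foldchange(19, noise_sd = 1)
  grab <- function(repeats, seed) {
    dcq(mx$input, repeats = repeats, seed = seed)$quantity[1]
  }
  sd1 <- stats::sd(vapply(1:20, function(s) grab(1L, s), 0))
  sd3 <- stats::sd(vapply(1:20, function(s) grab(3L, s), 0))
  expect_lt(sd3, sd1)
})

test_that("group averaging and the 2.0 filter boundary", {
  q <- function(vals) {
    structure(data.frame(cell_type = c("ct1", "ct2"), quantity = vals,
                         sd = 0),
              class = c("cell_quantities", "data.frame"))
  }
  per_sample <- list(s1 = q(c(1.0, 1.0)), s2 = q(c(3.0, 2.998)))
  groups <- c(s1 = "g", s2 = "g")
  # ct1 mean = 2.0 -> retained (boundary); ct2 mean = 1.999 -> removed
  gq <- group_average_and_filter(per_sample, groups, threshold = 2.0)
  expect_equal(rownames(gq), "ct1")
  expect_equal(attr(gq, "removed"), "ct2")
  expect_equal(unname(gq["ct1", "g"]), 2.0)

  # all-zero quantities vanish entirely
  zeroes <- list(s1 = q(c(0, 0)), s2 = q(c(0, 0)))
  gq0 <- group_average_and_filter(zeroes, groups)
  expect_equal(nrow(gq0), 0L)

  # absolute-value semantics keep strongly negative cell types
  negs <- list(s1 = q(c(-3, 1)), s2 = q(c(-3, 1)))
  gqn <- group_average_and_filter(negs, groups)
  expect_equal(rownames(gqn), "ct1")
  # signed semantics delete them
  gqs <- group_average_and_filter(negs, groups, signed = TRUE)
  expect_equal(nrow(gqs), 0L)

  expect_error(group_average_and_filter(per_sample, c(s1 = "g")),
               "ungrouped")
})

test_that("a cell type elevated in one group survives the filter", {
  mk_q <- function(vals) {
    structure(data.frame(cell_type = sprintf("ct%d", seq_along(vals)),
                         quantity = vals, sd = 0),
              class = c("cell_quantities", "data.frame"))
  }
  # 3 groups x 2 samples; ct1 elevated only in "disease", ct2 flat small
  per_sample <- list(
    a1 = mk_q(c(5.0, 0.3)), a2 = mk_q(c(5.4, 0.1)),
    b1 = mk_q(c(0.2, 0.2)), b2 = mk_q(c(0.0, 0.4)),
    c1 = mk_q(c(0.1, 0.3)), c2 = mk_q(c(0.3, 0.2)))
  groups <- c(a1 = "disease", a2 = "disease", b1 = "vehicle",
              b2 = "vehicle", c1 = "naive", c2 = "naive")
  gq <- group_average_and_filter(per_sample, groups)
  expect_equal(rownames(gq), "ct1")
  expect_equal(attr(gq, "removed"), "ct2")
})

test_that("z-score transform standardizes rows and drops constants", {
  gq <- matrix(c(1, 2, 3,
                 5, 5, 5), 2, 3, byrow = TRUE,
               dimnames = list(c("ct1", "ct2"), c("g1", "g2", "g3")))
  expect_warning(z <- zscore_by_celltype(gq), "constant row")
  expect_equal(unname(z["ct1", ]), c(-1, 0, 1))
  expect_false("ct2" %in% rownames(z))

  set.seed(77)
  big <- matrix(rnorm(40), 8, 5,
                dimnames = list(sprintf("ct%d", 1:8), sprintf("g%d", 1:5)))
  z2 <- zscore_by_celltype(big)
  expect_lt(max(abs(rowMeans(z2))), 1e-10)
  expect_lt(max(abs(apply(z2, 1, sd) - 1)), 1e-10)

  expect_error(zscore_by_celltype(gq[, 1, drop = FALSE]), ">= 2 groups")
})
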