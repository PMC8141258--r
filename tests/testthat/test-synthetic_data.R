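test_that("generators are pure functions of their seed", {
  expect_identical(gen_deg_studies(4, n_genes = 200),
                   gen_deg_studies(4, n_genes = 200))
  expect_identical(gen_cohort_matrix(4, n_samples = 20),
                   gen_cohort_matrix(4, n_samples = 20))
  expect_identical(gen_mixture_foldchange(4, n_genes = 120,
                                          n_cell_types = 4L,
                                          markers_per_type = 10L),
                   gen_mixture_foldchange(4, n_genes = 120,
                                          n_cell_types = 4L,
                                          markers_per_type = 10L))
  expect_identical(gen_ranked_planting(4, n_genes = 300,
                                       marker_ranks = 1:10),
                   gen_ranked_planting(4, n_genes = 300,
                                       marker_ranks = 1:10))
  expect_identical(gen_pd_table(4, cv = 0.1), gen_pd_table(4, cv = 0.1))
  # different seeds differ
  expect_false(identical(gen_cohort_matrix(4, n_samples = 20),
                         gen_cohort_matrix(5, n_samples = 20)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_deg_studies(1, n_genes = 50))
  expect_identical(runif(1), before)
})

test_that("DEG studies hit the requested between-study correlation", {
  studies <- gen_deg_studies(6, n_studies = 2, n_genes = 2000, rho = 0.7)
  r <- correlate_pair(studies[[1]], studies[[2]])$r
  expect_lt(abs(r - 0.7), 0.05)

  indep <- gen_deg_studies(6, n_studies = 2, n_genes = 2000, rho = 0)
  r0 <- correlate_pair(indep[[1]], indep[[2]])$r
  expect_lt(abs(r0), 0.06)

  expect_error(gen_deg_studies(1, rho = 1), "rho")
  expect_error(gen_deg_studies(1, rho = -0.2), "rho")
})

test_that("generated adjusted p-values are valid BH outputs", {
  tab <- gen_deg_studies(8, n_studies = 1, n_genes = 500)[[1]]
  expect_equal(tab$p_adj_fdr, stats::p.adjust(tab$p, method = "BH"))
  ord <- order(tab$p)
  expect_true(all(diff(tab$p_adj_fdr[ord]) >= -1e-15))
  expect_true(all(tab$p_adj_fdr >= tab$p))
})

test_that("cohort generator plants the requested high fraction", {
  co <- gen_cohort_matrix(10, n_samples = 60, planted_fraction = 0.4,
                          shift = 2)
  expect_equal(sum(co$truth == "high"), 24L)
  expect_equal(dim(co$matrix), c(200L, 60L))
  # planted samples really are shifted on the signature genes
  sig_mean_high <- mean(unclass(co$matrix)[default_th17_signature,
                                           co$truth == "high"])
  sig_mean_low <- mean(unclass(co$matrix)[default_th17_signature,
                                          co$truth == "low"])
  expect_gt(sig_mean_high - sig_mean_low, 1.5)
  expect_error(gen_cohort_matrix(1, n_samples = 5,
                                 planted_fraction = 0.1),
               "< 1")
})

test_that("mixture generator exposes its ground truth consistently", {
  mx <- gen_mixture_foldchange(3, noise_sd = 0)
  reconstructed <- as.vector(unclass(mx$compendium) %*% mx$w_true)
  expect_equal(unname(mx$input$fold_change), reconstructed,
               tolerance = 1e-12)
  # zero weights give a zero fold-change vector
  mx0 <- gen_mixture_foldchange(3, w_true = rep(0, 10), noise_sd = 0)
  expect_true(all(mx0$input$fold_change == 0))
  expect_error(gen_mixture_foldchange(1, n_genes = 5, n_cell_types = 10),
               "more genes")
})

test_that("planted rankings land markers at the stated ranks", {
  pl <- gen_ranked_planting(21, n_genes = 2500,
                            marker_ranks = c(1, 100, 101, 2000, 2400))
  rk <- rank_genes(pl$table, top_n = 2500)
  expect_equal(rk$gene[pl$ranks], pl$markers)
  expect_error(gen_ranked_planting(1, n_genes = 10, marker_ranks = c(1, 11)),
               "in range")
})

test_that("zero-noise PD tables reproduce the Hill truth exactly", {
  sim <- gen_pd_table(30, cv = 0)
  prof <- attr(efficacy_profile(sim$table), "raw")
  grid <- sim$truth$grid
  for (i in seq_len(nrow(grid))) {
    g <- sprintf("treated:%g", grid$dose[i])
    expect_equal(unname(prof[grid$endpoint[i], g]),
                 grid$true_inhibition[i], tolerance = 1e-9)
  }
  # default design sizes: saline 6, challenge 8, dosed arms 8
  il17 <- sim$table[sim$table$endpoint == "IL-17", ]
  expect_equal(sum(il17$group == "negative_control"), 6L)
  expect_equal(sum(il17$group == "positive_control"), 8L)
  expect_equal(sum(il17$group == "treated:3"), 8L)
})

test_that("noisy PD estimates track the truth across replicate seeds", {
  ests <- vapply(1:30, function(s) {
    sim <- gen_pd_table(s, cv = 0.05)
    prof <- attr(efficacy_profile(sim$table), "raw")
    unname(prof["IL-17", "treated:3"])
  }, 0)
  truth <- gen_pd_table(1, cv = 0)$truth$grid
  target <- truth$true_inhibition[truth$endpoint == "IL-17" &
                                    truth$dose == 3]
  expect_lt(abs(mean(ests) - target), 3)
})
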