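test_that("posterior_positive handles degenerate and symmetric cases", {
  m_half <- make_naive_model(1, 1, 10, 1, pi2 = 0.5)
  # identical components: posterior equals the positive prior for every y
  m_same <- make_naive_model(5, 2, 5, 2, pi2 = 0.3)
  expect_equal(posterior_positive(m_same, 0:50, rep(1000, 51)),
               rep(0.3, 51), tolerance = 1e-12)
  # degenerate priors
  expect_equal(posterior_positive(make_naive_model(1, 1, 10, 1, 1e-300),
                                  5, 1000), 0, tolerance = 1e-12)
  expect_equal(posterior_positive(make_naive_model(1, 1, 10, 1,
                                                   1 - 1e-16), 5, 1000),
               1, tolerance = 1e-12)
  # hand-evaluated Bayes rule from the pmf closed form
  expect_equal(posterior_positive(m_half, 5, 1000),
               oracle_posterior(0.5, 1, 1, 10, 1, 5), tolerance = 1e-12)
})

test_that("hard_class and expected_errors follow their definitions", {
  expect_identical(hard_class(c(0.51, 0.5, 0.49)), c(1L, 0L, 0L))
  expect_equal(expected_errors(c(0, 1, 1, 0)), 0)
  expect_equal(expected_errors(c(0.5, 0.5)), 1.0)
  expect_equal(expected_errors(c(0.9, 0.2, 0.6)), 0.7)
})

test_that("fit_em recovers naive mixture parameters and is monotone", {
  d <- sample_naive_mixture(4000, mu1 = 20, nu1 = 5, mu2 = 2000, nu2 = 10,
                            pi2 = 0.4, seed = 31)
  x <- rep(1800L, 4000)
  pos <- initial_clusters(d$y, seed = 31)
  fit <- fit_em(d$y, x, pos, variant = "naive")
  expect_true(fit$converged)
  expect_equal(fit$pi[2], 0.4, tolerance = 0.03)
  expect_equal(exp(fit$comp_neg$alpha), 20, tolerance = 0.1 * 20)
  expect_equal(exp(fit$comp_pos$alpha), 2000, tolerance = 0.1 * 2000)
  expect_nondecreasing(fit$loglik_trace)
  expect_gte(fit$loglik,
             fit$loglik_trace[1] - 1e-8 * (abs(fit$loglik_trace[1]) + 1))
})

test_that("fit_em errors on one-component data (collapse)", {
  set.seed(32)
  y <- rnbinom(1500, size = 5, mu = 50)
  x <- rep(1000L, 1500)
  pos <- initial_clusters(y, seed = 32)
  expect_error(fit_em(y, x, pos, variant = "naive", hto = "HTO_X"),
               "HTO_X")
})

test_that("fit_em is invariant under droplet permutation", {
  sim <- generate_dataset(m = 800, n = 1, seed = 33,
                          class_probs = list(msm = 0, negative = 0.6))
  y <- sim$experiment$counts[, 1]
  x <- sim$experiment$detected_genes
  pos <- initial_clusters(y, seed = 33)
  f1 <- fit_em(y, x, pos, variant = "pos_only")
  set.seed(2); perm <- sample(length(y))
  f2 <- fit_em(y[perm], x[perm], pos[perm], variant = "pos_only")
  expect_equal(f1$pi, f2$pi, tolerance = 1e-8)
  expect_equal(f1$comp_pos$alpha, f2$comp_pos$alpha, tolerance = 1e-6)
  expect_equal(f1$comp_pos$beta, f2$comp_pos$beta, tolerance = 1e-6)
  expect_equal(f1$posterior[perm], f2$posterior, tolerance = 1e-8)
})

test_that("outliers are excluded from fitting but still classified", {
  sim <- generate_dataset(m = 600, n = 1, seed = 34,
                          class_probs = list(msm = 0, negative = 0.6))
  y <- sim$experiment$counts[, 1]
  x <- sim$experiment$detected_genes
  prep <- preprocess_hto(y, x, seed = 34)
  fit <- fit_em(y, x, prep$positive_mask,
                fit_mask = !prep$outlier_mask, variant = "naive")
  expect_length(fit$posterior, length(y))
  expect_false(anyNA(fit$posterior))
})

test_that("variant restrictions on the slopes hold", {
  sim <- generate_dataset(m = 900, n = 1, seed = 35,
                          class_probs = list(msm = 0, negative = 0.6))
  y <- sim$experiment$counts[, 1]
  x <- sim$experiment$detected_genes
  pos <- initial_clusters(y, seed = 35)
  fn <- fit_em(y, x, pos, variant = "naive")
  expect_identical(c(fn$comp_neg$beta, fn$comp_pos$beta), c(0, 0))
  fp <- fit_em(y, x, pos, variant = "pos_only")
  expect_identical(fp$comp_neg$beta, 0)
  expect_false(fp$comp_pos$beta == 0)
})

test_that("fit_best_model selects by the expected-error criterion", {
  sim <- generate_dataset(m = 1200, n = 1, seed = 36,
                          class_probs = list(msm = 0, negative = 0.6))
  y <- sim$experiment$counts[, 1]
  x <- sim$experiment$detected_genes
  prep <- preprocess_hto(y, x, seed = 36)
  best <- fit_best_model(y, x, prep$positive_mask,
                         fit_mask = !prep$outlier_mask)
  sel <- best$selection
  crit_best <- sel$expected_errors[sel$variant == best$variant]
  ok <- !is.na(sel$expected_errors) & sel$converged %in% TRUE
  expect_true(all(crit_best <= sel$expected_errors[ok] + 1e-9))
  # the returned criterion was computed over the non-outlier droplets
  expect_equal(crit_best,
               expected_errors(best$posterior[!prep$outlier_mask]),
               tolerance = 1e-12)
})

test_that("model selection prefers regression models when beta_pos > 0", {
  # scaled-down replicate: 9 seeds instead of 20, majority vote
  picks <- vapply(1:9, function(s) {
    sim <- generate_dataset(m = 1000, n = 1, seed = 400 + s,
                            signal_params = list(alpha = log(300) -
                                                   0.6 * log(1800),
                                                 beta = 0.6, nu = 8),
                            class_probs = list(msm = 0, negative = 0.6))
    y <- sim$experiment$counts[, 1]
    x <- sim$experiment$detected_genes
    prep <- preprocess_hto(y, x, seed = s)
    fit_best_model(y, x, prep$positive_mask,
                   fit_mask = !prep$outlier_mask)$variant
  }, character(1))
  expect_gte(sum(picks %in% c("pos_only", "full")), 5)
})

test_that("mixture models serialize to JSON", {
  sim <- generate_dataset(m = 500, n = 1, seed = 37,
                          class_probs = list(msm = 0, negative = 0.5))
  y <- sim$experiment$counts[, 1]
  x <- sim$experiment$detected_genes
  fit <- fit_em(y, x, initial_clusters(y, seed = 37), variant = "naive",
                hto = "HTO1")
  path <- withr::local_tempfile(fileext = ".json")
  mixture_to_json(fit, path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$variant, "naive")
  expect_equal(obj$pi[2], fit$pi[2], tolerance = 1e-12)
  expect_equal(obj$comp_pos$nu, fit$comp_pos$nu, tolerance = 1e-12)
})
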