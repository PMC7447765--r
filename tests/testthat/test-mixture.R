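stem_params <- list(pi1 = 0.375, sigma0 = 0.261, sigma1 = 1.109)

test_that("EM log-likelihood trace is non-decreasing and the fit is label-ordered", {
  x <- generate_mixture_sample(0.3, 0.3, 1.2, 500, seed = 2)$effects
  fit <- fit_scale_mixture(x)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_lte(fit$params$sigma0, fit$params$sigma1)
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
})

test_that("swapping the initial component labels yields the identical reported fit", {
  x <- generate_mixture_sample(0.3, 0.3, 1.2, 400, seed = 9)$effects
  f1 <- fit_scale_mixture(x, init = list(sigma0 = 0.5 * sd(x), sigma1 = 2 * sd(x)))
  f2 <- fit_scale_mixture(x, init = list(sigma0 = 2 * sd(x), sigma1 = 0.5 * sd(x)))
  expect_equal(f1$params$pi1, f2$params$pi1, tolerance = 1e-3)
  expect_equal(f1$params$sigma0, f2$params$sigma0, tolerance = 1e-3)
  expect_equal(f1$params$sigma1, f2$params$sigma1, tolerance = 1e-3)
})

test_that("a single-Gaussian sample collapses to near-equal component SDs", {
  set.seed(5)
  x <- rnorm(800)
  fit <- fit_scale_mixture(x)
  # pi1 is unidentifiable here; the fit cannot beat the single-Gaussian
  # likelihood by more than optimisation slack
  single_ll <- sum(dnorm(x, 0, sqrt(mean(x^2)), log = TRUE))
  expect_gte(fit$loglik, single_ll - 1e-6)
  expect_lt(fit$loglik - single_ll, 3)
})

test_that("EM attains the grid-search optimum on a small sample", {
  x <- generate_mixture_sample(0.35, 0.3, 1.1, 40, seed = 17)$effects
  fit <- fit_scale_mixture(x)
  grid_best <- grid_search_mixture(x, fit$params)
  expect_gte(fit$loglik, grid_best - 1e-3)
})

test_that("EM recovers generating parameters from a large sample", {
  s <- generate_mixture_sample(stem_params$pi1, stem_params$sigma0,
                               stem_params$sigma1, 20000, seed = 12)
  fit <- fit_scale_mixture(s$effects)
  expect_lt(abs(fit$params$pi1 - 0.375), 0.03)
  expect_lt(abs(fit$params$sigma0 - 0.261), 0.02)
  expect_lt(abs(fit$params$sigma1 - 1.109), 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_scale_mixture(rep(1.3, 50)),
               class = "cellmixde_degenerate_error")
  expect_error(fit_scale_mixture(rnorm(5)),
               class = "cellmixde_degenerate_error")
})

test_that("the DE posterior is the closed-form two-component responsibility", {
  # direct density evaluation as the oracle
  xs <- c(-2, -0.5, 0, 0.3, 1, 3)
  with(stem_params, {
    oracle <- pi1 * dnorm(xs, 0, sigma1) /
      (pi1 * dnorm(xs, 0, sigma1) + (1 - pi1) * dnorm(xs, 0, sigma0))
    expect_equal(posterior_de(xs, stem_params), oracle, tolerance = 1e-12)
  })
  # at x = 0 the responsibility reduces to (pi/s1) / (pi/s1 + (1-pi)/s0)
  p0 <- (0.375 / 1.109) / (0.375 / 1.109 + 0.625 / 0.261)
  expect_equal(posterior_de(0, stem_params), p0, tolerance = 1e-12)
  expect_equal(p0, 0.124, tolerance = 0.005)
  expect_gt(posterior_de(3, stem_params), 0.999)
})

test_that("the posterior is symmetric and monotone in |x|", {
  xs <- seq(0, 4, by = 0.01)
  p_pos <- posterior_de(xs, stem_params)
  p_neg <- posterior_de(-xs, stem_params)
  expect_equal(p_pos, p_neg, tolerance = 1e-14)
  expect_true(all(diff(p_pos) >= -1e-12))
  # equal SDs: densities cancel, posterior is identically pi1
  flat <- list(pi1 = 0.3, sigma0 = 0.7, sigma1 = 0.7)
  expect_equal(posterior_de(c(-5, 0, 2), flat), rep(0.3, 3), tolerance = 1e-12)
})

test_that("classification is an |effect| threshold rule with the closed-form cutoff", {
  cutoff <- de_threshold(stem_params, 0.8)
  oracle <- uniroot(function(x) posterior_de(x, stem_params) - 0.8,
                    c(1e-6, 10), tol = 1e-10)$root
  expect_equal(cutoff, oracle, tolerance = 1e-6)
  expect_equal(cutoff, 0.69, tolerance = 0.01)
  s <- generate_mixture_sample(0.375, 0.261, 1.109, 2000, seed = 3)
  x <- setNames(s$effects, sprintf("g%04d", seq_along(s$effects)))
  fit <- fit_scale_mixture(x)
  calls <- classify_and_fdr(fit, x, threshold = 0.8)
  by_rule <- names(x)[abs(x) > calls$cutoff]
  expect_setequal(names(calls$de_genes), by_rule)
  expect_equal(unname(calls$de_genes), unname(sign(x[names(calls$de_genes)])))
})

test_that("the model FDR is bounded by 1 - threshold and undefined when empty", {
  s <- generate_mixture_sample(0.375, 0.261, 1.109, 3000, seed = 6)
  x <- setNames(s$effects, sprintf("g%04d", seq_along(s$effects)))
  fit <- fit_scale_mixture(x)
  for (thr in c(0.5, 0.8, 0.95)) {
    calls <- classify_and_fdr(fit, x, threshold = thr)
    expect_gt(calls$n_de, 0)
    expect_lt(calls$fdr, 1 - thr)
  }
  # an empty call set: posteriors all below threshold
  nearly_flat <- structure(
    list(params = list(pi1 = 0.2, sigma0 = 0.9, sigma1 = 1.0),
         posteriors = posterior_de(x, list(pi1 = 0.2, sigma0 = 0.9, sigma1 = 1.0)),
         loglik = 0, loglik_trace = 0, n_iterations = 1L, converged = TRUE),
    class = "mixture_fit")
  empty <- classify_and_fdr(nearly_flat, x, threshold = 0.8)
  expect_equal(empty$n_de, 0)
  expect_true(is.na(empty$fdr))
  expect_error(classify_and_fdr(fit, x, threshold = 1.2),
               class = "cellmixde_param_error")
})

test_that("the overall FDR is the DE-count-weighted mean of per-population FDRs", {
  one <- list(list(n_de = 100, fdr = 0.05))
  expect_equal(overall_fdr(one), 0.05)
  two <- list(list(n_de = 50, fdr = 0.02), list(n_de = 50, fdr = 0.04))
  expect_equal(overall_fdr(two), 0.03)
  with_empty <- c(two, list(list(n_de = 0, fdr = NA_real_)))
  expect_equal(overall_fdr(with_empty), 0.03)
  expect_true(is.na(overall_fdr(list(list(n_de = 0, fdr = NA_real_)))))
})

test_that("EM recovery holds across all four reference parameter sets", {
  tab <- reference_mixture_table()
  for (j in seq_len(nrow(tab))) {
    ests <- sapply(1:3, function(k) {
      s <- generate_mixture_sample(tab$pi1[j], tab$sigma0[j], tab$sigma1[j],
                                   20000, seed = 1000 * j + k)
      fit <- fit_scale_mixture(s$effects)
      c(fit$params$pi1, fit$params$sigma0, fit$params$sigma1)
    })
    truth <- c(tab$pi1[j], tab$sigma0[j], tab$sigma1[j])
    expect_lt(max(abs(rowMeans(ests) - truth) / truth), 0.15)
  }
})
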