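# Small crossed designs used throughout.
toy_dataset <- function(n_genes = 6, reps = c(A = 2, B = 2),
                        var_sample = 0.5, var_gene = 4, var_gc = 1,
                        var_resid = 0.2, seed = 42) {
  cfg <- generator_config(n_genes = n_genes, populations = reps,
                          grand_mean = 5, var_sample = var_sample,
                          var_gene = var_gene,
                          gene_cellpop_mode = "gaussian",
                          var_gene_cellpop = var_gc,
                          var_resid = var_resid, seed = seed)
  generate_dataset(cfg)$dataset
}

test_that("a constant dataset yields zero variance components and the constant mean", {
  m <- matrix(4.2, 5, 4, dimnames = list(paste0("g", 1:5), paste0("a", 1:4)))
  ds <- expression_dataset(m, setNames(c("P1", "P1", "P2", "P2"),
                                       colnames(m)))
  fit <- fit_reml(ds)
  expect_true(fit$converged)
  expect_equal(fit$variance_components$estimate, rep(0, 4))
  expect_equal(fit$fixed_effects$estimate[1], 4.2)
  expect_true(all(extract_gene_cellpop_effects(fit) == 0))
  ft <- test_cellpop_effect(fit)
  expect_equal(ft$f_statistic, 0)
  expect_equal(ft$p_value, 1)
})

test_that("sparse restricted log-likelihood matches the dense textbook formula", {
  ds <- toy_dataset()
  for (vc in list(c(0.5, 4, 1, 0.2), c(0.1, 1, 0.3, 1), c(2, 0.5, 2, 0.05))) {
    expect_equal(reml_loglik_vc(vc, ds), dense_reml_loglik(vc, ds),
                 tolerance = 1e-8)
  }
})

test_that("REML estimates agree with an independent dense optimisation", {
  ds <- toy_dataset(seed = 7)
  fit <- fit_reml(ds, se = FALSE)
  est <- setNames(fit$variance_components$estimate,
                  fit$variance_components$component)
  oracle <- dense_reml_fit(ds, start = c(0.5, 4, 1, 0.2))
  expect_equal(unname(est), unname(oracle), tolerance = 1e-3)
  # and the reported restricted log-likelihood is the value of the
  # restricted likelihood at the optimum
  expect_equal(fit$reml_loglik, dense_reml_loglik(est, ds), tolerance = 1e-6)
})

test_that("REML equals closed-form ANOVA estimators on a balanced design", {
  # Large, well-separated variances give an interior solution.
  ds <- toy_dataset(n_genes = 8, reps = c(A = 3, B = 3, C = 3),
                    var_sample = 1.5, var_gene = 6, var_gc = 2,
                    var_resid = 0.1, seed = 31)
  ems <- anova_ems_estimators(ds)
  expect_true(all(ems > 0)) # interior: equivalence precondition
  fit <- fit_reml(ds, se = FALSE)
  est <- setNames(fit$variance_components$estimate,
                  fit$variance_components$component)
  expect_equal(est, ems, tolerance = 1e-4)
})

test_that("gene-by-population BLUPs match a direct mixed-model-equation solve", {
  ds <- toy_dataset(seed = 13)
  fit <- fit_reml(ds, se = FALSE)
  est <- pmax(fit$variance_components$estimate, 1e-10)
  sol <- reml_loglik_vc(est, ds, solution = TRUE)
  expect_equal(as.vector(fit$gene_cellpop_blups),
               unname(sol$u$var_gene_cellpop), tolerance = 1e-6)
  expect_equal(unname(fit$gene_blups), unname(sol$u$var_gene),
               tolerance = 1e-6)
  expect_equal(fit$fixed_effects$estimate, unname(sol$beta), tolerance = 1e-6)
})

test_that("BLUPs shrink the interaction-space deviations by the closed-form factor", {
  # In a balanced design the interaction contrasts are orthogonal to every
  # other stratum, so there the BLUP is a uniform shrink of the raw two-way
  # deviation with factor var_gc / (var_gc + var_resid / a). (The
  # gene-average component of the interaction is allocated to the gene term
  # instead, so the full BLUP matrix is not a single rescaling of the raw
  # deviations.)
  ds <- toy_dataset(n_genes = 10, reps = c(A = 3, B = 3), seed = 19)
  fit <- fit_reml(ds, se = FALSE)
  blup <- extract_gene_cellpop_effects(fit, shrunken = TRUE)
  raw <- extract_gene_cellpop_effects(fit, shrunken = FALSE)
  dc <- function(m) sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m) - mean(m))
  blup_int <- dc(blup)
  expect_true(all(abs(blup_int) <= abs(raw) + 1e-10))
  lambda <- as.vector(blup_int) / as.vector(raw)
  expect_true(all(lambda > 0 & lambda < 1))
  expect_lt(diff(range(lambda)), 1e-6) # balanced design: a single factor
  est <- setNames(fit$variance_components$estimate,
                  fit$variance_components$component)
  lambda_closed <- est["var_gene_cellpop"] /
    (est["var_gene_cellpop"] + est["var_resid"] / 3)
  expect_equal(mean(lambda), unname(lambda_closed), tolerance = 1e-4)
})

test_that("BLUPs track the generating gene-by-population effects at study scale", {
  sim <- generate_dataset(reference_config(n_genes = 2000, seed = 3))
  fit <- fit_reml(sim$dataset, se = FALSE)
  eff <- extract_gene_cellpop_effects(fit)
  truth <- sim$truth$gene_cellpop_effects
  expect_gt(cor(as.vector(eff), as.vector(truth)), 0.75)
  # the gene-average part of the interaction is absorbed by the gene term,
  # so the BLUPs track the row-centred truth even more closely
  truth_centred <- sweep(truth, 1, rowMeans(truth))
  expect_gt(cor(as.vector(eff), as.vector(truth_centred)), 0.9)
  # shrunken zero-mean random effects: columns sum to ~0
  expect_true(all(abs(colSums(eff)) / nrow(eff) < 1e-6))
})

test_that("estimates are invariant to permuting genes and arrays", {
  ds <- toy_dataset(seed = 23)
  fit <- fit_reml(ds, se = FALSE)
  g_perm <- sample(rownames(ds$values))
  a_perm <- sample(colnames(ds$values))
  ds2 <- expression_dataset(ds$values[g_perm, a_perm],
                            ds$array_population[a_perm],
                            populations = ds$populations)
  fit2 <- fit_reml(ds2, se = FALSE)
  expect_equal(fit$variance_components$estimate,
               fit2$variance_components$estimate, tolerance = 1e-6)
  expect_equal(fit$gene_cellpop_blups[g_perm, ],
               fit2$gene_cellpop_blups, tolerance = 1e-6)
})

test_that("variance-component SEs come from a sane observed information", {
  ds <- toy_dataset(n_genes = 30, reps = c(A = 3, B = 3), seed = 5)
  fit <- fit_reml(ds, se = TRUE)
  se <- fit$variance_components$se
  est <- fit$variance_components$estimate
  interior <- est > 1e-6
  expect_true(all(is.finite(se[interior])))
  expect_true(all(se[interior] > 0))
})

test_that("under-identified or invalid designs are rejected with named causes", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
  # one array per population: interaction confounded with residual
  ds1 <- expression_dataset(m, setNames(paste0("P", 1:4), colnames(m)))
  expect_error(fit_reml(ds1), class = "cellmixde_design_error")
  # a single population
  ds2 <- expression_dataset(m, setNames(rep("P1", 4), colnames(m)))
  expect_error(fit_reml(ds2), class = "cellmixde_design_error")
})

test_that("a strong population shift is detected by the Wald F-test", {
  ds <- toy_dataset(n_genes = 12, reps = c(A = 3, B = 3), seed = 2)
  v <- ds$values
  v[, 4:6] <- v[, 4:6] + 50
  ds_shift <- expression_dataset(v, ds$array_population,
                                 populations = ds$populations)
  ft <- test_cellpop_effect(fit_reml(ds_shift, se = FALSE))
  expect_lt(ft$p_value, 0.001)
  expect_equal(ft$denominator_df, 4) # arrays - populations
})

test_that("the population F-test holds its nominal size under the null", {
  # 200 simulated null datasets at reduced gene count; rejection rate at the
  # 0.05 level should sit within binomial error of 0.05.
  n_rep <- 200
  rej <- logical(n_rep)
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- generate_dataset(reference_config(n_genes = 40, seed = 1000 + i))
    ft <- test_cellpop_effect(fit_reml(sim$dataset, se = FALSE))
    pvals[i] <- ft$p_value
    rej[i] <- ft$p_value < 0.05
  }
  expect_true(all(pvals >= 0 & pvals <= 1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
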