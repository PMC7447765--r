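#' Fit the crossed random-effects model by REML
#'
#' Fits `logExpr = constant + CellPop + Sample + Gene + Gene.CellPop + eps`
#' to a log-expression dataset, where CellPop is the fixed effect of the cell
#' population, Sample the random effect of the array, Gene the random effect
#' of the gene, and Gene.CellPop the random gene-by-population interaction —
#' the term whose estimates drive the downstream mixture stage. Estimation is
#' REML on the sparse crossed design (via [lme4::lmer()]); standard errors of
#' the variance components come from the observed information of the
#' restricted log-likelihood ([reml_loglik_vc()]).
#'
#' @param dataset An [expression_dataset()] with at least 2 populations,
#'   2 genes, and at least one population with 2 or more replicate arrays
#'   (without replicates the gene-by-population term is confounded with the
#'   residual). Missing values are rejected, not imputed.
#' @param se Compute variance-component standard errors (default `TRUE`;
#'   skipping them saves a few seconds per fit in large simulation studies).
#' @return An object of class `lmm_fit` with elements
#'   `variance_components` (data.frame: component, estimate, se),
#'   `fixed_effects` (data.frame: term, estimate, se; treatment coding, the
#'   intercept is the first population's mean),
#'   `gene_cellpop_blups` (genes x populations matrix of BLUPs),
#'   `gene_cellpop_raw` (unshrunken interaction deviations, for sensitivity
#'   analysis), `sample_blups`, `gene_blups`, `reml_loglik`, `n_iterations`,
#'   `converged`, and design bookkeeping (`populations`, `n_arrays`,
#'   `vcov_fixed`).
#' @export
fit_reml <- function(dataset, se = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  if (anyNA(v)) format_error("missing expression values; complete matrices are required")
  genes <- rownames(v); arrays <- colnames(v); pops <- dataset$populations
  if (length(pops) < 2) design_error("need >= 2 populations to separate Gene.CellPop from Gene")
  if (nrow(v) < 2) design_error("need >= 2 genes")
  reps <- table(factor(dataset$array_population, levels = pops))
  if (max(reps) < 2) {
    design_error(paste("no population has replicate arrays:",
                       "Gene.CellPop and residual terms are confounded"))
  }
  if (any(grepl("||", c(genes, pops), fixed = TRUE))) {
    format_error("gene and population ids must not contain '||'")
  }

  # Degenerate but legal input: a constant matrix has all components at zero.
  if (stats::sd(v) == 0) {
    return(constant_fit(dataset, v[1]))
  }

  arr_pop <- unname(dataset$array_population[arrays])
  n_g <- length(genes); n_a <- length(arrays)
  d <- data.frame(
    y = as.vector(v),
    gene = factor(rep(genes, n_a), levels = genes),
    array = factor(rep(arrays, each = n_g), levels = arrays),
    pop = factor(rep(arr_pop, each = n_g), levels = pops)
  )
  d$gp <- factor(paste(d$gene, d$pop, sep = "||"),
                 levels = as.vector(outer(genes, pops, paste, sep = "||")))

  fit <- suppressMessages(lme4::lmer(
    y ~ pop + (1 | array) + (1 | gene) + (1 | gp),
    data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  ))

  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) vc_tab$vcov[match(g, vc_tab$grp)]
  est <- c(var_sample = pick("array"),
           var_gene = pick("gene"),
           var_gene_cellpop = pick("gp"),
           var_resid = pick("Residual"))

  converged <- isTRUE(fit@optinfo$conv$opt == 0)
  ses <- rep(NA_real_, 4)
  if (se && converged) {
    design <- build_sparse_design(dataset)
    ses <- vc_se_information(design, est)
  }

  re <- lme4::ranef(fit, condVar = FALSE)
  gp_levels <- levels(d$gp)
  gp_blup <- stats::setNames(rep(0, length(gp_levels)), gp_levels)
  gp_blup[rownames(re$gp)] <- re$gp[["(Intercept)"]]
  blups <- matrix(gp_blup, n_g, length(pops),
                  dimnames = list(genes, pops))

  fe <- lme4::fixef(fit)
  vcov_fixed <- as.matrix(stats::vcov(fit))

  # Unshrunken counterpart of the BLUPs: two-way interaction deviations of
  # the per-cell means (gene x population), for sensitivity analysis.
  cell_means <- sapply(pops, function(p) {
    rowMeans(v[, arr_pop == p, drop = FALSE])
  })
  raw <- sweep(cell_means, 1, rowMeans(cell_means))
  raw <- sweep(raw, 2, colMeans(raw))

  structure(
    list(variance_components = data.frame(
           component = names(est), estimate = unname(est), se = ses,
           stringsAsFactors = FALSE),
         fixed_effects = data.frame(
           term = names(fe), estimate = unname(fe),
           se = sqrt(diag(vcov_fixed)), stringsAsFactors = FALSE),
         vcov_fixed = vcov_fixed,
         gene_cellpop_blups = blups,
         gene_cellpop_raw = raw,
         sample_blups = stats::setNames(
           re$array[["(Intercept)"]][match(arrays, rownames(re$array))], arrays),
         gene_blups = stats::setNames(
           re$gene[["(Intercept)"]][match(genes, rownames(re$gene))], genes),
         reml_loglik = as.numeric(stats::logLik(fit)),
         n_iterations = as.integer(fit@optinfo$feval %||% NA_integer_),
         converged = converged,
         populations = pops,
         n_arrays = n_a),
    class = "lmm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

constant_fit <- function(dataset, value) {
  genes <- rownames(dataset$values)
  arrays <- colnames(dataset$values)
  pops <- dataset$populations
  blups <- matrix(0, length(genes), length(pops), dimnames = list(genes, pops))
  fe_terms <- c("(Intercept)", paste0("pop", pops[-1]))
  structure(
    list(variance_components = data.frame(
           component = c("var_sample", "var_gene", "var_gene_cellpop", "var_resid"),
           estimate = 0, se = NA_real_, stringsAsFactors = FALSE),
         fixed_effects = data.frame(term = fe_terms,
                                    estimate = c(value, rep(0, length(pops) - 1)),
                                    se = 0, stringsAsFactors = FALSE),
         vcov_fixed = matrix(0, length(fe_terms), length(fe_terms),
                             dimnames = list(fe_terms, fe_terms)),
         gene_cellpop_blups = blups,
         gene_cellpop_raw = blups,
         sample_blups = stats::setNames(rep(0, length(arrays)), arrays),
         gene_blups = stats::setNames(rep(0, length(genes)), genes),
         reml_loglik = NA_real_,
         n_iterations = 0L,
         converged = TRUE,
         populations = pops,
         n_arrays = length(arrays)),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Crossed random-effects REML fit\n")
  cat(sprintf("  converged: %s  (restricted logLik %.3f)\n",
              x$converged, x$reml_loglik))
  vc <- x$variance_components
  for (i in seq_len(nrow(vc))) {
    cat(sprintf("  %-18s %8.4f  (SE %s)\n", vc$component[i], vc$estimate[i],
                ifelse(is.na(vc$se[i]), "NA", sprintf("%.4f", vc$se[i]))))
  }
  invisible(x)
}

#' Extract gene-by-population effect estimates for the mixture stage
#'
#' Returns the genes x populations matrix of Gene.CellPop estimates from a
#' converged fit: BLUPs by default, or the unshrunken per-cell interaction
#' deviations for sensitivity analysis. The signs of these estimates define
#' the up/down direction of later DE calls.
#'
#' @param fit An `lmm_fit` from [fit_reml()]; must have converged.
#' @param shrunken Use BLUPs (`TRUE`, default) or raw interaction deviations.
#' @return Numeric matrix, rows = genes, columns = populations.
#' @export
extract_gene_cellpop_effects <- function(fit, shrunken = TRUE) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) {
    convergence_error("REML fit did not converge; refusing to extract effects")
  }
  if (shrunken) fit$gene_cellpop_blups else fit$gene_cellpop_raw
}

#' Wald F-test of the cell-population fixed effect
#'
#' Tests equality of the population means with a Wald F statistic on the
#' REML fixed-effect estimates. The denominator degrees of freedom are taken
#' from the array stratum, `n_arrays - n_populations` — the stratum in which
#' population contrasts are estimated. For arrays normalized before analysis
#' no population effect is expected.
#'
#' @param fit An `lmm_fit` from [fit_reml()]; must have converged.
#' @return An object of class `fixed_effect_test`: list with `f_statistic`,
#'   `numerator_df`, `denominator_df`, `p_value`.
#' @export
test_cellpop_effect <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) convergence_error("REML fit did not converge")
  n_pop <- length(fit$populations)
  if (n_pop < 2) design_error("cell-population test undefined for a single population")
  b <- fit$fixed_effects$estimate[-1]
  Vb <- fit$vcov_fixed[-1, -1, drop = FALSE]
  q <- length(b)
  f_stat <- if (max(abs(b)) < 1e-12) {
    0
  } else {
    as.numeric(crossprod(b, pseudo_solve(Vb, b))) / q
  }
  df2 <- fit$n_arrays - n_pop
  structure(list(f_statistic = f_stat,
                 numerator_df = q,
                 denominator_df = df2,
                 p_value = stats::pf(f_stat, q, df2, lower.tail = FALSE)),
            class = "fixed_effect_test")
}

pseudo_solve <- function(A, b, tol = 1e-12) {
  tryCatch(solve(A, b), error = function(e) {
    s <- svd(A)
    pos <- s$d > tol * max(s$d)
    s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos])
  })
}

#' @export
print.fixed_effect_test <- function(x, ...) {
  cat(sprintf("Cell-population Wald F = %.3f on (%d, %d) df, p = %.3g\n",
              x$f_statistic, x$numerator_df, x$denominator_df, x$p_value))
  invisible(x)
}
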