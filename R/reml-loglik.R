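# Sparse restricted log-likelihood for the crossed-design model
#
#   y = X beta + Z_S u_S + Z_G u_G + Z_GP u_GP + eps
#
# evaluated as a function of the four variance components
# (var_sample, var_gene, var_gene_cellpop, var_resid) through the mixed-model
# equations, never materialising the n x n covariance:
#   log|V|        = n log s2e + sum_k q_k log s2_k + log|A|,
#   A             = Z'Z/s2e + G^{-1},
#   log|X'V^-1 X| = log|C| - log|A|,  C the MME coefficient matrix,
#   y'Py          = (y'y - [b;u]' M'y) / s2e,  M = [X Z].
# Standard errors of the components come from the numerically differentiated
# observed information of this function.

build_sparse_design <- function(dataset) {
  v <- dataset$values
  genes <- rownames(v)
  arrays <- colnames(v)
  pops <- dataset$populations
  n_g <- length(genes); n_a <- length(arrays); n_p <- length(pops)
  arr_pop <- unname(dataset$array_population[arrays])

  y <- as.vector(v) # column-major: gene index varies fastest
  gene_i <- rep(seq_len(n_g), n_a)
  array_i <- rep(seq_len(n_a), each = n_g)
  pop_i <- rep(match(arr_pop, pops), each = n_g)
  n <- length(y)

  pop_f <- factor(pops[pop_i], levels = pops)
  X <- stats::model.matrix(~pop_f)
  colnames(X) <- c("(Intercept)", paste0("pop", pops[-1]))

  ind <- function(j, nlev) {
    Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, nlev))
  }
  Z_S <- ind(array_i, n_a)
  Z_G <- ind(gene_i, n_g)
  Z_GP <- ind((pop_i - 1L) * n_g + gene_i, n_g * n_p) # gene within population

  Z <- cbind(Z_S, Z_G, Z_GP)
  M <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  list(y = y, X = X, Z = Z,
       MtM = Matrix::crossprod(M), Mty = as.vector(Matrix::crossprod(M, y)),
       ZtZ = Matrix::crossprod(Z), yty = sum(y * y),
       n = n, p = ncol(X),
       q = c(var_sample = n_a, var_gene = n_g, var_gene_cellpop = n_g * n_p),
       genes = genes, arrays = arrays, pops = pops)
}

chol_logdet <- function(A) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  list(chol = ch,
       logdet = 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                   sqrt = TRUE)$modulus))
}

#' Restricted log-likelihood of the crossed-design model
#'
#' Evaluates the REML log-likelihood (error-contrast likelihood, including its
#' normalising constants) of the gene/array/gene-by-population model at a
#' given vector of variance components, using sparse mixed-model-equation
#' algebra. Used internally for variance-component standard errors; exported
#' because it is a convenient cross-check of any REML fit of the same model.
#'
#' @param vc Numeric vector `c(var_sample, var_gene, var_gene_cellpop,
#'   var_resid)`, all strictly positive.
#' @param dataset An [expression_dataset()], or the design object produced by
#'   the internal builder (recomputed automatically from a dataset).
#' @param solution If `TRUE`, also return the mixed-model-equation solutions
#'   (GLS fixed effects and BLUPs) at `vc`.
#' @return The scalar log-likelihood, or (with `solution = TRUE`) a list with
#'   `loglik`, `beta` and `u` (named by random term).
#' @export
reml_loglik_vc <- function(vc, dataset, solution = FALSE) {
  design <- if (inherits(dataset, "expression_dataset")) {
    build_sparse_design(dataset)
  } else dataset
  vc <- as.numeric(vc)
  if (length(vc) != 4 || any(vc <= 0)) {
    param_error("vc must be 4 strictly positive variance components")
  }
  s2 <- vc[1:3]; s2e <- vc[4]
  q <- design$q; n <- design$n; p <- design$p

  ginv_diag <- rep(1 / s2, times = q)
  A <- design$ZtZ / s2e + Matrix::Diagonal(x = ginv_diag)
  ldA <- chol_logdet(A)$logdet

  C <- design$MtM / s2e +
    Matrix::Diagonal(x = c(rep(0, p), ginv_diag))
  cc <- chol_logdet(C)
  rhs <- design$Mty / s2e
  sol <- as.vector(Matrix::solve(cc$chol, rhs, system = "A"))

  yPy <- (design$yty - sum(sol * design$Mty)) / s2e
  logdetV <- n * log(s2e) + sum(q * log(s2)) + ldA
  logdetXVX <- cc$logdet - ldA
  ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXVX + yPy)
  if (!solution) return(ll)
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(design$X)
  u <- sol[-seq_len(p)]
  blocks <- rep(names(q), times = q)
  list(loglik = ll, beta = beta, u = split(u, factor(blocks, levels = names(q))))
}

# Observed-information SEs of the variance components at vc_hat.
# Components pinned at (near) zero are held fixed and reported with SE NA;
# the information for the free components is then the constrained one.
vc_se_information <- function(design, vc_hat, pin_tol = 1e-7) {
  vc_hat <- as.numeric(vc_hat)
  free <- vc_hat > pin_tol
  se <- rep(NA_real_, 4)
  if (!any(free)) return(se)
  idx <- which(free)
  f <- function(v_free) {
    v <- vc_hat
    v[idx] <- v_free
    reml_loglik_vc(v, design)
  }
  v0 <- vc_hat[idx]
  h <- pmin(pmax(1e-3 * v0, 1e-6), 0.49 * v0)
  k <- length(idx)
  H <- matrix(NA_real_, k, k)
  f0 <- f(v0)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(v0 + ei) - 2 * f0 + f(v0 - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(v0 + ei + ej) - f(v0 + ei - ej) - f(v0 - ei + ej) + f(v0 - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[idx] <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  se
}
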