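# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route (dense algebra, enumeration, naive
# agglomeration) so that it never shares code with the implementation.

# Dense textbook REML log-likelihood: builds the full n x n covariance.
dense_reml_loglik <- function(vc, ds) {
  v <- ds$values
  genes <- rownames(v); arrays <- colnames(v); pops <- ds$populations
  y <- as.vector(v); n <- length(y)
  gene_i <- rep(seq_along(genes), length(arrays))
  array_i <- rep(seq_along(arrays), each = length(genes))
  pop_i <- rep(match(unname(ds$array_population[arrays]), pops),
               each = length(genes))
  X <- stats::model.matrix(~ factor(pops[pop_i], levels = pops))
  ZS <- outer(array_i, seq_along(arrays), "==") * 1
  ZG <- outer(gene_i, seq_along(genes), "==") * 1
  gp <- (pop_i - 1) * length(genes) + gene_i
  ZGP <- outer(gp, seq_len(length(genes) * length(pops)), "==") * 1
  V <- vc[1] * tcrossprod(ZS) + vc[2] * tcrossprod(ZG) +
    vc[3] * tcrossprod(ZGP) + vc[4] * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - ncol(X)) * log(2 * pi) +
                     determinant(V)$modulus +
                     determinant(XVX)$modulus +
                     t(y) %*% P %*% y))
}

# Dense REML point estimates: direct box-constrained optimisation of the
# dense log-likelihood, independent of lme4.
dense_reml_fit <- function(ds, start) {
  opt <- stats::optim(log(start),
                      function(lv) -dense_reml_loglik(exp(lv), ds),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  exp(opt$par)
}

# Closed-form expected-mean-squares (ANOVA) estimators for a balanced design
# with p populations x a arrays each x g genes.
anova_ems_estimators <- function(ds) {
  v <- ds$values
  pops <- ds$populations
  arr_pop <- unname(ds$array_population[colnames(v)])
  p <- length(pops)
  a <- unique(table(arr_pop))
  stopifnot(length(a) == 1) # balanced only
  g <- nrow(v)
  ybar <- mean(v)
  arr_means <- colMeans(v)                        # ybar_ij.
  pop_means <- tapply(arr_means, arr_pop, mean)[pops] # ybar_i..
  gene_means <- rowMeans(v)                       # ybar_..k
  cell_means <- sapply(pops, function(pp) rowMeans(v[, arr_pop == pp, drop = FALSE]))

  ms_s <- g * sum((arr_means - pop_means[match(arr_pop, pops)])^2) / (p * (a - 1))
  ms_g <- p * a * sum((gene_means - ybar)^2) / (g - 1)
  inter <- sweep(sweep(cell_means, 1, gene_means), 2, pop_means - ybar)
  ms_gp <- a * sum(inter^2) / ((p - 1) * (g - 1))
  resid <- v - matrix(arr_means, g, p * a, byrow = TRUE) -
    cell_means[, match(arr_pop, pops)] +
    matrix(pop_means[match(arr_pop, pops)], g, p * a, byrow = TRUE)
  ms_e <- sum(resid^2) / (p * (a - 1) * (g - 1))

  c(var_sample = (ms_s - ms_e) / g,
    var_gene = (ms_g - ms_gp) / (p * a),
    var_gene_cellpop = (ms_gp - ms_e) / a,
    var_resid = ms_e)
}

# Scale-mixture log-likelihood evaluated directly (no EM machinery).
mixture_loglik <- function(x, pi1, s0, s1) {
  sum(log((1 - pi1) * stats::dnorm(x, 0, s0) + pi1 * stats::dnorm(x, 0, s1)))
}

# Exhaustive grid search around a candidate solution.
grid_search_mixture <- function(x, center) {
  pi_grid <- seq(max(0.01, center$pi1 - 0.05), min(0.99, center$pi1 + 0.05), by = 0.01)
  s0_grid <- seq(max(1e-3, center$sigma0 - 0.03), center$sigma0 + 0.03, by = 0.005)
  s1_grid <- seq(max(1e-3, center$sigma1 - 0.03), center$sigma1 + 0.03, by = 0.005)
  best <- -Inf
  for (p in pi_grid) for (s0 in s0_grid) for (s1 in s1_grid) {
    ll <- mixture_loglik(x, p, s0, s1)
    if (ll > best) best <- ll
  }
  best
}

# Naive O(n^3) Ward agglomeration (Lance-Williams update for ward.D2),
# returning the k-cluster partition.
naive_ward_partition <- function(z, k) {
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  while (length(active) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (m in setdiff(active, c(i, j))) {
      nm <- sizes[m]
      d_new <- sqrt(((ni + nm) * d[i, m]^2 + (nj + nm) * d[j, m]^2 -
                     nm * d[i, j]^2) / (ni + nj + nm))
      d[i, m] <- d[m, i] <- d_new
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  out <- integer(n)
  for (ci in seq_along(active)) out[members[[active[ci]]]] <- ci
  out
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of a
# universe with K special elements (feasible for N <= 25).
enum_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  special <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% special) >= k)
  mean(hits)
}

# Benjamini-Hochberg step-up written from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Minimal stand-in DE call object for set-logic tests.
fake_calls <- function(genes, de_signs, population) {
  structure(
    list(population = population, threshold = 0.8, cutoff = NA_real_,
         params = NULL, table = NULL,
         de_genes = de_signs, n_de = length(de_signs),
         fdr = if (length(de_signs)) 0.1 else NA_real_, genes = genes),
    class = "de_calls")
}
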