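#' Fit a two-component zero-mean normal scale mixture by EM
#'
#' Maximum-likelihood fit of
#' `f(x) = (1 - pi1) N(x; 0, sigma0^2) + pi1 N(x; 0, sigma1^2)`
#' to a vector of gene-by-population effect estimates. Both components are
#' centred at zero: the narrow component models estimation noise around
#' non-DE genes, the wide one genuinely differentially expressed genes, so
#' the two are distinguished by scale alone. The reported fit always has
#' `sigma0 <= sigma1` and the posteriors are the converged responsibilities
#' of the wide component.
#'
#' EM is run from `n_starts` starting points — the default initialisation
#' `(pi1, sigma0, sigma1) = (0.25, 0.5 sd(x), 2 sd(x))` plus jittered copies
#' with fixed sub-seeds — and the best converged log-likelihood is kept,
#' guarding against the sigma0 -> 0 spike degeneracy; SDs are floored at
#' `1e-6 sd(x)`.
#'
#' @param x Numeric vector of effect estimates; at least 10 finite values
#'   with non-zero spread.
#' @param init Optional list with elements `pi1`, `sigma0`, `sigma1`
#'   overriding the default first start.
#' @param n_starts Number of EM starts (default 5).
#' @param max_iter Iteration cap per start (default 50000; EM creeps along a
#'   likelihood ridge when the two component SDs are close, and iterations
#'   are cheap).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-9).
#' @param seed Seed for the start jitter (default 1; results are
#'   deterministic given `x` and `seed`).
#' @return An object of class `mixture_fit`: list with `params` (list
#'   `pi1`, `sigma0`, `sigma1`), `posteriors` (per-observation probability of
#'   the wide component, named like `x`), `loglik` (converged value),
#'   `loglik_trace` (per-iteration, non-decreasing), `n_iterations`,
#'   `converged`.
#' @export
fit_scale_mixture <- function(x, init = NULL, n_starts = 5, max_iter = 50000,
                              tol = 1e-9, seed = 1L) {
  nm <- names(x)
  x <- as.numeric(x)
  ok <- is.finite(x)
  if (sum(ok) < 10) degenerate_error("need >= 10 finite effect estimates")
  if (!all(ok)) {
    x <- x[ok]
    nm <- nm[ok]
  }
  s <- stats::sd(x)
  if (s == 0) degenerate_error("effect estimates have zero spread; mixture fit is degenerate")

  base <- list(pi1 = 0.25, sigma0 = 0.5 * s, sigma1 = 2 * s)
  if (!is.null(init)) base[names(init)] <- init
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- base
  if (n_starts > 1) {
    for (k in 2:n_starts) {
      starts[[k]] <- list(
        pi1 = min(max(base$pi1 * stats::runif(1, 0.4, 1.8), 0.02), 0.95),
        sigma0 = base$sigma0 * stats::runif(1, 0.5, 1.5),
        sigma1 = base$sigma1 * stats::runif(1, 0.5, 1.5)
      )
    }
  }

  best <- NULL
  for (st in starts) {
    cand <- em_scale_mixture(x, st$pi1, st$sigma0, st$sigma1,
                             max_iter = max_iter, tol = tol,
                             sd_floor = 1e-6 * s)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }

  # Component ordering convention: sigma0 <= sigma1. Swapping labels flips
  # pi1 and the responsibilities.
  if (best$sigma0 > best$sigma1) {
    best <- within(best, {
      tmp <- sigma0; sigma0 <- sigma1; sigma1 <- tmp; rm(tmp)
      pi1 <- 1 - pi1
      post <- 1 - post
    })
  }
  posteriors <- stats::setNames(best$post, nm)
  structure(
    list(params = list(pi1 = best$pi1, sigma0 = best$sigma0,
                       sigma1 = best$sigma1),
         posteriors = posteriors,
         loglik = best$loglik,
         loglik_trace = best$trace,
         n_iterations = best$iter,
         converged = best$converged),
    class = "mixture_fit"
  )
}

em_scale_mixture <- function(x, pi1, s0, s1, max_iter, tol, sd_floor) {
  n <- length(x)
  x2 <- x^2
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  pi1 <- min(max(pi1, 1e-10), 1 - 1e-10)
  r <- NULL
  repeat {
    iter <- iter + 1
    a0 <- log1p(-pi1) + stats::dnorm(x, 0, s0, log = TRUE)
    a1 <- log(pi1) + stats::dnorm(x, 0, s1, log = TRUE)
    m <- pmax(a0, a1)
    ll <- sum(m + log(exp(a0 - m) + exp(a1 - m)))
    trace <- c(trace, ll)
    r <- 1 / (1 + exp(a0 - a1)) # responsibility of the wide component
    if (abs(ll - ll_prev) < tol || iter >= max_iter) {
      converged <- abs(ll - ll_prev) < tol
      break
    }
    ll_prev <- ll
    r1 <- sum(r); r0 <- n - r1
    pi1 <- min(max(r1 / n, 1e-10), 1 - 1e-10)
    if (r1 > 0) s1 <- max(sqrt(sum(r * x2) / r1), sd_floor)
    if (r0 > 0) s0 <- max(sqrt(sum((1 - r) * x2) / r0), sd_floor)
  }
  list(pi1 = pi1, sigma0 = s0, sigma1 = s1, post = r,
       loglik = trace[length(trace)], trace = trace,
       iter = iter, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Scale-mixture fit: pi1 = %.3f, sigma0 = %.3f, sigma1 = %.3f (logLik %.3f, %d iter, converged: %s)\n",
    x$params$pi1, x$params$sigma0, x$params$sigma1,
    x$loglik, x$n_iterations, x$converged))
  invisible(x)
}

check_mixture_params <- function(params) {
  stopifnot(is.list(params), all(c("pi1", "sigma0", "sigma1") %in% names(params)))
  if (params$pi1 < 0 || params$pi1 > 1) param_error("pi1 must lie in [0, 1]")
  if (!(params$sigma1 >= params$sigma0 && params$sigma0 > 0)) {
    param_error("need sigma1 >= sigma0 > 0")
  }
  invisible(params)
}

#' Posterior probability of differential expression
#'
#' Under mixture parameters `(pi1, sigma0, sigma1)` the posterior probability
#' that an effect estimate `x` came from the wide (DE) component is
#' `pi1 phi(x; 0, sigma1^2) / [pi1 phi(x; 0, sigma1^2) +
#' (1 - pi1) phi(x; 0, sigma0^2)]`. It is symmetric in `x` and, when
#' `sigma1 > sigma0`, non-decreasing in `|x|`.
#'
#' @param x Numeric vector of effect estimates.
#' @param params List with `pi1`, `sigma0`, `sigma1` (e.g. `fit$params`).
#' @return Vector of probabilities in `[0, 1]`.
#' @export
posterior_de <- function(x, params) {
  check_mixture_params(params)
  if (params$pi1 == 0) return(rep(0, length(x)))
  if (params$pi1 == 1) return(rep(1, length(x)))
  a0 <- log1p(-params$pi1) + stats::dnorm(x, 0, params$sigma0, log = TRUE)
  a1 <- log(params$pi1) + stats::dnorm(x, 0, params$sigma1, log = TRUE)
  1 / (1 + exp(a0 - a1))
}

#' Effect-size cutoff implied by a posterior threshold
#'
#' The DE rule "posterior > threshold" is equivalent to `|x| > c`; this
#' returns `c` in closed form. `c = 0` when even `x = 0` exceeds the
#' threshold, `Inf` when no finite effect does (e.g. `sigma0 = sigma1` with
#' `pi1 <= threshold`).
#'
#' @param params List with `pi1`, `sigma0`, `sigma1`.
#' @param threshold Posterior probability threshold in (0, 1).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
de_threshold <- function(params, threshold = 0.8) {
  check_mixture_params(params)
  if (threshold <= 0 || threshold >= 1) param_error("threshold must lie in (0, 1)")
  if (params$pi1 == 0) return(Inf)
  if (params$pi1 == 1) return(0)
  if (params$sigma0 == params$sigma1) {
    return(if (params$pi1 > threshold) 0 else Inf)
  }
  num <- log(threshold / (1 - threshold)) -
    log(params$pi1 / (1 - params$pi1)) -
    log(params$sigma0 / params$sigma1)
  prec <- 1 / params$sigma0^2 - 1 / params$sigma1^2
  c2 <- 2 * num / prec
  if (c2 <= 0) 0 else sqrt(c2)
}

#' Classify genes as DE and compute the model-based FDR
#'
#' Calls gene `g` differentially expressed when its posterior probability of
#' the wide component exceeds `threshold` (default 0.8), signs the call by
#' the effect estimate, and reports the model-based false discovery rate of
#' the call set: the mean of `1 - posterior` over called genes, i.e. the
#' expected fraction of false discoveries. With an empty call set the FDR is
#' undefined and reported as `NA`.
#'
#' @param fit A converged `mixture_fit` whose posteriors align with `effects`.
#' @param effects Named numeric vector of effect estimates (same genes, same
#'   order as the vector the mixture was fitted to).
#' @param threshold Posterior threshold in (0, 1), default 0.8.
#' @param population Optional population label carried through to the output.
#' @return An object of class `de_calls`: list with `population`,
#'   `threshold`, `cutoff` (the equivalent |effect| cutoff), `table` (data
#'   frame gene, effect, posterior, called, sign), `de_genes` (named sign
#'   vector, +1/-1), `n_de`, `fdr`, and `genes` (the full universe scored).
#' @export
classify_and_fdr <- function(fit, effects, threshold = 0.8, population = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!isTRUE(fit$converged)) {
    convergence_error("mixture fit did not converge; refusing to classify")
  }
  if (threshold <= 0 || threshold >= 1) param_error("threshold must lie in (0, 1)")
  if (length(effects) != length(fit$posteriors)) {
    alignment_error("effects and fitted posteriors have different lengths")
  }
  genes <- names(effects)
  if (is.null(genes)) genes <- sprintf("gene_%05d", seq_along(effects))
  post <- unname(fit$posteriors)
  called <- post > threshold
  sgn <- sign(effects)
  zero_called <- called & sgn == 0
  if (any(zero_called)) {
    message(sprintf(
      "%d called gene(s) with a zero effect estimate: direction undefined, left unsigned",
      sum(zero_called)))
  }
  tab <- data.frame(gene = genes, effect = unname(effects), posterior = post,
                    called = called, sign = ifelse(called, sgn, NA_real_),
                    stringsAsFactors = FALSE)
  de <- tab[tab$called, ]
  structure(
    list(population = population,
         threshold = threshold,
         cutoff = de_threshold(fit$params, threshold),
         params = fit$params,
         table = tab,
         de_genes = stats::setNames(de$sign, de$gene),
         n_de = nrow(de),
         fdr = if (nrow(de) > 0) mean(1 - de$posterior) else NA_real_,
         genes = genes),
    class = "de_calls"
  )
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("DE calls%s: %d genes at posterior > %.2f (|effect| > %.3f), FDR = %s\n",
              if (is.null(x$population)) "" else paste0(" [", x$population, "]"),
              x$n_de, x$threshold, x$cutoff,
              ifelse(is.na(x$fdr), "undefined", sprintf("%.3f", x$fdr))))
  invisible(x)
}

#' DE-count-weighted overall false discovery rate
#'
#' Aggregates per-population model-based FDRs into a single figure:
#' `sum(n_de_i * fdr_i) / sum(n_de_i)`, the expected fraction of false
#' discoveries among all DE calls pooled across populations. Undefined
#' (returned as `NA`) when every call set is empty.
#'
#' @param calls List of `de_calls` objects (or any lists carrying `n_de`
#'   and `fdr`).
#' @return Scalar probability, or `NA_real_` if no genes were called.
#' @export
overall_fdr <- function(calls) {
  n_de <- vapply(calls, function(cl) as.numeric(cl$n_de), numeric(1))
  fdr <- vapply(calls, function(cl) as.numeric(cl$fdr), numeric(1))
  if (all(n_de == 0)) return(NA_real_)
  keep <- n_de > 0
  sum(n_de[keep] * fdr[keep]) / sum(n_de[keep])
}
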