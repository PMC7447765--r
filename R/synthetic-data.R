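#' Configuration for the synthetic expression generator
#'
#' Describes the generative model the two-stage analysis assumes: log
#' expression decomposes as a grand mean plus a fixed cell-population offset,
#' an array (sample) random effect, a gene random effect, a
#' gene-by-population random effect, and residual noise. The
#' gene-by-population term is either Gaussian with variance
#' `var_gene_cellpop`, or — in `mixture` mode — drawn per population from a
#' two-component zero-mean normal scale mixture so that ground-truth DE
#' labels exist.
#'
#' @param n_genes Number of genes (>= 1).
#' @param populations Named integer vector: population label -> number of
#'   replicate arrays (each >= 1).
#' @param grand_mean Grand mean on the log-expression scale.
#' @param cellpop_effects Fixed per-population offsets (log-expression units);
#'   a single value is recycled. Default 0 for every population, the expected
#'   situation for arrays normalized before analysis.
#' @param var_sample Array (sample) random-effect variance, sigma_S^2.
#' @param var_gene Gene random-effect variance, sigma_G^2.
#' @param gene_cellpop_mode `"gaussian"` or `"mixture"`.
#' @param var_gene_cellpop Gene-by-population variance sigma_G.CP^2
#'   (gaussian mode only).
#' @param mixture_params Data frame with columns `population`, `pi1`,
#'   `sigma0`, `sigma1`, one row per population (mixture mode only);
#'   `sigma1 > sigma0 > 0` and `0 <= pi1 <= 1`.
#' @param var_resid Residual variance sigma_eps^2.
#' @param seed Integer RNG seed. Sub-streams for the array, gene,
#'   gene-by-population and residual terms are derived deterministically from
#'   it, so enlarging `n_genes` leaves the array effects unchanged.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes,
                             populations,
                             grand_mean = 7,
                             cellpop_effects = 0,
                             var_sample = 0,
                             var_gene = 0,
                             gene_cellpop_mode = c("gaussian", "mixture"),
                             var_gene_cellpop = NULL,
                             mixture_params = NULL,
                             var_resid = 0,
                             seed = 1L) {
  gene_cellpop_mode <- match.arg(gene_cellpop_mode)
  if (length(n_genes) != 1 || n_genes < 1) config_error("n_genes must be a positive count")
  if (is.null(names(populations)) || any(names(populations) == "")) {
    config_error("populations must be a named vector: label -> replicate count")
  }
  if (any(populations < 1)) config_error("replicate counts must be >= 1")
  vars <- c(var_sample = var_sample, var_gene = var_gene, var_resid = var_resid)
  if (any(vars < 0)) config_error("variances must be >= 0")
  n_pop <- length(populations)
  cellpop_effects <- rep_len(cellpop_effects, n_pop)
  names(cellpop_effects) <- names(populations)
  if (gene_cellpop_mode == "gaussian") {
    if (!is.null(mixture_params)) {
      config_error("mixture_params supplied but gene_cellpop_mode is 'gaussian'")
    }
    if (is.null(var_gene_cellpop) || var_gene_cellpop < 0) {
      config_error("gaussian mode requires var_gene_cellpop >= 0")
    }
  } else {
    if (!is.null(var_gene_cellpop)) {
      config_error("var_gene_cellpop supplied but gene_cellpop_mode is 'mixture'")
    }
    if (is.null(mixture_params) ||
        !all(c("population", "pi1", "sigma0", "sigma1") %in% names(mixture_params))) {
      config_error("mixture mode requires mixture_params with columns population, pi1, sigma0, sigma1")
    }
    mixture_params <- as.data.frame(mixture_params)
    if (!setequal(mixture_params$population, names(populations))) {
      config_error("mixture_params must cover exactly the declared populations")
    }
    mixture_params <- mixture_params[match(names(populations), mixture_params$population), ]
    with(mixture_params, {
      if (any(pi1 < 0 | pi1 > 1)) config_error("pi1 must lie in [0, 1]")
      if (any(!(sigma1 > sigma0 & sigma0 > 0))) {
        config_error("mixture components must satisfy sigma1 > sigma0 > 0")
      }
    })
  }
  structure(
    list(n_genes = as.integer(n_genes),
         populations = stats::setNames(as.integer(populations), names(populations)),
         grand_mean = grand_mean,
         cellpop_effects = cellpop_effects,
         var_sample = var_sample,
         var_gene = var_gene,
         gene_cellpop_mode = gene_cellpop_mode,
         var_gene_cellpop = var_gene_cellpop,
         mixture_params = mixture_params,
         var_resid = var_resid,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Reference generator configuration (sorted bovine mammary design)
#'
#' Study conditions used throughout the package's recovery tests: four sorted
#' mammary epithelial cell populations (CD49f/P-Cadherin marker combinations)
#' with 3/2/3/3 replicate arrays, and the variance components estimated from
#' that design (`sigma_G^2 = 5.44`, `sigma_G.CP^2 = 0.672`,
#' `sigma_S^2 = 0.036`). The residual variance is not identifiable from the
#' published summaries and is fixed at 0.25, small relative to the
#' between-gene variance; fixed population effects are 0 (arrays are
#' normalized before analysis) and the grand mean is 7, a typical log-RPKM
#' scale. In `mixture` mode the gene-by-population term is drawn from the
#' per-population two-component fits (`pi1`, `sigma0`, `sigma1`) estimated on
#' the same design.
#'
#' @param n_genes Number of genes to simulate (default 2000; the published
#'   analysis does not state its gene count, so this is a package choice).
#' @param gene_cellpop_mode `"gaussian"` or `"mixture"`.
#' @param seed Integer RNG seed.
#' @return A [generator_config()].
#' @export
reference_config <- function(n_genes = 2000,
                             gene_cellpop_mode = c("gaussian", "mixture"),
                             seed = 1L) {
  gene_cellpop_mode <- match.arg(gene_cellpop_mode)
  pops <- c("CD49f_neg.Pcad_neg" = 3L,
            "CD49f_mid.Pcad_mid" = 2L,
            "CD49f_mid.Pcad_high" = 3L,
            "CD49f_high.Pcad_neg" = 3L)
  args <- list(n_genes = n_genes, populations = pops, grand_mean = 7,
               cellpop_effects = 0, var_sample = 0.036, var_gene = 5.44,
               gene_cellpop_mode = gene_cellpop_mode, var_resid = 0.25,
               seed = seed)
  if (gene_cellpop_mode == "gaussian") {
    args$var_gene_cellpop <- 0.672
  } else {
    args$mixture_params <- reference_mixture_table()
  }
  do.call(generator_config, args)
}

#' Reference per-population mixture parameters and DE summaries
#'
#' The per-population two-component scale-mixture fits for the sorted bovine
#' mammary design: proportion of DE genes `pi1`, non-DE SD `sigma0`, DE SD
#' `sigma1`, together with the reported number of DE calls `n_de` and
#' model-based `fdr` at posterior threshold 0.8.
#'
#' @return A data frame with one row per population.
#' @export
reference_mixture_table <- function() {
  data.frame(
    population = c("CD49f_neg.Pcad_neg", "CD49f_mid.Pcad_mid",
                   "CD49f_mid.Pcad_high", "CD49f_high.Pcad_neg"),
    pi1 = c(0.227, 0.225, 0.307, 0.375),
    sigma0 = c(0.302, 0.204, 0.350, 0.261),
    sigma1 = c(1.290, 0.612, 1.119, 1.109),
    n_de = c(1433L, 980L, 1644L, 2669L),
    fdr = c(0.030, 0.041, 0.035, 0.029),
    stringsAsFactors = FALSE
  )
}

#' Draw from a two-component zero-mean normal scale mixture
#'
#' Samples `n` values from `(1 - pi1) N(0, sigma0^2) + pi1 N(0, sigma1^2)`
#' and records which component generated each draw. The wide component
#' (`sigma1`) models DE genes, the narrow one non-DE noise.
#'
#' @param pi1 Mixing proportion of the wide component, in `[0, 1]`.
#' @param sigma0,sigma1 Component SDs; `sigma1 > sigma0 > 0` (the component
#'   ordering that makes the labels identifiable).
#' @param n Number of draws (>= 1).
#' @param seed Integer RNG seed.
#' @return List with `effects` (numeric vector) and `component`
#'   (integer 0/1 labels).
#' @export
generate_mixture_sample <- function(pi1, sigma0, sigma1, n, seed = 1L) {
  if (pi1 < 0 || pi1 > 1) param_error("pi1 must lie in [0, 1]")
  if (!(sigma1 > sigma0 && sigma0 > 0)) {
    param_error("need sigma1 > sigma0 > 0 (component ordering convention)")
  }
  if (n < 1) param_error("n must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  comp <- as.integer(stats::runif(n) < pi1)
  eff <- stats::rnorm(n, mean = 0, sd = ifelse(comp == 1L, sigma1, sigma0))
  list(effects = eff, component = comp)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Simulates `values[g, a] = grand_mean + cellpop_effects[pop(a)] + S[a] +
#' G[g] + GC[g, pop(a)] + eps[g, a]` with `S ~ N(0, var_sample)`,
#' `G ~ N(0, var_gene)`, `eps ~ N(0, var_resid)` and `GC` either Gaussian
#' (`var_gene_cellpop`) or a per-population two-component scale mixture whose
#' component labels are kept as ground-truth DE indicators. Bitwise
#' reproducible given the config (each random term uses its own sub-stream
#' derived from `config$seed`).
#'
#' @param config A [generator_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`, a list
#'   holding `sample_effects`, `gene_effects`, `gene_cellpop_effects`
#'   (genes x populations matrix) and, in mixture mode, logical `de_labels`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(config$seed)
  term_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  pops <- names(config$populations)
  arr_pop <- rep(pops, config$populations)
  array_ids <- unlist(lapply(pops, function(p) {
    sprintf("%s_r%d", p, seq_len(config$populations[[p]]))
  }))
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  n_a <- length(array_ids)
  n_g <- config$n_genes
  n_p <- length(pops)

  set.seed(term_seeds[1])
  S <- stats::rnorm(n_a, 0, sqrt(config$var_sample))
  names(S) <- array_ids

  set.seed(term_seeds[2])
  G <- stats::rnorm(n_g, 0, sqrt(config$var_gene))
  names(G) <- gene_ids

  set.seed(term_seeds[3])
  de_labels <- NULL
  if (config$gene_cellpop_mode == "gaussian") {
    GC <- matrix(stats::rnorm(n_g * n_p, 0, sqrt(config$var_gene_cellpop)),
                 n_g, n_p, dimnames = list(gene_ids, pops))
  } else {
    pop_seeds <- sample.int(.Machine$integer.max - 1L, n_p)
    GC <- matrix(0, n_g, n_p, dimnames = list(gene_ids, pops))
    de_labels <- matrix(FALSE, n_g, n_p, dimnames = list(gene_ids, pops))
    for (j in seq_len(n_p)) {
      mp <- config$mixture_params[j, ]
      draw <- generate_mixture_sample(mp$pi1, mp$sigma0, mp$sigma1,
                                      n_g, seed = pop_seeds[j])
      GC[, j] <- draw$effects
      de_labels[, j] <- draw$component == 1L
    }
  }

  set.seed(term_seeds[4])
  eps <- matrix(stats::rnorm(n_g * n_a, 0, sqrt(config$var_resid)),
                n_g, n_a, dimnames = list(gene_ids, array_ids))

  pop_idx <- match(arr_pop, pops)
  values <- config$grand_mean +
    matrix(config$cellpop_effects[pop_idx], n_g, n_a, byrow = TRUE) +
    matrix(S, n_g, n_a, byrow = TRUE) +
    matrix(G, n_g, n_a) +
    GC[, pop_idx, drop = FALSE] +
    eps
  dimnames(values) <- list(gene_ids, array_ids)

  dataset <- expression_dataset(values,
                                stats::setNames(arr_pop, array_ids),
                                populations = pops)
  truth <- list(sample_effects = S,
                gene_effects = G,
                gene_cellpop_effects = GC,
                de_labels = de_labels)
  list(dataset = dataset, truth = truth)
}

#' Write generator ground truth as a TSV bundle
#'
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["sample_effects"] <- wr(
    data.frame(array_id = names(truth$sample_effects),
               effect = unname(truth$sample_effects)),
    "truth_sample_effects.tsv")
  paths["gene_effects"] <- wr(
    data.frame(gene_id = names(truth$gene_effects),
               effect = unname(truth$gene_effects)),
    "truth_gene_effects.tsv")
  paths["gene_cellpop_effects"] <- wr(
    data.frame(gene_id = rownames(truth$gene_cellpop_effects),
               truth$gene_cellpop_effects, check.names = FALSE),
    "truth_gene_cellpop_effects.tsv")
  if (!is.null(truth$de_labels)) {
    paths["de_labels"] <- wr(
      data.frame(gene_id = rownames(truth$de_labels),
                 truth$de_labels, check.names = FALSE),
      "truth_de_labels.tsv")
  }
  invisible(paths)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file holds the fields of [generator_config()]; `populations` is a
#' mapping label -> replicate count and `mixture_params` (mixture mode) a
#' table with columns population, pi1, sigma0, sigma1.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      config_error("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    config_error("config file must be .yaml, .yml or .json")
  }
  if (!is.null(raw$populations)) raw$populations <- unlist(raw$populations)
  if (!is.null(raw$mixture_params)) {
    raw$mixture_params <- as.data.frame(raw$mixture_params)
  }
  do.call(generator_config, raw)
}
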