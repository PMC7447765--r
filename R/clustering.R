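#' Cluster DE genes by their expression pattern across populations
#'
#' Standardizes each gene's profile of gene-by-population effect estimates to
#' zero mean and unit SD across populations, then clusters by hierarchical
#' agglomeration (Ward linkage on Euclidean distances) and cuts the
#' dendrogram into `2^n_levels` clusters — three binary levels of splitting
#' give the canonical 8 expression-pattern groups for a four-population
#' design. Genes with a constant profile (SD 0) cannot be standardized; they
#' enter with their centred raw profile and a message reports how many.
#'
#' @param effects Numeric matrix of effect estimates restricted to DE genes;
#'   rows = genes (named), columns = populations (>= 2).
#' @param n_levels Number of binary split levels; the cut yields
#'   `2^n_levels` clusters (default 3, i.e. 8 clusters). Must satisfy
#'   `nrow(effects) >= 2^n_levels`.
#' @return An object of class `cluster_assignment`: list with `assignments`
#'   (named integer vector, labels `1..2^n_levels` in order of first
#'   appearance along the gene order), `linkage_tree` (the `hclust` object),
#'   `standardized_profiles` (the matrix clustered), `leaf_order` (gene ids
#'   in dendrogram order, for heatmaps), `n_levels`.
#' @export
cluster_de_profiles <- function(effects, n_levels = 3) {
  effects <- as.matrix(effects)
  if (is.null(rownames(effects))) format_error("effects must have gene row names")
  if (ncol(effects) < 2) design_error("need >= 2 population columns to define a profile")
  if (n_levels < 0 || n_levels != round(n_levels)) {
    param_error("n_levels must be a non-negative integer")
  }
  k <- 2^n_levels
  if (nrow(effects) < k) {
    param_error(sprintf("fewer genes (%d) than requested clusters (%d)",
                        nrow(effects), k))
  }
  # Deterministic tie-break: operate in lexicographic gene order.
  effects <- effects[order(rownames(effects)), , drop = FALSE]
  mu <- rowMeans(effects)
  sd_ <- apply(effects, 1, stats::sd)
  flat <- sd_ == 0
  if (any(flat)) {
    message(sprintf("%d gene(s) with constant profile kept unstandardized (centred only)",
                    sum(flat)))
  }
  z <- sweep(effects, 1, mu)
  z[!flat, ] <- z[!flat, , drop = FALSE] / sd_[!flat]

  if (k == 1) {
    return(structure(
      list(assignments = stats::setNames(rep(1L, nrow(z)), rownames(z)),
           linkage_tree = NULL, standardized_profiles = z,
           leaf_order = rownames(z), n_levels = n_levels),
      class = "cluster_assignment"))
  }
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  # Relabel so cluster ids run 1..k in gene (row) order — stable across
  # permutations of the input rows.
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(
    list(assignments = stats::setNames(labels, rownames(z)),
         linkage_tree = tree,
         standardized_profiles = z,
         leaf_order = rownames(z)[tree$order],
         n_levels = n_levels),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d genes in %d clusters\n",
              length(x$assignments), length(unique(x$assignments))))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Write cluster assignments and a heatmap-ready matrix
#'
#' Writes `clusters.tsv` (gene, cluster) and `heatmap_matrix.tsv` (the
#' standardized profiles in dendrogram leaf order).
#'
#' @param assignment A `cluster_assignment`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_cluster_assignment <- function(assignment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cl_path <- file.path(dir, "clusters.tsv")
  utils::write.table(
    data.frame(gene = names(assignment$assignments),
               cluster = unname(assignment$assignments)),
    cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  hm <- assignment$standardized_profiles[assignment$leaf_order, , drop = FALSE]
  hm_path <- file.path(dir, "heatmap_matrix.tsv")
  utils::write.table(data.frame(gene = rownames(hm), hm, check.names = FALSE),
                     hm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(clusters = cl_path, heatmap = hm_path))
}
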