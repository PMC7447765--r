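#' Hypergeometric over-representation analysis with BH correction
#'
#' Tests each annotation term for over-representation of a gene set within a
#' universe: with `N` universe genes, `K` of them annotated to the term, and
#' a query set of size `n` overlapping the term in `k` genes, the p-value is
#' the hypergeometric upper tail `P(X >= k)`. P-values are adjusted across
#' all tested terms by Benjamini-Hochberg and flagged at `fdr_cutoff`
#' (default 0.05). One-sided over-representation only; depletion is not
#' tested.
#'
#' @param gene_set Character vector of query gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of all genes eligible for selection
#'   (typically every gene in the fitted dataset).
#' @param annotations Named list mapping term id to a character vector of
#'   member gene ids (see [read_annotation_map()] / [read_gmt()]); an
#'   optional `term_names` attribute (named character vector) supplies
#'   display names. Memberships are restricted to the universe; terms left
#'   empty are dropped.
#' @param fdr_cutoff BH-adjusted significance cutoff, default 0.05.
#' @return Data frame with one row per tested term, sorted by p-value:
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich <- function(gene_set, universe, annotations, fdr_cutoff = 0.05) {
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  offenders <- setdiff(gene_set, universe)
  if (length(offenders)) {
    alignment_error(paste0("gene_set members absent from universe: ",
                           paste(utils::head(offenders, 10), collapse = ", "),
                           if (length(offenders) > 10) ", ..."))
  }
  term_names <- attr(annotations, "term_names")
  ann <- lapply(annotations, function(g) intersect(unique(g), universe))
  ann <- ann[lengths(ann) > 0]
  if (!length(ann)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  N <- length(universe)
  n <- length(gene_set)
  K <- lengths(ann)
  k <- vapply(ann, function(g) length(intersect(g, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(ann),
                    term_name = if (is.null(term_names)) names(ann) else {
                      ifelse(is.na(term_names[names(ann)]),
                             names(ann), term_names[names(ann)])
                    },
                    k = k, n = n, K = unname(K), N = N,
                    p_value = unname(p), fdr = unname(fdr),
                    significant = unname(fdr) < fdr_cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Read an annotation map from a two-column TSV
#'
#' Expects columns `term_id` and `gene_id` (header required); an optional
#' sidecar TSV with columns `term_id` and `term_name` supplies display names.
#'
#' @param path Path to the term-gene TSV.
#' @param names_path Optional path to the term-name sidecar TSV.
#' @return Named list term id -> gene id vector, with a `term_names`
#'   attribute when a sidecar is given.
#' @export
read_annotation_map <- function(path, names_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(tab))) {
    format_error("annotation TSV must have columns term_id and gene_id")
  }
  ann <- split(as.character(tab$gene_id), as.character(tab$term_id))
  if (!is.null(names_path)) {
    nm <- utils::read.delim(names_path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "term_name") %in% names(nm))) {
      format_error("term-name sidecar must have columns term_id and term_name")
    }
    attr(ann, "term_names") <- stats::setNames(as.character(nm$term_name),
                                               as.character(nm$term_id))
  }
  ann
}

#' Read an annotation map in GMT format
#'
#' One term per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list term id -> gene id vector with a `term_names`
#'   attribute holding the descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) format_error("GMT lines need term, description and >= 1 gene")
  ids <- vapply(parts, `[[`, "", 1)
  ann <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(ann) <- ids
  attr(ann, "term_names") <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  ann
}
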