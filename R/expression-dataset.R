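#' Construct an expression dataset
#'
#' Bundles a genes x arrays matrix of log-expression values with the mapping
#' from each array to the cell population it was sorted from. This is the
#' input container consumed by [fit_reml()].
#'
#' @param values Numeric matrix of log-expression values; rows are genes,
#'   columns are arrays. Row and column names are required and must be unique.
#' @param array_population Named character vector mapping array id (name) to
#'   population label (value). Every column of `values` must appear.
#' @param populations Optional character vector fixing the population order
#'   (default: order of first appearance in `array_population`).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `array_population` and `populations`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
#' ds <- expression_dataset(m, c(a1 = "P1", a2 = "P1", a3 = "P2", a4 = "P2"))
expression_dataset <- function(values, array_population, populations = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    format_error("expression values contain missing cells; complete matrices are required")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    format_error("expression matrix must carry gene (row) and array (column) names")
  }
  if (anyDuplicated(rownames(values))) format_error("duplicated gene ids")
  if (anyDuplicated(colnames(values))) format_error("duplicated array ids")
  if (is.null(names(array_population))) {
    format_error("array_population must be a named vector (names = array ids)")
  }
  missing_arr <- setdiff(colnames(values), names(array_population))
  if (length(missing_arr)) {
    alignment_error(paste0("arrays missing from metadata: ",
                           paste(missing_arr, collapse = ", ")))
  }
  extra_arr <- setdiff(names(array_population), colnames(values))
  if (length(extra_arr)) {
    alignment_error(paste0("metadata arrays absent from matrix: ",
                           paste(extra_arr, collapse = ", ")))
  }
  array_population <- array_population[colnames(values)]
  if (is.null(populations)) {
    populations <- unique(unname(array_population))
  } else if (!setequal(populations, unique(array_population))) {
    alignment_error("declared populations do not match the metadata populations")
  }
  structure(
    list(values = values,
         array_population = array_population,
         populations = as.character(populations)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d arrays\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$array_population, levels = x$populations))
  cat("arrays per population:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Write an expression dataset to TSV files
#'
#' Writes `expression.tsv` (first column `gene_id`, one column per array) and
#' `metadata.tsv` (`array_id`, `population`) under `dir`.
#'
#' @param dataset An [expression_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(array_id = names(dataset$array_population),
                     population = unname(dataset$array_population))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, metadata = meta_path))
}

#' Read an expression matrix and array metadata from TSV
#'
#' Reads a genes x arrays table (first column gene ids, header of array ids)
#' and a metadata table with columns `array_id` and `population`, optionally
#' log-transforming RPKM-scale values. Genes with zero variance across all
#' arrays are dropped (their count is reported in a message and stored in the
#' `n_dropped` attribute) because they carry no information for any random
#' term of the model.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param log_transform `"none"` (values are already on the log scale) or
#'   `"log2_offset"` (values are non-negative RPKM; transformed to
#'   `log2(x + offset)`).
#' @param offset Offset added before taking log2 (default 1).
#' @return An [expression_dataset()]; attribute `n_dropped` records the number
#'   of zero-variance genes removed.
#' @export
read_expression <- function(matrix_path, metadata_path,
                            log_transform = c("none", "log2_offset"),
                            offset = 1) {
  log_transform <- match.arg(log_transform)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) format_error("expression TSV needs a gene id column plus arrays")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("array_id", "population") %in% names(meta))) {
    format_error("metadata TSV must have columns array_id and population")
  }
  if (log_transform == "log2_offset") {
    if (anyNA(m)) format_error("missing RPKM values")
    if (min(m) < 0) format_error("negative RPKM values are not a valid expression scale")
    m <- log2(m + offset)
  }
  keep <- apply(m, 1, stats::sd) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d gene(s) with zero variance across arrays", n_dropped))
    m <- m[keep, , drop = FALSE]
  }
  pop <- stats::setNames(as.character(meta$population), as.character(meta$array_id))
  ds <- expression_dataset(m, pop)
  attr(ds, "n_dropped") <- n_dropped
  ds
}
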