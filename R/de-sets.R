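#' Population-exclusive up/down DE gene sets
#'
#' For each population, the genes called DE there and in no other population,
#' split by the sign of the gene-by-population effect estimate into
#' overexpressed (`up`) and underexpressed (`down`). A called gene whose
#' effect estimate is exactly zero has no direction and is assigned to
#' neither set (a message reports how many).
#'
#' @param calls Named list of `de_calls`, one per population, all derived
#'   from the same gene universe.
#' @return An object of class `exclusive_de_sets`: named list (one element
#'   per population) of lists with `population`, `up`, `down` (character
#'   vectors of gene ids).
#' @export
exclusive_de_sets <- function(calls) {
  stopifnot(length(calls) >= 1, all(vapply(calls, inherits, TRUE, "de_calls")))
  pops <- names(calls)
  if (is.null(pops)) {
    pops <- vapply(calls, function(cl) cl$population %||% NA_character_, "")
    if (anyNA(pops)) alignment_error("calls must be named by population")
    names(calls) <- pops
  }
  universe <- calls[[1]]$genes
  for (cl in calls[-1]) {
    if (!identical(sort(cl$genes), sort(universe))) {
      alignment_error("call sets derive from different gene universes")
    }
  }
  de_names <- lapply(calls, function(cl) names(cl$de_genes))
  out <- lapply(pops, function(p) {
    others <- unique(unlist(de_names[setdiff(pops, p)]))
    mine <- calls[[p]]$de_genes
    excl <- mine[!(names(mine) %in% others)]
    n_unsigned <- sum(is.na(excl) | excl == 0)
    if (n_unsigned > 0) {
      message(sprintf("%s: %d exclusive DE gene(s) with undefined sign omitted",
                      p, n_unsigned))
    }
    list(population = p,
         up = sort(names(excl)[!is.na(excl) & excl > 0]),
         down = sort(names(excl)[!is.na(excl) & excl < 0]))
  })
  names(out) <- pops
  structure(out, class = "exclusive_de_sets")
}

#' @export
print.exclusive_de_sets <- function(x, ...) {
  cat("Exclusive DE sets (called in exactly one population):\n")
  for (s in x) {
    cat(sprintf("  %-22s up: %4d  down: %4d\n",
                s$population, length(s$up), length(s$down)))
  }
  invisible(x)
}

#' Write exclusive DE sets as one TSV per population
#'
#' Each file lists gene, direction (`up`/`down`), effect and posterior.
#'
#' @param sets An `exclusive_de_sets` object.
#' @param calls The `de_calls` list the sets were derived from.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_exclusive_de_sets <- function(sets, calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in sets) {
    tab <- calls[[s$population]]$table
    rows <- tab[tab$gene %in% c(s$up, s$down), , drop = FALSE]
    rows$direction <- ifelse(rows$gene %in% s$up, "up", "down")
    p <- file.path(dir, sprintf("exclusive_de_%s.tsv", s$population))
    utils::write.table(rows[, c("gene", "direction", "effect", "posterior")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[s$population] <- p
  }
  invisible(paths)
}
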