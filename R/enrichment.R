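#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member genes. Duplicate genes within a line are collapsed; lines
#' with fewer than 3 fields and duplicate set names are errors.
#'
#' @param path GMT file path.
#' @param source Optional tag (e.g. `"GO_BP"`, `"KEGG"`) carried along.
#' @return A `GeneSetCollection`: list with `sets` (named list of gene
#'   vectors), `description`, `source`.
#' @export
read_gmt <- function(path, source = NA_character_) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 tab-separated fields")
    if (f[1L] %in% names(sets))
      stop("GMT duplicate set name: ", f[1L])
    sets[[f[1L]]] <- unique(f[-(1:2)])
    descr[f[1L]] <- f[2L]
  }
  structure(list(sets = sets, description = descr, source = source),
            class = "GeneSetCollection")
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the overlap of `genes` with the set inside `universe` is
#' tested with the upper-tail hypergeometric probability
#' P(X >= overlap | N, K, n). Gene symbols are compared case-insensitively.
#'
#' @param genes Query gene symbols (module or signed subset); must lie in
#'   `universe`.
#' @param universe Background gene symbols (e.g. variable genes present in
#'   the database, one probe per gene).
#' @param collection A [read_gmt()] collection.
#' @param ease If `TRUE`, use the conservative EASE-style variant that
#'   tests overlap - 1.
#' @return Data frame (`EnrichmentResult`) with columns `set`, `in_module`,
#'   `in_category`, `overlap`, `percent`, `p_hyper`, sorted by p.
#' @export
hypergeom_enrich <- function(genes, universe, collection, ease = FALSE) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  genes <- unique(toupper(genes))
  if (length(setdiff(genes, universe)))
    stop("query genes must be a subset of the universe")
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(collection$sets), function(s) {
    set <- intersect(toupper(collection$sets[[s]]), universe)
    K <- length(set)
    x <- length(intersect(genes, set))
    xx <- if (ease) max(x - 1L, 0L) else x
    p <- stats::phyper(xx - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, in_module = n, in_category = K, overlap = x,
               percent = if (K > 0) 100 * x / K else NA_real_,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hyper, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Test overlap of two gene sets
#'
#' Upper-tail hypergeometric test of |A intersect B| within a common
#' universe, with a Bonferroni correction over `n_tests` comparisons.
#'
#' @param genes_a,genes_b Gene sets (subsets of `universe`).
#' @param universe Background gene set.
#' @param n_tests Number of comparisons for the Bonferroni correction.
#' @param alpha Significance level applied to the adjusted p.
#' @return List with `overlap`, `p`, `p_adjusted`, `significant`.
#' @export
module_overlap <- function(genes_a, genes_b, universe, n_tests = 1,
                           alpha = 0.05) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  a <- unique(toupper(genes_a))
  b <- unique(toupper(genes_b))
  if (length(setdiff(a, universe)) || length(setdiff(b, universe)))
    stop("both gene sets must be subsets of the universe")
  x <- length(intersect(a, b))
  p <- stats::phyper(x - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  p_adj <- min(1, p * n_tests)
  list(overlap = x, p = p, p_adjusted = p_adj,
       significant = p_adj < alpha)
}

#' Shared-enrichment rule for a category across two modules
#'
#' Two modules share enrichment for a category when each contains at least
#' 4 genes of the category and both enrichment p-values are below 0.01.
#'
#' @param results_a,results_b [hypergeom_enrich()] results for the two
#'   modules.
#' @param category Set name to compare.
#' @param min_overlap,max_p Rule constants (defaults 4 and 0.01).
#' @return Logical flag; `FALSE` with a `note` attribute when the category
#'   is missing from either result.
#' @export
shared_enrichment <- function(results_a, results_b, category,
                              min_overlap = 4, max_p = 0.01) {
  ra <- results_a[results_a$set == category, , drop = FALSE]
  rb <- results_b[results_b$set == category, , drop = FALSE]
  if (nrow(ra) == 0L || nrow(rb) == 0L)
    return(structure(FALSE, note = paste0("category '", category,
                                          "' missing from a result")))
  ra$overlap >= min_overlap && rb$overlap >= min_overlap &&
    ra$p_hyper < max_p && rb$p_hyper < max_p
}
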