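#' Map probes across platforms by gene symbol
#'
#' For each non-control probe of study A with a gene symbol, candidate
#' probes of study B sharing the symbol (case-insensitive) are considered;
#' candidates with mean intensity below `min_intensity_b` are excluded, and
#' the candidate with the highest Pearson correlation to the A probe across
#' shared samples is selected (ties broken by probe id order).
#'
#' @param study_a,study_b [expression_study()] objects sharing sample
#'   identities.
#' @param min_intensity_b Mean-intensity floor for B probes (default 7).
#' @return A `CrossPlatformMap`: list with `pairs` (probe_a, probe_b,
#'   gene_symbol, r) and `exclusions` (probe_a, reason).
#' @export
map_platforms <- function(study_a, study_b, min_intensity_b = 7) {
  shared <- intersect(colnames(study_a$values), colnames(study_b$values))
  if (length(shared) == 0L) stop("no shared samples between platforms")
  va <- study_a$values[, shared, drop = FALSE]
  vb <- study_b$values[, shared, drop = FALSE]
  pb <- study_b$probes
  b_mean <- rowMeans(vb)
  b_sym <- toupper(pb$gene_symbol)
  pairs <- list()
  excl <- list()
  pa <- study_a$probes
  for (i in which(!pa$is_negative_control)) {
    sym <- toupper(pa$gene_symbol[i])
    if (is.na(sym) || !nzchar(sym)) {
      excl[[length(excl) + 1L]] <- c(pa$probe_id[i], "no gene symbol")
      next
    }
    cand <- which(b_sym == sym & !pb$is_negative_control)
    if (length(cand) == 0L) {
      excl[[length(excl) + 1L]] <- c(pa$probe_id[i], "no symbol match")
      next
    }
    cand <- cand[b_mean[cand] >= min_intensity_b]
    if (length(cand) == 0L) {
      excl[[length(excl) + 1L]] <- c(pa$probe_id[i], "intensity filter")
      next
    }
    cand <- cand[order(pb$probe_id[cand])]
    r <- as.vector(stats::cor(t(vb[cand, , drop = FALSE]), va[i, ]))
    best <- cand[which.max(r)]
    pairs[[length(pairs) + 1L]] <-
      data.frame(probe_a = pa$probe_id[i], probe_b = pb$probe_id[best],
                 gene_symbol = pa$gene_symbol[i], r = max(r),
                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(probe_a = character(), probe_b = character(),
               gene_symbol = character(), r = numeric())
  excl <- if (length(excl))
    data.frame(probe_a = vapply(excl, `[`, "", 1L),
               reason = vapply(excl, `[`, "", 2L), stringsAsFactors = FALSE)
  else data.frame(probe_a = character(), reason = character())
  structure(list(pairs = pairs, exclusions = excl,
                 shared_samples = shared),
            class = "CrossPlatformMap")
}

#' Compare module eigengenes across platforms
#'
#' For each module defined on platform A, the eigengene is recomputed on
#' platform B from the mapped member probes (same sign and scaling
#' conventions) and correlated with the platform-A eigengene over the
#' shared samples. Because the eigengene sign is a per-platform majority
#' convention, the sign-aligned (absolute) correlation is reported.
#'
#' @param map A [map_platforms()] result.
#' @param modules A [detect_modules()] `ModuleSet` from platform A.
#' @param study_b The platform-B [expression_study()].
#' @param min_genes Minimum mapped members; smaller modules are skipped
#'   with a note (default 3).
#' @return Data frame with `module`, `n_mapped`, `r`, `varexp_b`, `note`.
#' @export
cross_platform_eigengenes <- function(map, modules, study_b, min_genes = 3) {
  stopifnot(inherits(map, "CrossPlatformMap"), inherits(modules, "ModuleSet"))
  shared <- map$shared_samples
  rows <- lapply(names(modules$modules), function(m) {
    mod <- modules$modules[[m]]
    hit <- map$pairs[map$pairs$probe_a %in% mod$genes, , drop = FALSE]
    if (nrow(hit) < min_genes)
      return(data.frame(module = m, n_mapped = nrow(hit), r = NA_real_,
                        varexp_b = NA_real_,
                        note = "skipped: fewer mapped genes than minimum",
                        stringsAsFactors = FALSE))
    eb <- eigengene(study_b$values[, shared, drop = FALSE],
                    genes = unique(hit$probe_b))
    ea <- mod$eigengene[shared]
    data.frame(module = m, n_mapped = nrow(hit),
               r = abs(stats::cor(ea, eb$profile)),
               varexp_b = eb$varexp, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
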