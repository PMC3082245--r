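#' Build a weighted coexpression network
#'
#' Adjacency between two genes is the square of their Pearson correlation
#' across all samples (unsigned, soft power 2 on |r|). The topological
#' overlap matrix combines direct adjacency with shared neighbourhood:
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, with connectivity k_i = sum_u a_iu over u != i, and unit
#' diagonal.
#'
#' @param x An [expression_study()] object or a numeric genes x samples
#'   matrix.
#' @param genes Optional probe ids restricting the network (e.g. the
#'   variable genes).
#' @return A `CoexpressionNetwork`: list with `genes`, `adjacency`, `tom`.
#' @export
build_network <- function(x, genes = NULL) {
  v <- if (inherits(x, "ExpressionStudy")) x$values else as.matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("gene not in matrix: ", miss[1L])
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) < 3L) stop("network needs >= 3 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene: ", rownames(v)[which(sds == 0)[1L]])
  r <- stats::cor(t(v))
  a <- r * r
  diag(a) <- 1
  k <- colSums(a) - 1
  num <- a %*% a - 2 * a + a          # sum_{u != i,j} a_iu a_uj + a_ij
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- pmin(pmax(tom, 0), 1)
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  structure(list(genes = rownames(v), adjacency = a, tom = tom),
            class = "CoexpressionNetwork")
}

# conventional module colour order; size rank 1 = turquoise. "gold" takes
# the fourth slot (alias of the conventional yellow).
module_colours <- function() {
  c("turquoise", "blue", "brown", "gold", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue")
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on 1 - TOM, followed by a
#' dynamic cut of the dendrogram at a deep-split-controlled fraction of the
#' maximum merge height, pruning of members whose correlation with their
#' cluster eigengene falls below `prune_cor` (which removes noise genes
#' chained onto a cluster by average linkage), dissolution of clusters with
#' `min_size` or fewer members to unassigned, and iterative merging of
#' modules whose eigengenes correlate above `merge_threshold`. Labels
#' follow the conventional colour order by decreasing module size.
#'
#' @param network A [build_network()] result.
#' @param x The expression source the network was built from (study or
#'   matrix); needed for the eigengene-based merge step.
#' @param min_size Modules must have strictly more than this many members
#'   (default 25).
#' @param merge_threshold Eigengene correlation above which two modules are
#'   merged (default 0.8).
#' @param prune_cor Minimum absolute correlation of a member with its
#'   cluster eigengene (default 0.3).
#' @param deep_split Integer 0-4 controlling cut depth (higher = lower cut
#'   = smaller clusters); default 2.
#' @param cut_height Optional explicit cut height on the 1 - TOM scale,
#'   overriding `deep_split`.
#' @return A `ModuleSet`: list with `assignment` (named character, `NA` =
#'   unassigned) and `modules`, a named list carrying per module `genes`,
#'   `eigengene`, `varexp`, `positive_set`, `negative_set`, `size`.
#' @export
detect_modules <- function(network, x, min_size = 25, merge_threshold = 0.8,
                           prune_cor = 0.3, deep_split = 2,
                           cut_height = NULL) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  v <- if (inherits(x, "ExpressionStudy")) x$values else as.matrix(x)
  v <- v[network$genes, , drop = FALSE]
  genes <- network$genes
  empty <- structure(list(assignment = stats::setNames(
    rep(NA_character_, length(genes)), genes),
    modules = list(),
    params = list(min_size = min_size, merge_threshold = merge_threshold)),
    class = "ModuleSet")
  if (length(genes) <= min_size) {
    warning("fewer genes than min_size: no modules")
    return(empty)
  }
  h <- stats::hclust(stats::as.dist(1 - network$tom), method = "average")
  if (is.null(cut_height)) {
    # adaptive cut: the largest gap between consecutive merge heights in the
    # upper part of the tree separates branch structure from the agglomerate
    # top; deep_split widens the searched region (deeper cuts). Over-splits
    # are healed by the eigengene merge step.
    q <- c(0.75, 0.6, 0.5, 0.35, 0.2)[pmin(pmax(deep_split, 0), 4) + 1]
    hs <- sort(h$height)
    lo <- stats::quantile(hs, q, type = 7)
    cand <- which(hs[-length(hs)] >= lo)
    if (length(cand) == 0L) cand <- length(hs) - 1L
    gaps <- hs[cand + 1L] - hs[cand]
    i <- cand[which.max(gaps)]
    cut_height <- (hs[i] + hs[i + 1L]) / 2
  }
  cl <- stats::cutree(h, h = cut_height)
  eg <- function(g) eigengene(v, g)
  # prune weakly attached members, then apply the size rule
  mods <- lapply(unique(cl), function(ci) {
    g <- genes[cl == ci]
    if (length(g) < 2L) return(g)
    e <- eg(g)
    cors <- as.vector(stats::cor(t(v[g, , drop = FALSE]), e$profile))
    g[abs(cors) >= prune_cor]
  })
  mods <- mods[lengths(mods) > min_size]
  if (length(mods) == 0L) {
    warning("no cluster exceeds min_size: no modules")
    return(empty)
  }
  repeat {
    if (length(mods) < 2L) break
    E <- vapply(mods, function(g) eg(g)$profile, numeric(ncol(v)))
    C <- stats::cor(E)
    C[lower.tri(C, diag = TRUE)] <- -Inf
    mx <- max(C)
    if (mx <= merge_threshold) break
    ij <- which(C == mx, arr.ind = TRUE)[1L, ]
    mods[[ij[1L]]] <- c(mods[[ij[1L]]], mods[[ij[2L]]])
    mods <- mods[-ij[2L]]
  }
  # order by decreasing size, ties by first gene position
  first_pos <- vapply(mods, function(g) min(match(g, genes)), numeric(1))
  ord <- order(-lengths(mods), first_pos)
  mods <- mods[ord]
  cols <- module_colours()
  labels <- if (length(mods) <= length(cols)) cols[seq_along(mods)]
            else c(cols, paste0("module", seq.int(length(cols) + 1,
                                                  length(mods))))[seq_along(mods)]
  assignment <- stats::setNames(rep(NA_character_, length(genes)), genes)
  modules <- list()
  for (i in seq_along(mods)) {
    g <- mods[[i]][order(match(mods[[i]], genes))]
    assignment[g] <- labels[i]
    e <- eg(g)
    modules[[labels[i]]] <- list(genes = g, eigengene = e$profile,
                                 varexp = e$varexp,
                                 positive_set = e$positive_set,
                                 negative_set = e$negative_set,
                                 size = length(g))
  }
  structure(list(assignment = assignment, modules = modules,
                 params = list(min_size = min_size,
                               merge_threshold = merge_threshold,
                               prune_cor = prune_cor,
                               cut_height = cut_height)),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat("ModuleSet:", length(x$modules), "modules,",
      sum(is.na(x$assignment)), "unassigned of", length(x$assignment),
      "genes\n")
  for (m in names(x$modules))
    cat(sprintf("  %-12s size %4d  varexp %.2f\n", m, x$modules[[m]]$size,
                x$modules[[m]]$varexp))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix
#' across samples. The sign is chosen so the strict majority of member
#' genes correlate positively with the eigengene (ties resolved toward a
#' positive correlation sum); the profile is rescaled so its variance
#' equals the median per-gene variance of the members. `varexp` is the
#' leading eigenvalue's share of the standardized variance.
#'
#' @param x An [expression_study()] object or genes x samples matrix.
#' @param genes Optional member probe ids; default all rows.
#' @return List with `profile` (named by sample), `varexp`,
#'   `positive_set`, `negative_set` (member ids split by sign of their
#'   correlation with the eigengene).
#' @export
eigengene <- function(x, genes = NULL) {
  v <- if (inherits(x, "ExpressionStudy")) x$values else as.matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("gene not in matrix: ", miss[1L])
    v <- v[genes, , drop = FALSE]
  }
  if (nrow(v) == 0L) stop("empty module")
  ids <- rownames(v)
  if (nrow(v) == 1L) {
    prof <- v[1L, ] - mean(v[1L, ])
    return(list(profile = prof, varexp = 1,
                positive_set = ids, negative_set = character()))
  }
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) stop("constant gene: ", ids[which(sds == 0)[1L]])
  Z <- (v - rowMeans(v)) / sds
  sv <- svd(Z)
  e <- sv$v[, 1L]
  varexp <- sv$d[1L]^2 / sum(sv$d^2)
  cors <- as.vector(stats::cor(t(v), e))
  npos <- sum(cors > 0)
  nneg <- sum(cors < 0)
  flip <- npos < nneg || (npos == nneg && sum(cors) < 0)
  if (flip) {
    e <- -e
    cors <- -cors
  }
  med_var <- stats::median(apply(v, 1L, stats::var))
  e <- e - mean(e)
  profile <- e * sqrt(med_var) / stats::sd(e)
  names(profile) <- colnames(v)
  list(profile = profile, varexp = varexp,
       positive_set = ids[cors > 0], negative_set = ids[cors <= 0])
}
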