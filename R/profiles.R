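#' Split a profile into between-mouse and within-mouse parts
#'
#' The between-mouse profile B_i averages the replicates of each mouse; the
#' within-mouse profile W_i is replicate 1 minus that mean (for duplicate
#' samples this is the half-difference, so y_i1 = B_i + W_i and
#' y_i2 = B_i - W_i reconstruct exactly).
#'
#' @param profile Numeric vector over samples, named by (or aligned with)
#'   `samples$sample_id`.
#' @param samples Sample metadata table with `sample_id`, `mouse`,
#'   `replicate`, `tissue`.
#' @return A `ProfilePair`: list with `between` (named by mouse), `within`
#'   (`NULL` unless every mouse has exactly 2 replicates), `n_mice`,
#'   `tissue`.
#' @export
split_profiles <- function(profile, samples) {
  if (!is.null(names(profile))) {
    miss <- setdiff(samples$sample_id, names(profile))
    if (length(miss)) stop("profile missing sample: ", miss[1L])
    profile <- profile[samples$sample_id]
  } else if (length(profile) != nrow(samples)) {
    stop("profile length does not match sample table")
  }
  mice <- unique(samples$mouse)
  between <- vapply(mice, function(m) mean(profile[samples$mouse == m]),
                    numeric(1))
  names(between) <- mice
  k <- as.integer(table(samples$mouse))
  within <- NULL
  if (all(k == 2L)) {
    within <- vapply(mice, function(m) {
      i <- which(samples$mouse == m)
      i <- i[order(samples$replicate[i])]
      unname(profile[i[1L]] - between[m])
    }, numeric(1))
    names(within) <- mice
  }
  structure(list(between = between, within = within,
                 n_mice = length(mice),
                 tissue = unique(samples$tissue)[1L]),
            class = "ProfilePair")
}

#' Between- and within-mouse profile correlations
#'
#' r_b is the Pearson correlation of the two between-mouse profiles; r_w the
#' Pearson correlation of the within-mouse profiles. r_w is only meaningful
#' between profiles of the same tissue (replicate labels must correspond)
#' and errors otherwise.
#'
#' @param x,y `ProfilePair` objects from [split_profiles()] over the same
#'   mice.
#' @param which `"both"` (default), `"rb"` or `"rw"`.
#' @return Named numeric vector with `r_b` and/or `r_w` (`NA` when a profile
#'   has zero variance).
#' @export
profile_correlations <- function(x, y, which = c("both", "rb", "rw")) {
  which <- match.arg(which)
  stopifnot(inherits(x, "ProfilePair"), inherits(y, "ProfilePair"))
  if (!identical(names(x$between), names(y$between)))
    stop("profiles come from different designs (mouse sets differ)")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      message("zero-variance profile: correlation reported NA")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  out <- c()
  if (which %in% c("both", "rb"))
    out <- c(out, r_b = safe_cor(x$between, y$between))
  if (which %in% c("both", "rw")) {
    if (is.null(x$within) || is.null(y$within))
      stop("within-mouse profile undefined (needs exactly 2 replicates per mouse)")
    if (!identical(x$tissue, y$tissue))
      stop("r_w is only defined within one tissue (tissue tags differ)")
    out <- c(out, r_w = safe_cor(x$within, y$within))
  }
  out
}

#' Critical correlation magnitude from the Fisher transformation
#'
#' The critical |r| at level alpha is tanh(q / sqrt(n - 3)) where q is the
#' two-sided 1 - alpha/2 quantile of the reference distribution: standard
#' normal (`"normal"`, the textbook Fisher test) or Student t with 9
#' degrees of freedom (`"t9"`, the default convention that gives 0.66 at
#' n = 11 and 0.64 at n = 12 for alpha = 0.05).
#'
#' @param n Sample size used for the correlation (>= 4).
#' @param alpha Two-sided significance level.
#' @param reference `"t9"` (default) or `"normal"`.
#' @return Critical correlation magnitude in (0, 1).
#' @export
fisher_critical <- function(n, alpha = 0.05, reference = c("t9", "normal")) {
  reference <- match.arg(reference)
  if (n <= 3) stop("fisher_critical needs n >= 4")
  q <- switch(reference,
              normal = stats::qnorm(1 - alpha / 2),
              t9 = stats::qt(1 - alpha / 2, df = 9))
  tanh(q / sqrt(n - 3))
}

#' Median intraclass correlation of a module
#'
#' @param decomp A [decompose_variance()] result.
#' @param module_genes Member probe ids (all must appear in `decomp`).
#' @return Median of the members' intraclass correlation `c`.
#' @export
module_icc <- function(decomp, module_genes) {
  if (length(module_genes) == 0L) stop("empty module")
  idx <- match(module_genes, decomp$probe_id)
  if (anyNA(idx))
    stop("gene not in decomposition: ", module_genes[which(is.na(idx))[1L]])
  stats::median(decomp$icc[idx])
}
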