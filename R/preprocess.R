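#' Quantile-normalize a study
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of the order statistics. Ties within a column
#' receive the mean of the quantile values they span. Applied within one
#' tissue at a time in the full pipeline.
#'
#' @param study An [expression_study()] object with at least 2 samples.
#' @return The study with normalized `values`.
#' @export
quantile_normalize <- function(study) {
  if (ncol(study$values) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(study$values))) stop("non-finite values in input")
  v <- limma::normalizeQuantiles(study$values, ties = TRUE)
  dimnames(v) <- dimnames(study$values)
  study$values <- v
  study
}

#' Remove per-gene batch effects
#'
#' For each gene, a robust location estimate per batch is subtracted and the
#' gene's global robust location restored, so that (with the median
#' estimator) batch medians of every gene coincide afterwards. Batches with
#' a single sample are skipped with a warning.
#'
#' @param study An [expression_study()] object.
#' @param estimator `"median"` (default, exact and dependency-free) or
#'   `"huber"` (Huber M-estimator of location, the hook for an
#'   MM-regression-style robust fit).
#' @return The study with corrected `values`.
#' @export
correct_batch <- function(study, estimator = c("median", "huber")) {
  estimator <- match.arg(estimator)
  batch <- study$samples$batch
  if (is.null(batch) || all(is.na(batch)) || length(unique(batch)) < 2L) {
    warning("no usable batch labels; returning values unchanged")
    return(study)
  }
  loc <- switch(estimator,
    median = function(x) stats::median(x),
    huber = function(x) {
      if (stats::mad(x) == 0) stats::median(x) else MASS::huber(x)$mu
    })
  v <- study$values
  global <- apply(v, 1L, loc)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2L) {
      warning("batch ", b, " has a single sample; skipped")
      next
    }
    bloc <- apply(v[, idx, drop = FALSE], 1L, loc)
    v[, idx] <- v[, idx, drop = FALSE] - bloc + global
  }
  study$values <- v
  study
}
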