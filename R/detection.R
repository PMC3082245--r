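#' Call expressed genes from negative-control probes
#'
#' The detection threshold is the 95th percentile (linear interpolation
#' between order statistics) of the pooled per-mouse replicate means of all
#' negative-control probes. Under the default `"mouse-mean"` rule a gene is
#' expressed when its best per-mouse replicate mean exceeds the threshold;
#' under `"both-samples"` both replicates of at least one mouse must exceed
#' it individually.
#'
#' @param study An [expression_study()] object containing at least one
#'   negative-control probe (or supply `threshold`).
#' @param rule `"mouse-mean"` (default) or `"both-samples"`.
#' @param probability Percentile used for the threshold (default 0.95).
#' @param threshold Optional explicit intensity threshold, overriding the
#'   negative-control computation.
#' @return A `DetectionCall`: list with `threshold`, `rule`, and `expressed`,
#'   a logical vector named by probe id (`NA` for negative controls).
#' @export
detect_expressed <- function(study, rule = c("mouse-mean", "both-samples"),
                             probability = 0.95, threshold = NULL) {
  rule <- match.arg(rule)
  is_nc <- study$probes$is_negative_control
  if (is.null(threshold)) {
    if (!any(is_nc))
      stop("no negative-control probes: supply an explicit 'threshold'")
    nc_means <- .mouse_means(study)[is_nc, , drop = FALSE]
    threshold <- unname(stats::quantile(as.vector(nc_means), probability,
                                        type = 7))
  }
  mouse <- factor(study$samples$mouse, levels = unique(study$samples$mouse))
  if (rule == "mouse-mean") {
    best <- apply(.mouse_means(study), 1L, max)
  } else {
    # per-mouse minimum over replicates, then best mouse
    per_mouse_min <- vapply(levels(mouse), function(m) {
      apply(study$values[, mouse == m, drop = FALSE], 1L, min)
    }, numeric(study$G))
    best <- apply(per_mouse_min, 1L, max)
  }
  expressed <- best > threshold
  expressed[is_nc] <- NA
  names(expressed) <- study$probes$probe_id
  structure(list(threshold = threshold, rule = rule, expressed = expressed),
            class = "DetectionCall")
}

#' @export
print.DetectionCall <- function(x, ...) {
  cat("DetectionCall (rule:", x$rule, ") threshold", format(x$threshold), "\n")
  cat("  expressed:", sum(x$expressed, na.rm = TRUE), "of",
      sum(!is.na(x$expressed)), "probes\n")
  invisible(x)
}

#' Maximal fold change across mice
#'
#' Per gene, the antilogged range of per-mouse mean log2 expression:
#' 2^(max mouse mean - min mouse mean). Threshold counts in the pipeline
#' summary apply the thresholds strictly (`>`).
#'
#' @param study An [expression_study()] object with at least 2 mice.
#' @return Data frame with columns `probe_id`, `max_fc` (ratio scale,
#'   always >= 1).
#' @export
max_fold_change <- function(study) {
  mm <- .mouse_means(study)
  if (ncol(mm) < 2L) stop("max_fold_change needs >= 2 mice")
  rng <- apply(mm, 1L, max) - apply(mm, 1L, min)
  data.frame(probe_id = study$probes$probe_id, max_fc = 2^rng,
             stringsAsFactors = FALSE)
}
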