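#' Construct an expression study
#'
#' Bundles a genes x samples matrix of log2 intensities with the nested
#' design metadata (mouse, cage, replicate, batch, tissue) and probe
#' annotation (gene symbol, negative-control flag). All downstream
#' operations take this container.
#'
#' @param values Numeric matrix, rows = probes, columns = samples. Row names
#'   must be probe ids and column names sample ids.
#' @param samples Data frame with columns `sample_id`, `mouse`, `cage`,
#'   `replicate`, `batch`, `tissue`; one row per matrix column.
#' @param probes Data frame with columns `probe_id`, `gene_symbol`,
#'   `is_negative_control`; one row per matrix row.
#'
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values`, `samples`, `probes`, `G` (probe count) and `balanced`
#'   (logical, equal replicate count per mouse).
#' @export
expression_study <- function(values, samples, probes) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(!is.finite(values))) stop("expression values must be finite")

  need_s <- c("sample_id", "mouse", "cage", "replicate", "batch", "tissue")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  need_p <- c("probe_id", "gene_symbol", "is_negative_control")
  miss <- setdiff(need_p, names(probes))
  if (length(miss)) stop("probe metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(probes) == 0L) stop("no probes: probe metadata table is empty")

  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         probes$probe_id[duplicated(probes$probe_id)][1L])
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])

  if (is.null(colnames(values))) stop("matrix must have sample ids as column names")
  if (is.null(rownames(values))) stop("matrix must have probe ids as row names")

  extra_col <- setdiff(colnames(values), samples$sample_id)
  if (length(extra_col))
    stop("matrix column not in sample metadata: ", extra_col[1L])
  extra_meta <- setdiff(samples$sample_id, colnames(values))
  if (length(extra_meta))
    stop("sample in metadata missing from matrix: ", extra_meta[1L])
  if (!identical(sort(rownames(values)), sort(as.character(probes$probe_id))))
    stop("matrix row names do not match probe_id column")

  # align metadata to matrix order
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  probes <- probes[match(rownames(values), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  probes$is_negative_control <- as.logical(probes$is_negative_control)

  # replicate labels distinct within each mouse
  for (m in unique(samples$mouse)) {
    reps <- samples$replicate[samples$mouse == m]
    if (anyDuplicated(reps))
      stop("duplicate replicate label within mouse ", m)
  }
  reps_per_mouse <- table(samples$mouse)
  balanced <- length(unique(as.integer(reps_per_mouse))) == 1L

  structure(
    list(values = values, samples = samples, probes = probes,
         G = nrow(values), balanced = balanced),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", x$G, "probes x", ncol(x$values), "samples\n")
  cat("  mice:", length(unique(x$samples$mouse)),
      " cages:", length(unique(x$samples$cage)),
      " batches:", length(unique(x$samples$batch)),
      " tissues:", paste(unique(x$samples$tissue), collapse = ","), "\n")
  cat("  negative controls:", sum(x$probes$is_negative_control),
      if (x$balanced) " (balanced design)\n" else " (UNBALANCED design)\n")
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV with first column `probe_id` and one column per sample.
#' @param samples_path TSV with sample metadata (`sample_id`, `mouse`, `cage`,
#'   `replicate`, `batch`, `tissue`).
#' @param probes_path TSV with probe metadata (`probe_id`, `gene_symbol`,
#'   `is_negative_control`).
#' @return An [expression_study()] object.
#' @export
read_study <- function(matrix_path, samples_path, probes_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(mat)[1L] != "probe_id")
    stop("matrix file ", matrix_path, ": first column must be 'probe_id'")
  values <- as.matrix(mat[, -1L, drop = FALSE])
  rownames(values) <- mat$probe_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  probes <- utils::read.delim(probes_path, stringsAsFactors = FALSE)
  expression_study(values, samples, probes)
}

# internal: per-mouse mean matrix (genes x mice), mice in first-appearance order
.mouse_means <- function(study) {
  mouse <- factor(study$samples$mouse, levels = unique(study$samples$mouse))
  M <- stats::model.matrix(~ mouse - 1)
  counts <- colSums(M)
  mm <- study$values %*% M
  sweep(mm, 2L, counts, "/")
}

.design_info <- function(study) {
  s <- study$samples
  mouse <- factor(s$mouse, levels = unique(s$mouse))
  list(mouse = mouse,
       n_mice = nlevels(mouse),
       k = as.integer(table(mouse))[1L],
       balanced = study$balanced,
       n_samples = ncol(study$values))
}
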