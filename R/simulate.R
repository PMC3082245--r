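#' Configuration for the replicated-design study simulator
#'
#' Defaults mirror the study design the analysis assumes: 12 mice housed as
#' pairs in 6 cages, two tissue samples per mouse (24 arrays), processed in
#' two batches of three cages. Per-gene log2 values are Gaussian sums of a
#' cage effect, a mouse-within-cage effect and a within-mouse term; planted
#' coexpression modules add a shared latent factor (per mouse or per sample)
#' scaled by a loading. Non-expressed genes and negative-control probes are
#' drawn from a low-intensity background distribution.
#'
#' @param n_genes Number of non-control probes.
#' @param n_cages,mice_per_cage,reps_per_mouse Design (default 6, 2, 2).
#' @param sigma2_cage,sigma2_mouse,sigma2_within Variance components in
#'   (log2 units)^2; scalars or per-gene vectors.
#' @param gene_mean_range Interval of baseline log2 means for expressed genes.
#' @param frac_expressed Fraction of genes carrying signal; the remainder are
#'   background draws.
#' @param n_negative_controls Number of negative-control probes.
#' @param background_mean,background_sd Background (non-expressed) log2
#'   intensity distribution.
#' @param module_spec List of planted modules; each element a list with
#'   `size`, `loading`, and `level` (`"mouse"` or `"sample"`). Latent factors
#'   are standard normal.
#' @param batch_assignment Optional named character vector sample_id -> batch;
#'   default splits the cages into two blocks.
#' @param batch_effect_sd SD of the additive per-gene per-batch shift.
#' @param seed Integer seed; all draws flow from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 5000, n_cages = 6, mice_per_cage = 2,
                              reps_per_mouse = 2,
                              sigma2_cage = 0, sigma2_mouse = 0.05,
                              sigma2_within = 0.05,
                              gene_mean_range = c(8, 14),
                              frac_expressed = 0.5,
                              n_negative_controls = 500,
                              background_mean = 5, background_sd = 0.3,
                              module_spec = list(),
                              batch_assignment = NULL,
                              batch_effect_sd = 0,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cages = as.integer(n_cages),
              mice_per_cage = as.integer(mice_per_cage),
              reps_per_mouse = as.integer(reps_per_mouse),
              sigma2_cage = sigma2_cage, sigma2_mouse = sigma2_mouse,
              sigma2_within = sigma2_within,
              gene_mean_range = gene_mean_range,
              frac_expressed = frac_expressed,
              n_negative_controls = as.integer(n_negative_controls),
              background_mean = background_mean,
              background_sd = background_sd,
              module_spec = module_spec,
              batch_assignment = batch_assignment,
              batch_effect_sd = batch_effect_sd,
              seed = as.integer(seed))
  for (nm in c("sigma2_cage", "sigma2_mouse", "sigma2_within"))
    if (any(cfg[[nm]] < 0)) stop(nm, " must be non-negative")
  if (cfg$reps_per_mouse < 2L)
    stop("reps_per_mouse must be >= 2 (within-mouse component unidentifiable)")
  if (cfg$frac_expressed < 0 || cfg$frac_expressed > 1)
    stop("frac_expressed must be in [0, 1]")
  if (length(cfg$gene_mean_range) != 2L ||
      diff(cfg$gene_mean_range) < 0)
    stop("gene_mean_range must be an increasing interval")
  if (cfg$batch_effect_sd < 0) stop("batch_effect_sd must be non-negative")
  n_expr <- round(cfg$n_genes * cfg$frac_expressed)
  msizes <- vapply(cfg$module_spec, function(m) as.integer(m$size), integer(1))
  if (sum(msizes) > n_expr)
    stop("module sizes (", sum(msizes), ") exceed expressed gene count (",
         n_expr, ")")
  for (m in cfg$module_spec) {
    if (!m$level %in% c("mouse", "sample"))
      stop("module latent level must be 'mouse' or 'sample'")
    if (is.null(m$loading)) stop("module entries need a 'loading'")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a replicated-design expression study with known truth
#'
#' Runs the nested random-effects model forward: per expressed gene g and
#' sample (cage j, mouse i, replicate k),
#' y = mu_g + c_jg + b_ig + w_ikg, with module structure added via shared
#' standard-normal latent factors (per mouse or per sample) entering member
#' genes scaled by their loading. Negative-control probes and non-expressed
#' genes are background draws; per-batch gene-wise shifts are added last.
#'
#' @param config A [simulation_config()].
#' @return A `SimulatedStudy`: list with `study` (an [expression_study()]),
#'   `truth` (one row per probe: true components, module label, expressed
#'   flag) and the `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_mice <- config$n_cages * config$mice_per_cage
  k <- config$reps_per_mouse
  n_samples <- n_mice * k
  G <- config$n_genes

  mouse_of_sample <- rep(seq_len(n_mice), each = k)
  cage_of_mouse <- rep(seq_len(config$n_cages), each = config$mice_per_cage)
  cage_of_sample <- cage_of_mouse[mouse_of_sample]
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    mouse = sprintf("M%02d", mouse_of_sample),
    cage = sprintf("C%d", cage_of_sample),
    replicate = rep(seq_len(k), times = n_mice),
    tissue = "T1",
    stringsAsFactors = FALSE)
  if (is.null(config$batch_assignment)) {
    samples$batch <- ifelse(cage_of_sample <= ceiling(config$n_cages / 2),
                            "B1", "B2")
  } else {
    samples$batch <- unname(config$batch_assignment[samples$sample_id])
    if (any(is.na(samples$batch)))
      stop("batch_assignment missing some sample ids")
  }

  n_expr <- round(G * config$frac_expressed)
  s2c <- rep_len(config$sigma2_cage, G)
  s2m <- rep_len(config$sigma2_mouse, G)
  s2w <- rep_len(config$sigma2_within, G)

  # background probes: a per-probe baseline (probe affinity, sd =
  # background_sd) plus smaller within-probe noise, mirroring how array
  # background is dominated by probe-to-probe differences
  bg_draw <- function(n_rows) {
    baseline <- stats::rnorm(n_rows, config$background_mean,
                             config$background_sd)
    baseline + matrix(stats::rnorm(n_rows * n_samples, 0,
                                   config$background_sd / 4),
                      n_rows, n_samples)
  }
  Y <- bg_draw(G)
  if (n_expr > 0L) {
    ie <- seq_len(n_expr)
    mu <- stats::runif(n_expr, config$gene_mean_range[1L],
                       config$gene_mean_range[2L])
    cage_eff <- matrix(stats::rnorm(n_expr * config$n_cages, 0,
                                    sqrt(s2c[ie])),
                       n_expr, config$n_cages)
    mouse_eff <- matrix(stats::rnorm(n_expr * n_mice, 0, sqrt(s2m[ie])),
                        n_expr, n_mice)
    within <- matrix(stats::rnorm(n_expr * n_samples, 0, sqrt(s2w[ie])),
                     n_expr, n_samples)
    Y[ie, ] <- mu + cage_eff[, cage_of_sample, drop = FALSE] +
      mouse_eff[, mouse_of_sample, drop = FALSE] + within
  }

  module <- rep(NA_character_, G)
  loading <- rep(0, G)
  level <- rep(NA_character_, G)
  start <- 1L
  for (m_i in seq_along(config$module_spec)) {
    m <- config$module_spec[[m_i]]
    idx <- seq.int(start, start + m$size - 1L)
    start <- start + as.integer(m$size)
    lab <- if (!is.null(m$name)) m$name else sprintf("M%d", m_i)
    module[idx] <- lab
    loading[idx] <- m$loading
    level[idx] <- m$level
    z <- if (m$level == "mouse") stats::rnorm(n_mice)[mouse_of_sample]
         else stats::rnorm(n_samples)
    Y[idx, ] <- Y[idx, , drop = FALSE] +
      m$loading * matrix(z, length(idx), n_samples, byrow = TRUE)
  }

  if (config$batch_effect_sd > 0) {
    for (b in unique(samples$batch)) {
      shift <- stats::rnorm(G, 0, config$batch_effect_sd)
      Y[, samples$batch == b] <- Y[, samples$batch == b, drop = FALSE] + shift
    }
  }

  if (config$n_negative_controls > 0L) {
    NC <- bg_draw(config$n_negative_controls)
    if (config$batch_effect_sd > 0) {
      for (b in unique(samples$batch)) {
        shift <- stats::rnorm(config$n_negative_controls, 0,
                              config$batch_effect_sd)
        NC[, samples$batch == b] <- NC[, samples$batch == b, drop = FALSE] + shift
      }
    }
    Y <- rbind(Y, NC)
  }

  probe_id <- c(sprintf("P%05d", seq_len(G)),
                if (config$n_negative_controls > 0L)
                  sprintf("NC%04d", seq_len(config$n_negative_controls)))
  probes <- data.frame(
    probe_id = probe_id,
    gene_symbol = c(sprintf("GENE%d", seq_len(G)),
                    rep("", config$n_negative_controls)),
    is_negative_control = c(rep(FALSE, G),
                            rep(TRUE, config$n_negative_controls)),
    stringsAsFactors = FALSE)
  rownames(Y) <- probe_id
  colnames(Y) <- samples$sample_id

  expressed <- c(seq_len(G) <= n_expr, rep(FALSE, config$n_negative_controls))
  pad <- function(x, fill) c(x, rep(fill, config$n_negative_controls))
  truth <- data.frame(
    probe_id = probe_id,
    sigma2_cage = pad(ifelse(seq_len(G) <= n_expr, s2c, 0), 0),
    sigma2_mouse = pad(ifelse(seq_len(G) <= n_expr, s2m, 0), 0),
    sigma2_within = pad(ifelse(seq_len(G) <= n_expr, s2w, 0), 0),
    module = pad(module, NA_character_),
    loading = pad(loading, 0),
    latent_level = pad(level, NA_character_),
    expressed = expressed,
    stringsAsFactors = FALSE)

  structure(list(study = expression_study(Y, samples, probes),
                 truth = truth, config = config),
            class = "SimulatedStudy")
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat("SimulatedStudy (seed", x$config$seed, ")\n")
  print(x$study)
  nm <- sum(!is.na(x$truth$module))
  cat("  expressed:", sum(x$truth$expressed), " planted module genes:", nm, "\n")
  invisible(x)
}

#' Summarize the ground truth of a simulated study
#'
#' Per gene, the true between-mouse and within-mouse variance (design
#' components plus loading^2 times the unit latent variance, attributed to
#' the level the latent factor acts on), true total variance and true
#' intraclass correlation; plus a per-module table with the expected
#' intraclass correlation and expected pairwise member correlation.
#'
#' @param sim A `SimulatedStudy`.
#' @return List with data frames `genes` and `modules`.
#' @export
ground_truth_summary <- function(sim) {
  stopifnot(inherits(sim, "SimulatedStudy"))
  tr <- sim$truth
  lat_mouse <- !is.na(tr$latent_level) & tr$latent_level == "mouse"
  lat_sample <- !is.na(tr$latent_level) & tr$latent_level == "sample"
  between <- tr$sigma2_cage + tr$sigma2_mouse + tr$loading^2 * lat_mouse
  within <- tr$sigma2_within + tr$loading^2 * lat_sample
  total <- between + within
  icc <- ifelse(total > 0, between / total, NA_real_)
  genes <- data.frame(probe_id = tr$probe_id,
                      true_between = between, true_within = within,
                      true_total = total, true_icc = icc,
                      module = tr$module, stringsAsFactors = FALSE)
  mods <- unique(stats::na.omit(tr$module))
  modules <- do.call(rbind, lapply(mods, function(m) {
    i <- which(!is.na(tr$module) & tr$module == m)
    data.frame(module = m, size = length(i),
               latent_level = tr$latent_level[i[1L]],
               expected_icc = mean(icc[i]),
               expected_pairwise_cor = mean(tr$loading[i]^2 / total[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(modules))
    modules <- data.frame(module = character(), size = integer(),
                          latent_level = character(),
                          expected_icc = numeric(),
                          expected_pairwise_cor = numeric())
  list(genes = genes, modules = modules)
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a simulated study to a fixture directory
#'
#' Produces `matrix.tsv` (probe_id + one column per sample), `samples.tsv`,
#' `probes.tsv`, `truth.tsv` and `config.yaml`. Numeric values are written
#' with 17 significant digits so the round trip through [read_fixture()] is
#' exact.
#'
#' @param sim A `SimulatedStudy`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(sim, path) {
  stopifnot(inherits(sim, "SimulatedStudy"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  v <- sim$study$values
  mat <- data.frame(probe_id = rownames(v),
                    matrix(.fmt_num(v), nrow(v), ncol(v)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(mat)[-1L] <- colnames(v)
  utils::write.table(mat, file.path(path, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$study$samples, file.path(path, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- sim$study$probes
  pr$is_negative_control <- as.integer(pr$is_negative_control)
  utils::write.table(pr, file.path(path, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  for (nm in c("sigma2_cage", "sigma2_mouse", "sigma2_within", "loading"))
    tr[[nm]] <- .fmt_num(tr[[nm]])
  utils::write.table(tr, file.path(path, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  cfg <- unclass(sim$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  invisible(path)
}

#' Read a simulated-study fixture
#'
#' @param path Directory written by [write_fixture()].
#' @return A `SimulatedStudy` (config re-attached when `config.yaml` is
#'   present).
#' @export
read_fixture <- function(path) {
  fp <- function(f) file.path(path, f)
  for (f in c("matrix.tsv", "samples.tsv", "probes.tsv", "truth.tsv"))
    if (!file.exists(fp(f))) stop("fixture file missing: ", f)
  study <- read_study(fp("matrix.tsv"), fp("samples.tsv"), fp("probes.tsv"))
  truth <- utils::read.delim(fp("truth.tsv"), stringsAsFactors = FALSE)
  need <- c("probe_id", "sigma2_cage", "sigma2_mouse", "sigma2_within",
            "module", "loading", "latent_level", "expressed")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth.tsv missing column(s): ",
                         paste(miss, collapse = ", "))
  truth$module <- as.character(truth$module)
  truth$latent_level <- as.character(truth$latent_level)
  cfg <- NULL
  if (file.exists(fp("config.yaml"))) {
    raw <- yaml::read_yaml(fp("config.yaml"))
    ms <- raw$module_spec
    raw$module_spec <- if (is.null(ms)) list() else ms
    cfg <- do.call(simulation_config, raw)
  }
  structure(list(study = study, truth = truth, config = cfg),
            class = "SimulatedStudy")
}
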