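#' Pipeline configuration
#'
#' Collects every stage's parameters with the field's standard defaults:
#' quantile normalization and per-gene batch correction on, the mouse-mean
#' detection rule, 2500 variable genes, alpha grid 0.05/0.01/1e-4,
#' fold-change thresholds 1.5/2/3, modules of more than 25 members with
#' eigengene merge at 0.8, and the t9 Fisher reference.
#'
#' @param input Either a directory written by [write_fixture()], a list with
#'   `matrix`, `samples`, `probes` paths, or an `ExpressionStudy` /
#'   `SimulatedStudy` object.
#' @param simulation Optional [simulation_config()] used when `input` is
#'   `NULL`.
#' @param out_dir Output directory for the report files.
#' @param quantile_normalize,batch_correct Preprocessing switches.
#' @param detection_rule Passed to [detect_expressed()].
#' @param n_variable Number of variable genes (default 2500).
#' @param alpha Significance grid for the excess-variance counts.
#' @param fc_thresholds Maximal-fold-change thresholds (strictly applied).
#' @param n_perm,seed Permutation rounds and top-level seed.
#' @param statistic,pooling Passed to [permutation_pvalues()].
#' @param min_size,merge_threshold,deep_split Module-detection parameters.
#' @param fisher_reference Reference for [fisher_critical()].
#' @param gmt Optional named character vector of GMT paths (names become
#'   the collection source tags).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            out_dir = tempfile("nestvar_run_"),
                            quantile_normalize = TRUE, batch_correct = TRUE,
                            detection_rule = "mouse-mean",
                            n_variable = 2500,
                            alpha = c(0.05, 0.01, 1e-4),
                            fc_thresholds = c(1.5, 2.0, 3.0),
                            n_perm = 1000, seed = 1L,
                            statistic = "shrunken_f", pooling = "pooled",
                            min_size = 25, merge_threshold = 0.8,
                            deep_split = 2,
                            fisher_reference = "t9",
                            gmt = NULL) {
  if (is.null(input) && is.null(simulation))
    stop("provide 'input' or a 'simulation' config")
  if (any(diff(fc_thresholds) <= 0) || any(fc_thresholds <= 0))
    stop("fc_thresholds must be positive and increasing")
  structure(list(input = input, simulation = simulation, out_dir = out_dir,
                 quantile_normalize = quantile_normalize,
                 batch_correct = batch_correct,
                 detection_rule = detection_rule, n_variable = n_variable,
                 alpha = alpha, fc_thresholds = fc_thresholds,
                 n_perm = n_perm, seed = as.integer(seed),
                 statistic = statistic, pooling = pooling,
                 min_size = min_size, merge_threshold = merge_threshold,
                 deep_split = deep_split,
                 fisher_reference = fisher_reference, gmt = gmt),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/simulate, quantile normalization, batch correction,
#' expression detection, total variance and variable genes, variance
#' decomposition with shrunken-F permutation p-values and multiple-testing
#' adjustments, coexpression network and modules, eigengene profile
#' correlations, gene-set enrichment (when GMT collections are supplied),
#' and the two summary tables. All randomness flows from `config$seed`;
#' identical config gives byte-identical output files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("nestvar ", as.character(utils::packageVersion("nestvar")),
           " | R ", getRversion()),
    paste0("seed: ", config$seed),
    paste0("flags: quantile_normalize=", config$quantile_normalize,
           " batch_correct=", config$batch_correct,
           " detection_rule=", config$detection_rule,
           " statistic=", config$statistic,
           " pooling=", config$pooling,
           " n_variable=", config$n_variable,
           " n_perm=", config$n_perm,
           " min_size=", config$min_size,
           " merge_threshold=", config$merge_threshold,
           " fisher_reference=", config$fisher_reference))
  logit <- function(...) log_lines <<- c(log_lines, paste0(...))
  set.seed(config$seed)

  study <- .stage("ingest", {
    inp <- config$input
    if (is.null(inp)) simulate_study(config$simulation)$study
    else if (inherits(inp, "SimulatedStudy")) inp$study
    else if (inherits(inp, "ExpressionStudy")) inp
    else if (is.character(inp) && length(inp) == 1L) read_fixture(inp)$study
    else if (is.list(inp)) read_study(inp$matrix, inp$samples, inp$probes)
    else stop("unrecognized input")
  })
  logit("ingested ", study$G, " probes x ", ncol(study$values), " samples")

  if (config$quantile_normalize)
    study <- .stage("quantile_normalize", quantile_normalize(study))
  if (config$batch_correct)
    study <- .stage("batch_correct", correct_batch(study))

  detection <- .stage("detect_expressed",
                      detect_expressed(study, rule = config$detection_rule))
  n_expressed <- sum(detection$expressed, na.rm = TRUE)
  logit("expressed: ", n_expressed)

  fc <- .stage("max_fold_change", max_fold_change(study))

  evt <- .stage("excess_variance", {
    keep <- !study$probes$is_negative_control &
      !is.na(detection$expressed) & detection$expressed
    s2 <- apply(study$values[keep, , drop = FALSE], 1L, stats::var)
    scale <- pooled_scale(s2, nu = ncol(study$values) - 1L)
    withCallingHandlers(
      excess_variance_test(study, scale, n_variable = config$n_variable,
                           alpha = config$alpha,
                           expressed = detection$expressed),
      message = function(m) {
        logit("warning: ", trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  })
  logit("variable genes: ", length(evt$variable_genes))

  decomp <- .stage("decompose_variance", decompose_variance(study))
  fshr <- .stage("shrunken_f", shrunken_f(decomp))
  p_perm <- .stage("permutation_pvalues",
                   permutation_pvalues(study, statistic = config$statistic,
                                       n_perm = config$n_perm,
                                       pooling = config$pooling))
  ctrl <- study$probes$is_negative_control
  p_test <- ifelse(ctrl, NA_real_, p_perm)
  sidak <- .stage("adjust_sidak", adjust_pvalues(p_test, "sidak_stepdown"))
  bh <- .stage("adjust_bh", adjust_pvalues(p_test, "bh"))
  pi0 <- .stage("estimate_pi0", estimate_pi0(p_test[!ctrl]))
  logit("pi0: ", format(pi0))

  varcomp <- data.frame(
    decomp,
    chi2_stat = evt$table$chi2_stat, chi2_p = evt$table$chi2_p,
    f_shrunk = fshr$f_shrunk,
    p_perm = unname(p_perm),
    p_sidak = sidak$adjusted, q_bh = bh$adjusted,
    expressed = unname(detection$expressed[decomp$probe_id]),
    is_variable = decomp$probe_id %in% evt$variable_genes,
    max_fc = fc$max_fc,
    stringsAsFactors = FALSE)
  .write_tsv(varcomp, file.path(config$out_dir, "varcomp.tsv"))

  network <- .stage("network", build_network(study, genes = evt$variable_genes))
  modules <- .stage("modules",
                    detect_modules(network, study, min_size = config$min_size,
                                   merge_threshold = config$merge_threshold,
                                   deep_split = config$deep_split))
  logit("modules: ", length(modules$modules))

  mod_rows <- do.call(rbind, lapply(names(modules$modules), function(m) {
    mod <- modules$modules[[m]]
    data.frame(gene = mod$genes, module = m,
               cor_eigengene = as.vector(stats::cor(
                 t(study$values[mod$genes, , drop = FALSE]),
                 mod$eigengene)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mod_rows))
    mod_rows <- data.frame(gene = character(), module = character(),
                           cor_eigengene = numeric())
  .write_tsv(mod_rows, file.path(config$out_dir, "modules.tsv"))

  eigs <- do.call(rbind, lapply(names(modules$modules), function(m)
    data.frame(module = m, t(modules$modules[[m]]$eigengene),
               check.names = FALSE, stringsAsFactors = FALSE)))
  if (is.null(eigs)) eigs <- data.frame(module = character())
  .write_tsv(eigs, file.path(config$out_dir, "eigengenes.tsv"))

  profile_cors <- .stage("profile_correlations", {
    mods <- names(modules$modules)
    d <- .design_info(study)
    crit_b <- fisher_critical(max(d$n_mice - 1L, 4L),
                              reference = config$fisher_reference)
    crit_w <- fisher_critical(d$n_mice, reference = config$fisher_reference)
    pairs <- if (length(mods) >= 2L) utils::combn(mods, 2L) else
      matrix(character(), 2L, 0L)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      pa <- split_profiles(modules$modules[[a]]$eigengene, study$samples)
      pb <- split_profiles(modules$modules[[b]]$eigengene, study$samples)
      r <- suppressMessages(profile_correlations(pa, pb))
      data.frame(module_a = a, module_b = b,
                 r_b = r[["r_b"]], r_w = r[["r_w"]],
                 sig_b = !is.na(r[["r_b"]]) && abs(r[["r_b"]]) > crit_b,
                 sig_w = !is.na(r[["r_w"]]) && abs(r[["r_w"]]) > crit_w,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(module_a = character(), module_b = character(),
                        r_b = numeric(), r_w = numeric(),
                        sig_b = logical(), sig_w = logical())
    attr(out, "critical") <- c(r_b = crit_b, r_w = crit_w)
    out
  })
  .write_tsv(profile_cors, file.path(config$out_dir,
                                     "eigengene_correlations.tsv"))

  enrich <- NULL
  if (!is.null(config$gmt)) {
    enrich <- .stage("enrichment", {
      collections <- lapply(seq_along(config$gmt), function(i)
        read_gmt(config$gmt[[i]],
                 source = if (!is.null(names(config$gmt)))
                   names(config$gmt)[i] else paste0("collection", i)))
      .enrich_modules(study, modules, evt$variable_genes, collections)
    })
    .write_tsv(enrich, file.path(config$out_dir, "enrichment.tsv"))
  }

  t1 <- table1_summary(study, detection, evt, sidak, bh, pi0, fc,
                       config$fc_thresholds)
  .write_tsv(t1, file.path(config$out_dir, "summary_table1.tsv"))
  t2 <- table2_summary(modules, enrich, decomp)
  .write_tsv(t2, file.path(config$out_dir, "summary_table2.tsv"))

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(study = study, detection = detection, fold_changes = fc,
                 excess_variance = evt, decomposition = decomp,
                 shrunken_f = fshr, p_perm = p_perm, sidak = sidak, bh = bh,
                 pi0 = pi0, varcomp = varcomp, network = network,
                 modules = modules, profile_correlations = profile_cors,
                 enrichment = enrich, table1 = t1, table2 = t2,
                 out_dir = config$out_dir))
}

# enrichment of every module and its signed subsets against each collection;
# universe = variable genes present in the collection, one probe per gene
# (largest total variance), symbols compared upper-case.
.enrich_modules <- function(study, modules, variable_genes, collections) {
  pr <- study$probes
  sym <- stats::setNames(toupper(pr$gene_symbol), pr$probe_id)
  s2 <- apply(study$values, 1L, stats::var)
  vg <- variable_genes[nzchar(sym[variable_genes])]
  # one probe per gene: keep the largest-variance probe
  ord <- vg[order(-s2[vg], vg)]
  keep <- ord[!duplicated(sym[ord])]
  probe_of_sym <- stats::setNames(keep, sym[keep])
  rows <- list()
  for (col in collections) {
    db_genes <- toupper(unique(unlist(col$sets)))
    uni_syms <- intersect(names(probe_of_sym), db_genes)
    if (length(uni_syms) == 0L) next
    for (m in names(modules$modules)) {
      mod <- modules$modules[[m]]
      subsets <- list(all = mod$genes, positive = mod$positive_set,
                      negative = mod$negative_set)
      for (sub in names(subsets)) {
        g_syms <- intersect(unname(sym[intersect(subsets[[sub]], keep)]),
                            uni_syms)
        if (length(g_syms) == 0L) next
        er <- hypergeom_enrich(g_syms, uni_syms, col)
        if (nrow(er) == 0L) next
        rows[[length(rows) + 1L]] <-
          data.frame(module = m, subset = sub, database = col$source, er,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), subset = character(),
               database = character(), set = character(),
               in_module = integer(), in_category = integer(),
               overlap = integer(), percent = numeric(), p_hyper = numeric())
  rownames(out) <- NULL
  out
}

# round half away from zero to integer percent
.pct <- function(count, total) floor(100 * count / total + 0.5)

#' Study-level variability summary
#'
#' Counts and percentages (of the non-control probe universe) of expressed
#' genes, excess-variance genes at each alpha, genes significant after
#' family-wise (Sidak step-down, p < 0.05) and FDR (BH, q < 0.10)
#' correction, the estimated differential fraction 1 - pi0, and maximal
#' fold-change exceedances (strict).
#'
#' @param study,detection,evt,sidak,bh,pi0,fc Pipeline intermediates (see
#'   [run_pipeline()]).
#' @param fc_thresholds Fold-change thresholds.
#' @return Data frame with `row`, `label`, `count`, `percent`, `formatted`.
#' @export
table1_summary <- function(study, detection, evt, sidak, bh, pi0, fc,
                           fc_thresholds = c(1.5, 2.0, 3.0)) {
  ctrl <- study$probes$is_negative_control
  total <- sum(!ctrl)
  expressed <- detection$expressed[study$probes$probe_id[!ctrl]]
  keepnames <- study$probes$probe_id[!ctrl]
  rows <- list(list("A", "expressed_genes", sum(expressed, na.rm = TRUE)))
  for (i in seq_along(evt$alpha))
    rows[[length(rows) + 1L]] <-
      list("B", paste0("variable_alpha_",
                       format(evt$alpha[i], scientific = FALSE, trim = TRUE)),
           unname(evt$counts[i]))
  adj_s <- sidak$adjusted[!ctrl]
  adj_b <- bh$adjusted[!ctrl]
  rows[[length(rows) + 1L]] <- list("C", "fwer_p_lt_0.05",
                                    sum(adj_s < 0.05, na.rm = TRUE))
  rows[[length(rows) + 1L]] <- list("C", "fdr_p_lt_0.10",
                                    sum(adj_b < 0.10, na.rm = TRUE))
  fcv <- fc$max_fc[!ctrl]
  for (th in fc_thresholds)
    rows[[length(rows) + 1L]] <- list("D", paste0("maxfc_gt_", th),
                                      sum(fcv > th))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(row = r[[1L]], label = r[[2L]], count = r[[3L]],
               percent = .pct(r[[3L]], total),
               formatted = sprintf("%d(%d%%)", r[[3L]], .pct(r[[3L]], total)),
               stringsAsFactors = FALSE)))
  out <- rbind(out[out$row %in% c("A", "B"), ],
               data.frame(row = "C", label = "one_minus_pi0",
                          count = NA_integer_,
                          percent = .pct(1 - pi0, 1),
                          formatted = sprintf("%d%%", .pct(1 - pi0, 1)),
                          stringsAsFactors = FALSE),
               out[out$row == "C", ],
               out[out$row == "D", ])
  rownames(out) <- NULL
  out
}

#' Module highlights table
#'
#' One row per module: its top-scoring enrichment category (smallest
#' hypergeometric p with overlap >= 1, whole-module subset) with the
#' standard In Module / In Category / Overlap / percent / p-value columns,
#' and the module's median intraclass correlation.
#'
#' @param modules A `ModuleSet`.
#' @param enrichment The pipeline's enrichment table (may be `NULL`).
#' @param decomp A [decompose_variance()] result.
#' @return Data frame, one row per module.
#' @export
table2_summary <- function(modules, enrichment, decomp) {
  rows <- lapply(names(modules$modules), function(m) {
    mod <- modules$modules[[m]]
    c_med <- module_icc(decomp, mod$genes)
    base <- data.frame(module = m, database = "", category = "no enrichment",
                       in_module = mod$size, in_category = NA_integer_,
                       overlap = NA_integer_, percent = NA_real_,
                       p_value = NA_real_, c = c_med, varexp = mod$varexp,
                       stringsAsFactors = FALSE)
    if (is.null(enrichment)) return(base)
    er <- enrichment[enrichment$module == m & enrichment$subset == "all" &
                       enrichment$overlap >= 1, , drop = FALSE]
    if (nrow(er) == 0L) return(base)
    top <- er[order(er$p_hyper, er$set), , drop = FALSE][1L, ]
    base$database <- top$database
    base$category <- top$set
    base$in_category <- top$in_category
    base$overlap <- top$overlap
    base$percent <- top$percent
    base$p_value <- top$p_hyper
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(), database = character(),
                      category = character(), in_module = integer(),
                      in_category = integer(), overlap = integer(),
                      percent = numeric(), p_value = numeric(), c = numeric(),
                      varexp = numeric())
  rownames(out) <- NULL
  out
}
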