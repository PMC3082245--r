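#' Pooled James-Stein variance scale
#'
#' The common variance under the null that all genes share one variance is
#' estimated as the bias-corrected geometric mean of the per-gene sample
#' variances: sigma2_pool = exp(mean(log s2_g) - (digamma(nu/2) - log(nu/2))).
#' The correction removes the mean of log(s2/sigma2) under a chi-squared
#' distribution with nu degrees of freedom.
#'
#' @param s2_total Per-gene total sample variances (all must be > 0;
#'   zero-variance genes are dropped with a warning).
#' @param nu Degrees of freedom, total samples minus 1 (23 for the
#'   12-mouse, duplicate-sample design).
#' @return A `PooledScale`: list with `sigma2_pool`, `nu`, `bias_correction`.
#' @export
pooled_scale <- function(s2_total, nu) {
  if (length(s2_total) == 0L) stop("empty variance vector")
  if (nu < 1) stop("nu must be >= 1")
  bad <- !is.finite(s2_total) | s2_total <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero/non-finite variance excluded")
    s2_total <- s2_total[!bad]
    if (length(s2_total) == 0L) stop("no positive variances left")
  }
  bias <- digamma(nu / 2) - log(nu / 2)
  structure(list(sigma2_pool = exp(mean(log(s2_total)) - bias),
                 nu = nu, bias_correction = bias),
            class = "PooledScale")
}

#' Excess-variance chi-squared test and variable-gene set
#'
#' Scales each gene's total variance by the pooled estimate and refers
#' nu * s2 / sigma2_pool to the analytic upper tail of a chi-squared
#' distribution with nu degrees of freedom. The `n_variable` genes with the
#' largest total variance (among expressed genes when a detection call is
#' supplied) are designated variable genes for the network analysis.
#'
#' @param study An [expression_study()] object (balanced).
#' @param scale A [pooled_scale()] whose `nu` matches `ncol(values) - 1`.
#' @param n_variable Number of variable genes to designate (default 2500,
#'   capped at the candidate count).
#' @param alpha Significance levels at which exceedance counts are reported.
#' @param expressed Optional logical vector (named by probe id) restricting
#'   ranking/counting to expressed genes; negative controls are always
#'   excluded.
#' @return List with `table` (probe_id, s2_total, chi2_stat, chi2_p),
#'   `counts` (genes with p below each alpha), `variable_genes`, `n_variable`.
#' @export
excess_variance_test <- function(study, scale, n_variable = 2500,
                                 alpha = c(0.05, 0.01, 1e-4),
                                 expressed = NULL) {
  stopifnot(inherits(scale, "PooledScale"))
  nu <- ncol(study$values) - 1L
  if (scale$nu != nu)
    stop("nu mismatch: scale has ", scale$nu, ", study implies ", nu)
  s2 <- apply(study$values, 1L, stats::var)
  stat <- nu * s2 / scale$sigma2_pool
  p <- stats::pchisq(stat, df = nu, lower.tail = FALSE)
  tab <- data.frame(probe_id = study$probes$probe_id, s2_total = s2,
                    chi2_stat = stat, chi2_p = p, stringsAsFactors = FALSE)
  keep <- !study$probes$is_negative_control
  if (!is.null(expressed))
    keep <- keep & !is.na(expressed[tab$probe_id]) & expressed[tab$probe_id]
  counts <- vapply(alpha, function(a) sum(p[keep] < a), integer(1))
  names(counts) <- paste0("alpha_", format(alpha, scientific = FALSE,
                                           trim = TRUE))
  n_cand <- sum(keep)
  if (n_variable > n_cand) {
    message("n_variable clamped from ", n_variable, " to ", n_cand)
    n_variable <- n_cand
  }
  ord <- order(-s2, tab$probe_id)
  ord <- ord[keep[ord]]
  variable_genes <- tab$probe_id[ord[seq_len(n_variable)]]
  structure(list(table = tab, counts = counts,
                 variable_genes = variable_genes, n_variable = n_variable,
                 alpha = alpha),
            class = "ExcessVarianceTest")
}

#' Per-gene between-/within-mouse variance decomposition
#'
#' For the balanced one-way random-effects layout (n mice, k replicates)
#' the closed-form REML solution is used: with MSW = SSW / (n(k-1)) and
#' MSB = k * sum((mouse mean - grand mean)^2) / (n-1), the interior case
#' (MSB > MSW) gives the ANOVA estimator s2_within = MSW, s2_between =
#' (MSB - MSW)/k; when MSB <= MSW the between component is truncated to 0
#' and the within component pools both strata, (SSB + SSW)/(nk - 1).
#' icc = s2_between / (s2_between + s2_within). Unbalanced designs fall
#' back to iterative REML via lme4 with a warning.
#'
#' @param study An [expression_study()] object, >= 2 replicates per mouse.
#' @return A data frame of class `VarianceDecomposition` with columns
#'   `probe_id`, `mu`, `s2_total`, `msb`, `msw`, `s2_between`, `s2_within`,
#'   `icc`, `near_zero_between` (estimated between component < 1e-4, the
#'   reporting bin used for density plots). Design degrees of freedom are
#'   attached as attributes `df_between`, `df_within`, `n_mice`, `reps`.
#' @export
decompose_variance <- function(study) {
  d <- .design_info(study)
  v <- study$values
  if (d$balanced && d$k >= 2L) {
    res <- .anova_oneway(v, d$mouse, d$n_mice, d$k)
  } else {
    warning("unbalanced design: falling back to iterative REML (lme4)")
    res <- .reml_oneway(v, d$mouse)
  }
  out <- data.frame(probe_id = study$probes$probe_id, res,
                    stringsAsFactors = FALSE)
  out$icc <- ifelse(out$s2_between + out$s2_within > 0,
                    out$s2_between / (out$s2_between + out$s2_within), 0)
  out$near_zero_between <- out$s2_between < 1e-4
  attr(out, "df_between") <- d$n_mice - 1L
  attr(out, "df_within") <- d$n_mice * (d$k - 1L)
  attr(out, "n_mice") <- d$n_mice
  attr(out, "reps") <- d$k
  class(out) <- c("VarianceDecomposition", "data.frame")
  out
}

.anova_oneway <- function(v, mouse, n, k) {
  M <- stats::model.matrix(~ mouse - 1)
  means <- (v %*% M) / k
  grand <- rowMeans(v)
  ssb <- k * rowSums((means - grand)^2)
  ssw <- rowSums((v - means[, as.integer(mouse), drop = FALSE])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  # REML: interior solution is the ANOVA estimator; on the boundary
  # (MSB <= MSW) the between component is 0 and the within estimate pools
  # both strata. The two agree at MSB == MSW.
  data.frame(mu = grand,
             s2_total = (ssb + ssw) / (n * k - 1),
             msb = msb, msw = msw,
             s2_between = pmax(0, (msb - msw) / k),
             s2_within = ifelse(msb > msw, msw,
                                (ssb + ssw) / (n * k - 1)))
}

.reml_oneway <- function(v, mouse) {
  res <- t(apply(v, 1L, function(y) {
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | mouse), REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    c(s2_between = vc$vcov[vc$grp == "mouse"],
      s2_within = vc$vcov[vc$grp == "Residual"],
      mu = unname(lme4::fixef(fit)[1L]))
  }))
  data.frame(mu = res[, "mu"],
             s2_total = apply(v, 1L, stats::var),
             msb = NA_real_, msw = res[, "s2_within"],
             s2_between = res[, "s2_between"],
             s2_within = res[, "s2_within"])
}

#' Shrunken F statistic for between-mouse variation
#'
#' MSB divided by a James-Stein estimate of the within-mouse variance:
#' the bias-corrected log MSW is shrunk toward its across-gene mean with a
#' Lindley-type factor B = min(1, (G-3) * trigamma(d/2) / sum((z - mean
#' z)^2)), d = n(k-1), and exponentiated back with the chi-squared log bias
#' restored. With B = 0 this is exactly the
#' classic F = MSB/MSW; permutation calibration (see
#' [permutation_pvalues()]) makes the resulting p-values valid for any
#' shrinkage constant.
#'
#' @param decomp A [decompose_variance()] result (balanced design, `msb`
#'   and `msw` available).
#' @param shrink Set `FALSE` to force B = 0 (classic F).
#' @return Data frame with `probe_id`, `sigma2_tilde`, `f_shrunk`, and the
#'   shrink factor as attribute `B`.
#' @export
shrunken_f <- function(decomp, shrink = TRUE) {
  stopifnot(inherits(decomp, "VarianceDecomposition"))
  d <- attr(decomp, "df_within")
  msw <- decomp$msw
  msb <- decomp$msb
  if (any(is.na(msb))) stop("shrunken_f needs balanced mean squares")
  ok <- msw > 0
  if (!all(ok)) warning(sum(!ok), " constant gene(s): f_shrunk set NA")
  G <- sum(ok)
  z <- rep(NA_real_, length(msw))
  z[ok] <- log(msw[ok]) - (digamma(d / 2) - log(d / 2))
  m <- mean(z[ok])
  if (!shrink) {
    B <- 0
  } else if (G < 4L) {
    warning("fewer than 4 genes: no shrinkage applied (B = 0)")
    B <- 0
  } else {
    B <- min(1, (G - 3) * trigamma(d / 2) / sum((z[ok] - m)^2))
  }
  # restore the chi-squared log bias so B = 0 recovers MSW exactly
  sigma2_tilde <- exp(m + (1 - B) * (z - m) + (digamma(d / 2) - log(d / 2)))
  out <- data.frame(probe_id = decomp$probe_id,
                    sigma2_tilde = sigma2_tilde,
                    f_shrunk = ifelse(ok, msb / sigma2_tilde, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "B") <- B
  out
}

# per-gene statistic on a (residual) matrix given a mouse factor
.between_stat <- function(mat, mouse, n, k, statistic, shrink = TRUE) {
  M <- stats::model.matrix(~ mouse - 1)
  means <- (mat %*% M) / k
  grand <- rowMeans(mat)
  ssb <- k * rowSums((means - grand)^2)
  ssw <- rowSums((mat - means[, as.integer(mouse), drop = FALSE])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (statistic == "classic_f") return(msb / msw)
  d <- n * (k - 1)
  z <- log(msw) - (digamma(d / 2) - log(d / 2))
  m <- mean(z)
  G <- length(z)
  B <- if (shrink && G >= 4L)
    min(1, (G - 3) * trigamma(d / 2) / sum((z - m)^2)) else 0
  msb / exp(m + (1 - B) * (z - m) + (digamma(d / 2) - log(d / 2)))
}

#' Permutation p-values for the between-mouse statistic
#'
#' Residuals (values minus the per-gene mean) are relabelled by a single
#' random permutation of the sample positions per round, applied to every
#' gene, and the statistic is recomputed (including its shrinkage step).
#' p = (1 + number of null statistics >= observed) / (1 + number of null
#' statistics), with the null pooled across genes (default) or kept per
#' gene.
#'
#' @param study An [expression_study()] object (balanced).
#' @param statistic `"shrunken_f"` (default) or `"classic_f"`.
#' @param n_perm Number of permutation rounds (>= 1).
#' @param seed Optional seed for reproducible permutations.
#' @param pooling `"pooled"` (default) or `"per_gene"`.
#' @return Named numeric vector of p-values (`NA` for constant genes).
#' @export
permutation_pvalues <- function(study, statistic = c("shrunken_f", "classic_f"),
                                n_perm = 1000, seed = NULL,
                                pooling = c("pooled", "per_gene")) {
  statistic <- match.arg(statistic)
  pooling <- match.arg(pooling)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- .design_info(study)
  if (!d$balanced) stop("permutation test requires a balanced design")
  v <- study$values
  resid <- v - rowMeans(v)
  const <- apply(v, 1L, stats::sd) == 0
  if (any(const)) message(sum(const), " constant gene(s): p reported NA")
  use <- which(!const)
  r_use <- resid[use, , drop = FALSE]
  obs <- .between_stat(r_use, d$mouse, d$n_mice, d$k, statistic)
  null <- matrix(NA_real_, length(use), n_perm)
  for (r in seq_len(n_perm)) {
    perm <- sample.int(d$n_samples)
    null[, r] <- .between_stat(r_use[, perm, drop = FALSE],
                               d$mouse, d$n_mice, d$k, statistic)
  }
  p_use <- if (pooling == "pooled") {
    sorted <- sort(as.vector(null))
    n_tot <- length(sorted)
    n_lt <- findInterval(obs, sorted, left.open = TRUE)
    (1 + (n_tot - n_lt)) / (1 + n_tot)
  } else {
    (1 + rowSums(null >= obs)) / (1 + n_perm)
  }
  p <- rep(NA_real_, nrow(v))
  p[use] <- p_use
  names(p) <- study$probes$probe_id
  p
}

#' Multiple-testing adjustment
#'
#' `sidak_stepdown`: sort ascending, adj_(i) = 1 - (1 - p_(i))^(m - i + 1),
#' then a running maximum enforces monotonicity. `bh`: Benjamini-Hochberg
#' step-up (via [stats::p.adjust()]). `qvalue`: Storey q-values, the BH
#' quantity multiplied by the estimated null proportion pi0.
#'
#' @param p P-values in \[0, 1\].
#' @param method One of `"sidak_stepdown"`, `"bh"`, `"qvalue"`.
#' @param lambda Tuning parameter passed to [estimate_pi0()] for
#'   `method = "qvalue"`.
#' @return A `MultipleTestingResult`: list with `method`, `adjusted`
#'   (same order as `p`), `pi0` (`NA` unless `method = "qvalue"`).
#' @export
adjust_pvalues <- function(p, method = c("sidak_stepdown", "bh", "qvalue"),
                           lambda = 0.5) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  adj <- rep(NA_real_, length(p))
  pi0 <- NA_real_
  pv <- p[ok]
  if (method == "sidak_stepdown") {
    o <- order(pv)
    a <- 1 - (1 - pv[o])^(m - seq_len(m) + 1)
    a <- cummax(a)
    adj[ok][o] <- pmin(1, a)
  } else if (method == "bh") {
    adj[ok] <- stats::p.adjust(pv, method = "BH")
  } else {
    pi0 <- estimate_pi0(pv, lambda = lambda)
    adj[ok] <- pmin(1, pi0 * stats::p.adjust(pv, method = "BH"))
  }
  structure(list(method = method, adjusted = adj, pi0 = pi0),
            class = "MultipleTestingResult")
}

#' Estimate the null proportion pi0
#'
#' Default fixed-lambda estimator: pi0 = #\{p > lambda\} / (m (1 - lambda)),
#' capped at 1. The `"smoother"` method evaluates the estimator on a lambda
#' grid and extrapolates a cubic smoothing spline to the largest lambda.
#'
#' @param p P-values in \[0, 1\].
#' @param lambda Threshold for the fixed estimator (default 0.5).
#' @param method `"fixed"` (default) or `"smoother"`.
#' @return Estimated pi0 in \[0, 1\].
#' @export
estimate_pi0 <- function(p, lambda = 0.5, method = c("fixed", "smoother")) {
  method <- match.arg(method)
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (method == "fixed") {
    return(min(1, sum(p > lambda) / (length(p) * (1 - lambda))))
  }
  grid <- seq(0.05, 0.9, by = 0.05)
  pi0g <- vapply(grid, function(l) sum(p > l) / (length(p) * (1 - l)),
                 numeric(1))
  fit <- stats::smooth.spline(grid, pi0g, df = 3)
  max(0, min(1, stats::predict(fit, x = max(grid))$y))
}

#' Nested cage/mouse-within-cage variance decomposition
#'
#' Balanced nested ANOVA with C cages, M mice (M/C per cage) and k
#' replicates: mean squares for cage, mouse-within-cage and within-mouse
#' strata with degrees of freedom (C-1), (M-C), (M(k-1)); truncated
#' component estimates; analytic F tests of the cage stratum against
#' mouse-within-cage and of mouse-within-cage against within-mouse.
#'
#' @param study An [expression_study()] object with >= 2 cages, balanced.
#' @return Data frame of class `CageDecomposition` with per-gene mean
#'   squares, components `s2_cage`, `s2_mouse_in_cage`, `s2_within`, and
#'   p-values `p_cage`, `p_mouse_in_cage`.
#' @export
decompose_cage <- function(study) {
  s <- study$samples
  cage <- factor(s$cage, levels = unique(s$cage))
  mouse <- factor(s$mouse, levels = unique(s$mouse))
  C <- nlevels(cage)
  if (C < 2L) stop("decompose_cage needs >= 2 cages")
  Mn <- nlevels(mouse)
  k <- as.integer(table(mouse))
  mpc <- as.integer(table(factor(s$cage[!duplicated(s$mouse)],
                                 levels = levels(cage))))
  if (length(unique(k)) != 1L || length(unique(mpc)) != 1L)
    stop("decompose_cage requires a balanced nested design")
  k <- k[1L]; mpc <- mpc[1L]
  v <- study$values
  Mm <- stats::model.matrix(~ mouse - 1)
  Mc <- stats::model.matrix(~ cage - 1)
  mouse_means <- (v %*% Mm) / k
  cage_means <- (v %*% Mc) / (k * mpc)
  grand <- rowMeans(v)
  cage_of_mouse <- as.integer(factor(
    s$cage[!duplicated(s$mouse)][order(match(unique(s$mouse), levels(mouse)))],
    levels = levels(cage)))
  ss_cage <- k * mpc * rowSums((cage_means - grand)^2)
  ss_mouse <- k * rowSums((mouse_means -
                             cage_means[, cage_of_mouse, drop = FALSE])^2)
  ss_within <- rowSums((v - mouse_means[, as.integer(mouse), drop = FALSE])^2)
  df_c <- C - 1L; df_m <- Mn - C; df_w <- Mn * (k - 1L)
  ms_cage <- ss_cage / df_c
  ms_mouse <- ss_mouse / df_m
  ms_within <- ss_within / df_w
  out <- data.frame(
    probe_id = study$probes$probe_id,
    ms_cage = ms_cage, ms_mouse_in_cage = ms_mouse, ms_within = ms_within,
    s2_cage = pmax(0, (ms_cage - ms_mouse) / (k * mpc)),
    s2_mouse_in_cage = pmax(0, (ms_mouse - ms_within) / k),
    s2_within = ms_within,
    p_cage = stats::pf(ms_cage / ms_mouse, df_c, df_m, lower.tail = FALSE),
    p_mouse_in_cage = stats::pf(ms_mouse / ms_within, df_m, df_w,
                                lower.tail = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "df") <- c(cage = df_c, mouse_in_cage = df_m, within = df_w)
  class(out) <- c("CageDecomposition", "data.frame")
  out
}
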