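# Build a small balanced ExpressionStudy from a genes x (n_mice * k) matrix;
# columns are mouse-major (mouse 1 replicates, mouse 2 replicates, ...).
make_study <- function(values, n_mice, k = 2,
                       n_cages = max(1L, n_mice %/% 2L),
                       n_controls = 0, batch = NULL, symbols = NULL,
                       tissue = "T1") {
  values <- as.matrix(values)
  n_samples <- n_mice * k
  stopifnot(ncol(values) == n_samples)
  mouse_of_sample <- rep(seq_len(n_mice), each = k)
  cage_of_mouse <- rep(seq_len(n_cages),
                       each = ceiling(n_mice / n_cages))[seq_len(n_mice)]
  if (is.null(batch)) batch <- rep("B1", n_samples)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    mouse = sprintf("M%02d", mouse_of_sample),
    cage = sprintf("C%d", cage_of_mouse[mouse_of_sample]),
    replicate = rep(seq_len(k), times = n_mice),
    batch = batch, tissue = tissue, stringsAsFactors = FALSE)
  G <- nrow(values)
  ids <- if (!is.null(rownames(values))) rownames(values)
         else sprintf("P%05d", seq_len(G))
  if (is.null(symbols))
    symbols <- ifelse(seq_len(G) > G - n_controls, "",
                      toupper(sprintf("GENE%d", seq_len(G))))
  probes <- data.frame(
    probe_id = ids, gene_symbol = symbols,
    is_negative_control = seq_len(G) > G - n_controls,
    stringsAsFactors = FALSE)
  rownames(values) <- ids
  colnames(values) <- samples$sample_id
  expression_study(values, samples, probes)
}

# Independent REML oracle for the balanced one-way random-effects layout:
# direct grid-refined minimization of -2 * restricted log-likelihood over
# (s2_between >= 0, s2_within > 0).
reml_grid_oracle <- function(y, mouse, k) {
  mouse <- factor(mouse)
  n <- nlevels(mouse)
  means <- tapply(y, mouse, mean)[levels(mouse)]
  grand <- mean(y)
  ssb <- k * sum((means - grand)^2)
  ssw <- sum((y - means[as.character(mouse)])^2)
  neg2rl <- function(sb, sw)
    (n - 1) * log(sw + k * sb) + ssb / (sw + k * sb) +
    n * (k - 1) * log(sw) + ssw / sw
  sb_rng <- c(0, max(ssb, 1))
  sw_rng <- c(1e-10, max(ssw, 1))
  for (it in 1:40) {
    sb_g <- seq(sb_rng[1], sb_rng[2], length.out = 21)
    sw_g <- seq(sw_rng[1], sw_rng[2], length.out = 21)
    val <- outer(sb_g, sw_g, Vectorize(neg2rl))
    ij <- which(val == min(val), arr.ind = TRUE)[1, ]
    step_b <- diff(sb_rng) / 20
    step_w <- diff(sw_rng) / 20
    sb_rng <- c(max(0, sb_g[ij[1]] - step_b), sb_g[ij[1]] + step_b)
    sw_rng <- c(max(1e-12, sw_g[ij[2]] - step_w), sw_g[ij[2]] + step_w)
  }
  c(s2_between = mean(sb_rng), s2_within = mean(sw_rng))
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability P(overlap >= x) over all size-n draws from a universe of N
# genes of which the first K belong to the category.
enum_hyper_upper <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= x)
}
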