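test_that("pooled scale is the bias-corrected geometric mean", {
  sc <- pooled_scale(1, nu = 23)
  expect_equal(sc$sigma2_pool, exp(log(11.5) - digamma(11.5)),
               tolerance = 1e-12)
  expect_equal(sc$sigma2_pool, 1.045095, tolerance = 1e-5)
  # large-nu limit: bias -> 0, pooled -> geometric mean
  sc2 <- pooled_scale(c(1, 4), nu = 1e8)
  expect_equal(sc2$sigma2_pool, 2, tolerance = 1e-6)
  # one extreme outlier moves the estimate by at most outlier^(1/G)
  base <- rep(1, 10)
  with_out <- pooled_scale(c(base, 1e6), nu = 23)$sigma2_pool
  without <- pooled_scale(base, nu = 23)$sigma2_pool
  expect_lte(with_out / without, 1e6^(1 / 11) * (1 + 1e-12))
  expect_error(pooled_scale(numeric(0), 23), "empty")
  expect_warning(pooled_scale(c(1, 0), 23), "excluded")
})

test_that("excess-variance test scales by the pooled estimate and ranks variable genes", {
  set.seed(5)
  v <- matrix(rnorm(5 * 24), 5, 24)
  v <- v * c(1, 2, 3, 4, 5)  # distinct variances
  st <- make_study(v, n_mice = 12, k = 2)
  s2 <- apply(st$values, 1, var)
  sc <- pooled_scale(s2, nu = 23)
  ev <- excess_variance_test(st, sc, n_variable = 3)
  expect_equal(ev$table$chi2_stat, unname(23 * s2 / sc$sigma2_pool))
  # upper-tail chi-squared oracle
  expect_equal(ev$table$chi2_p,
               unname(pchisq(23 * s2 / sc$sigma2_pool, 23,
                             lower.tail = FALSE)))
  expect_setequal(ev$variable_genes,
                  st$probes$probe_id[order(-s2)][1:3])
  # nu mismatch
  expect_error(excess_variance_test(st, pooled_scale(s2, nu = 11)),
               "mismatch")
})

test_that("chi-squared excess-variance p-values are calibrated and uniform under the null", {
  cfg <- simulation_config(n_genes = 3000, frac_expressed = 1,
                           n_negative_controls = 0, sigma2_cage = 0,
                           sigma2_mouse = 0, sigma2_within = 1, seed = 33)
  sim <- simulate_study(cfg)
  s2 <- apply(sim$study$values, 1, var)
  ev <- excess_variance_test(sim$study, pooled_scale(s2, 23),
                             n_variable = 100)
  frac <- mean(ev$table$chi2_p < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_gt(suppressWarnings(ks.test(ev$table$chi2_p, "punif"))$p.value,
            0.01)
})

test_that("balanced decomposition matches the hand-worked ANOVA", {
  st <- make_study(rbind(c(1, 3, 5, 7, 2, 4),
                         c(0, 10, 5, 5, 4, 6)), n_mice = 3, k = 2)
  d <- decompose_variance(st)
  expect_equal(d$msw[1], 2)
  expect_equal(d$msb[1], 26 / 3)
  expect_equal(d$s2_within[1], 2)
  expect_equal(d$s2_between[1], 10 / 3)
  expect_equal(d$icc[1], 0.625)
  # equal mouse means: MSB = 0, truncation to 0, c = 0
  expect_equal(d$msb[2], 0)
  expect_equal(d$s2_between[2], 0)
  expect_equal(d$icc[2], 0)
  # icc formula: s_b = 1, s_w = 3 -> c = 0.25
  expect_equal(1 / (1 + 3), 0.25)
  # total variance column equals the plain sample variance
  expect_equal(d$s2_total, unname(apply(st$values, 1, var)))
})

test_that("closed-form estimates agree with the grid-search REML oracle", {
  set.seed(17)
  n <- 12; k <- 2
  mouse <- rep(seq_len(n), each = k)
  v <- t(replicate(10, rnorm(n, sd = sqrt(0.5))[mouse] +
                     rnorm(n * k, sd = sqrt(0.5))))
  st <- make_study(v, n_mice = n, k = k)
  d <- decompose_variance(st)
  for (g in 1:10) {
    o <- reml_grid_oracle(v[g, ], mouse, k)
    expect_equal(d$s2_between[g], unname(o["s2_between"]), tolerance = 1e-6)
    expect_equal(d$s2_within[g], unname(o["s2_within"]), tolerance = 1e-6)
  }
})

test_that("component estimators recover the generating variances", {
  cfg <- simulation_config(n_genes = 2000, frac_expressed = 1,
                           n_negative_controls = 0, sigma2_cage = 0,
                           sigma2_mouse = 0.5, sigma2_within = 0.5,
                           seed = 19)
  d <- decompose_variance(simulate_study(cfg)$study)
  expect_lt(abs(mean(d$s2_between) - 0.5), 0.05)
  expect_lt(abs(mean(d$s2_within) - 0.5), 0.05)
  expect_lt(abs(mean(d$icc) - 0.5), 0.05)
  expect_true(all(d$icc >= 0 & d$icc <= 1))
})

test_that("shrunken F reduces to the classic F without shrinkage and preserves MSB ranking under equal MSW", {
  set.seed(23)
  st <- make_study(matrix(rnorm(20 * 8), 20, 8), n_mice = 4, k = 2)
  d <- decompose_variance(st)
  f0 <- shrunken_f(d, shrink = FALSE)
  expect_equal(attr(f0, "B"), 0)
  expect_equal(f0$f_shrunk, d$msb / d$msw)
  # identical within-mouse residual pattern for every gene -> equal MSW
  base <- rep(c(-1, 1), 4)
  amp <- seq(0.5, 5, length.out = 10)
  v <- t(sapply(amp, function(a) a * rep(rnorm(4), each = 2) + base))
  st2 <- make_study(v, n_mice = 4, k = 2)
  d2 <- decompose_variance(st2)
  f2 <- shrunken_f(d2)
  expect_equal(var(f2$sigma2_tilde), 0)
  expect_equal(order(f2$f_shrunk), order(d2$msb))
  # tiny gene sets get no shrinkage, with a warning
  st3 <- make_study(matrix(rnorm(3 * 8), 3, 8), n_mice = 4, k = 2)
  expect_warning(f3 <- shrunken_f(decompose_variance(st3)), "shrinkage")
  expect_equal(attr(f3, "B"), 0)
})

test_that("permutation p-values hit the attainable minimum, reproduce under a seed, and are uniform under the null", {
  # one gene with an enormous mouse effect among null genes
  cfg <- simulation_config(n_genes = 20, frac_expressed = 1,
                           n_negative_controls = 0, sigma2_cage = 0,
                           sigma2_mouse = c(25, rep(0, 19)),
                           sigma2_within = 0.01, seed = 71)
  st <- simulate_study(cfg)$study
  p <- permutation_pvalues(st, n_perm = 99, seed = 1, pooling = "per_gene")
  expect_equal(unname(p[1]), 1 / 100)
  p2 <- permutation_pvalues(st, n_perm = 99, seed = 1, pooling = "per_gene")
  expect_identical(p, p2)

  # pooled null p-values are uniform under the global null
  cfg0 <- simulation_config(n_genes = 500, frac_expressed = 1,
                            n_negative_controls = 0, sigma2_cage = 0,
                            sigma2_mouse = 0, sigma2_within = 1, seed = 72)
  st0 <- simulate_study(cfg0)$study
  p0 <- permutation_pvalues(st0, n_perm = 200, seed = 2)
  expect_gt(suppressWarnings(ks.test(p0, "punif"))$p.value, 0.01)
  expect_error(permutation_pvalues(st0, n_perm = 0), "n_perm")
})

test_that("multiple-testing adjustments match hand-worked examples", {
  sidak <- adjust_pvalues(c(0.01, 0.5), "sidak_stepdown")
  expect_equal(sidak$adjusted, c(1 - 0.99^2, 0.5))
  bh <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh")
  expect_equal(bh$adjusted, rep(0.04, 4))
  expect_equal(adjust_pvalues(0, "sidak_stepdown")$adjusted, 0)
  expect_equal(adjust_pvalues(0, "bh")$adjusted, 0)
  # monotone nondecreasing in sorted order, NA passthrough
  set.seed(3)
  p <- c(runif(20), NA)
  a <- adjust_pvalues(p, "sidak_stepdown")$adjusted
  expect_true(all(diff(a[order(p)][1:20]) >= 0))
  expect_true(is.na(a[21]))
  q <- adjust_pvalues(p, "qvalue")
  expect_true(q$pi0 >= 0 && q$pi0 <= 1)
  expect_true(all(q$adjusted <= adjust_pvalues(p, "bh")$adjusted + 1e-12,
                  na.rm = TRUE))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("pi0 estimator counts the upper tail and caps at one", {
  expect_equal(estimate_pi0(c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0), lambda = 0.5),
               1.0)
  expect_equal(estimate_pi0(rep(1, 10)), 1)
  expect_error(estimate_pi0(numeric(0)), "empty")
  # smoother variant stays in [0, 1] and near truth on a null sample
  set.seed(9)
  expect_lt(abs(estimate_pi0(runif(2000), method = "smoother") - 1), 0.1)
})

test_that("nested cage decomposition truncates, matches the one-way split, and ranks power correctly", {
  # equal cage means but different mouse means -> s2_cage = 0
  st <- make_study(rbind(c(1, 1, -1, -1, 2, 2, -2, -2, 0.5, 0.5, -0.5, -0.5)),
                   n_mice = 6, k = 2, n_cages = 3)
  cg <- decompose_cage(st)
  expect_equal(cg$s2_cage[1], 0)
  expect_gt(cg$s2_mouse_in_cage[1], 0)

  # cage + mouse-within-cage components average to the one-way between component
  cfg <- simulation_config(n_genes = 2000, frac_expressed = 1,
                           n_negative_controls = 0, sigma2_cage = 0.3,
                           sigma2_mouse = 0.3, sigma2_within = 0.5, seed = 31)
  sim <- simulate_study(cfg)
  cg2 <- decompose_cage(sim$study)
  d2 <- decompose_variance(sim$study)
  # untruncated estimators agree on average (both unbiased for 0.6)
  nested_sum <- (cg2$ms_cage - cg2$ms_mouse_in_cage) / 4 +
    (cg2$ms_mouse_in_cage - cg2$ms_within) / 2
  oneway <- (d2$msb - d2$msw) / 2
  expect_lt(abs(mean(nested_sum) - mean(oneway)), 0.05)
  # truncation inflates both, but the sums stay close
  expect_lt(abs(mean(cg2$s2_cage + cg2$s2_mouse_in_cage) -
                  mean(d2$s2_between)), 0.1)
  expect_lt(abs(mean(cg2$s2_cage) - 0.3), 0.05)

  # pure cage signal: the cage test is more powerful than mouse-within-cage
  cfg3 <- simulation_config(n_genes = 400, frac_expressed = 1,
                            n_negative_controls = 0, sigma2_cage = 1,
                            sigma2_mouse = 0, sigma2_within = 1, seed = 37)
  cg3 <- decompose_cage(simulate_study(cfg3)$study)
  expect_gt(mean(cg3$p_cage < 0.05), mean(cg3$p_mouse_in_cage < 0.05))

  st1 <- make_study(matrix(rnorm(8), 1, 8), n_mice = 4, k = 2, n_cages = 1)
  expect_error(decompose_cage(st1), "cages")
})
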