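gmt_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GMT reader deduplicates and validates", {
  col <- read_gmt(gmt_file(c("S1\tdesc\tA\tB\tA", "S2\td2\tC")), "GO_BP")
  expect_equal(col$sets, list(S1 = c("A", "B"), S2 = "C"))
  expect_equal(unname(col$description["S1"]), "desc")
  expect_equal(col$source, "GO_BP")
  # empty file -> empty collection
  expect_length(read_gmt(gmt_file(character()))$sets, 0)
  # malformed lines
  expect_error(read_gmt(gmt_file("S1\tonly-two-fields")), "line 1")
  expect_error(read_gmt(gmt_file(c("S1\td\tA", "S1\td\tB"))), "duplicate")
  expect_error(read_gmt(file.path(tempdir(), "nope.gmt")), "not found")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  col <- structure(list(sets = list(CAT = LETTERS[1:5]),
                        description = c(CAT = ""), source = "x"),
                   class = "GeneSetCollection")
  # N = 10, K = 5, n = 2, overlap = 2 -> 10/45
  r <- hypergeom_enrich(c("A", "B"), LETTERS[1:10], col)
  expect_equal(r$p_hyper, 10 / 45)
  expect_equal(r$overlap, 2)
  expect_equal(r$percent, 40)

  # oracle equivalence on random small instances
  set.seed(79)
  for (i in 1:20) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    genes <- sample(LETTERS[1:N], n)
    colr <- structure(list(sets = list(S = LETTERS[seq_len(K)]),
                           description = c(S = ""), source = "x"),
                      class = "GeneSetCollection")
    p <- hypergeom_enrich(genes, LETTERS[1:N], colr)$p_hyper
    x <- sum(genes %in% LETTERS[seq_len(K)])
    expect_equal(p, enum_hyper_upper(N, K, n, x), tolerance = 1e-12)
  }

  # overlap 0 with an empty category gives p = 1
  col0 <- structure(list(sets = list(S = character()),
                         description = c(S = ""), source = "x"),
                    class = "GeneSetCollection")
  expect_equal(hypergeom_enrich("A", LETTERS[1:5], col0)$p_hyper, 1)
  # module = universe: the draw is exhaustive, p = 1
  expect_equal(hypergeom_enrich(LETTERS[1:10], LETTERS[1:10], col)$p_hyper, 1)
  # genes outside the universe don't change the result
  col2 <- structure(list(sets = list(CAT = c(LETTERS[1:5], "ZZZ9")),
                         description = c(CAT = ""), source = "x"),
                    class = "GeneSetCollection")
  expect_equal(hypergeom_enrich(c("A", "B"), LETTERS[1:10], col2)$p_hyper,
               10 / 45)
  # case-insensitive matching; query must lie in the universe
  expect_equal(hypergeom_enrich(c("a", "b"), LETTERS[1:10], col)$p_hyper,
               10 / 45)
  expect_error(hypergeom_enrich("Q99", LETTERS[1:10], col), "subset")
  expect_error(hypergeom_enrich("A", character(), col), "empty universe")
})

test_that("module overlap test is symmetric with Bonferroni control", {
  uni <- sprintf("G%02d", 1:20)
  r <- module_overlap(uni[1:5], uni[1:5], uni)
  expect_equal(r$overlap, 5)
  expect_equal(r$p, 1 / choose(20, 5))
  # disjoint sets covering the universe: p = 1
  r2 <- module_overlap(uni[1:5], uni[6:20], uni)
  expect_equal(r2$overlap, 0)
  expect_equal(r2$p, 1)
  # Bonferroni multiplication
  r3 <- module_overlap(uni[1:6], uni[5:10], uni, n_tests = 100)
  expect_equal(r3$p_adjusted, min(1, r3$p * 100))
  rr <- module_overlap(uni[1:8], uni[4:12], uni)
  expect_equal(module_overlap(uni[4:12], uni[1:8], uni)$p, rr$p)
  # the shared-enrichment rule
  mk <- function(ov, p) data.frame(set = "C", overlap = ov, p_hyper = p)
  expect_true(shared_enrichment(mk(5, 1e-5), mk(4, 1e-3), "C"))
  expect_false(shared_enrichment(mk(5, 1e-5), mk(3, 1e-3), "C"))
  expect_false(shared_enrichment(mk(5, 1e-5), mk(4, 0.02), "C"))
  missing <- shared_enrichment(mk(5, 1e-5), mk(4, 1e-3), "ABSENT")
  expect_false(missing)
  expect_match(attr(missing, "note"), "ABSENT")
})

test_that("cross-platform mapping picks the best-correlated candidate above the intensity floor", {
  set.seed(83)
  base <- rnorm(24, mean = 10)
  va <- rbind(base + rnorm(24, sd = 0.1))
  rownames(va) <- "ILM1"
  st_a <- make_study(va, n_mice = 12, k = 2, symbols = "ACTB")
  vb <- rbind(base + rnorm(24, sd = 0.1),    # good candidate
              rnorm(24, mean = 10),          # poor candidate
              base - 4)                      # mean intensity 6 -> excluded
  rownames(vb) <- c("AFX1", "AFX2", "AFX3")
  st_b <- make_study(vb, n_mice = 12, k = 2,
                     symbols = c("ACTB", "ACTB", "ACTB"))
  map <- map_platforms(st_a, st_b)
  expect_equal(map$pairs$probe_b, "AFX1")
  expect_gt(map$pairs$r, 0.9)

  # single low-intensity candidate -> excluded with reason
  st_b2 <- make_study(vb[3, , drop = FALSE], n_mice = 12, k = 2,
                      symbols = "ACTB")
  map2 <- map_platforms(st_a, st_b2)
  expect_equal(nrow(map2$pairs), 0)
  expect_equal(map2$exclusions$reason, "intensity filter")

  # no symbol match
  st_b3 <- make_study(vb[1, , drop = FALSE], n_mice = 12, k = 2,
                      symbols = "GAPDH")
  expect_equal(map_platforms(st_a, st_b3)$exclusions$reason,
               "no symbol match")
})

test_that("cross-platform eigengenes correlate perfectly on a copy and survive noise", {
  cfg <- simulation_config(
    n_genes = 120, frac_expressed = 1, n_negative_controls = 0,
    sigma2_mouse = 0.05, sigma2_within = 0.05,
    module_spec = list(list(size = 40, loading = 0.8, level = "mouse"),
                       list(size = 40, loading = 0.8, level = "sample")),
    seed = 89)
  sim <- simulate_study(cfg)
  st <- sim$study
  net <- build_network(st)
  mods <- detect_modules(net, st)
  expect_gte(length(mods$modules), 2)

  # platform B = exact copy (different probe ids)
  st_b <- st
  rownames(st_b$values) <- st_b$probes$probe_id <-
    paste0("B_", st$probes$probe_id)
  map <- map_platforms(st, st_b, min_intensity_b = 0)
  cp <- cross_platform_eigengenes(map, mods, st_b)
  expect_equal(cp$r, rep(1, nrow(cp)), tolerance = 1e-9)

  # platform B = copy plus independent noise at 0.2 x signal sd
  st_n <- st_b
  sds <- apply(st$values, 1, sd)
  set.seed(97)
  st_n$values <- st_n$values +
    matrix(rnorm(length(st_n$values)), nrow(st_n$values)) * (0.2 * sds)
  map_n <- map_platforms(st, st_n, min_intensity_b = 0)
  cp_n <- cross_platform_eigengenes(map_n, mods, st_n)
  expect_true(all(cp_n$r > 0.9))

  # unmapped module is skipped with a note
  mods_fake <- mods
  mods_fake$modules[[1]]$genes <- paste0("GHOST", 1:30)
  cp_f <- cross_platform_eigengenes(map, mods_fake, st_b)
  expect_match(cp_f$note[1], "skipped")
  expect_true(is.na(cp_f$r[1]))
})
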