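test_that("size factors scale exactly with elementwise sample scaling", {
  m <- matrix(c(10, 20, 30, 40, 50,
                20, 40, 60, 80, 100), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("A", "B")))
  sf <- size_factors(expr_from_matrix(m))
  expect_equal(unname(sf["B"] / sf["A"]), 2, tolerance = 1e-12)
  # identical samples give equal factors
  sf2 <- size_factors(expr_from_matrix(cbind(A = m[, 1], B = m[, 1])))
  expect_equal(unname(sf2["A"]), unname(sf2["B"]), tolerance = 1e-12)
})

test_that("size factors equal brute-force median-of-ratios on a hand matrix", {
  m <- matrix(c(100, 50, 20, 8, 400,
                200, 60, 10, 16, 420,
                150, 55, 40, 4, 410), ncol = 3,
              dimnames = list(paste0("g", 1:5), c("s1", "s2", "s3")))
  sf <- size_factors(expr_from_matrix(m))
  # oracle: per-gene geometric mean, per-sample median of count/geomean
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  oracle <- apply(m, 2, function(col) median(col / geo))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  m <- matrix(rnbinom(200, mu = 300, size = 10), ncol = 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  sf <- size_factors(expr_from_matrix(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("size factors refuse matrices with no always-positive gene", {
  m <- matrix(c(0, 5, 5, 0), ncol = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(expr_from_matrix(m)), "pseudocount")
})

test_that("fold changes behave on identities, scaling and group errors", {
  m <- matrix(rep(c(100, 300, 50), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  x <- expr_from_matrix(m)
  fc <- fold_changes(x, c("s1", "s2"), c("s3", "s4"))
  expect_true(all(fc$fold_change == 1))
  expect_true(all(abs(fc$log2_fc - log2(fc$fold_change)) < 1e-12))
  # mean_test = 3 * mean_baseline with pc = 0 gives FC 3 (no renormalization
  # on the rpkm scale)
  m2 <- cbind(a = c(g1 = 100), b = 300)
  x2 <- expr_from_matrix(m2, value_kind = "rpkm")
  expect_equal(fold_changes(x2, "b", "a", pseudocount = 0)$fold_change, 3,
               tolerance = 1e-12)
  expect_error(fold_changes(x, c("s1", "s2"), c("s2", "s3")), "overlap")
})

test_that("simulated amplitude-4 activation recovers fold change 4 noise-free", {
  cfg <- tiny_config(size_factor_sd = 0, amplitude = 4)
  model <- chain_model()
  series <- simulate_stage_series(model, cfg, n_replicates = 2, exact = TRUE)
  combined <- bind_expr(series$otic, series$reference)
  test_s <- series$otic$meta$sample_id[series$otic$meta$stage == "11-12ss"]
  base_s <- series$reference$meta$sample_id[series$reference$meta$stage == "0ss"]
  fc <- fold_changes(combined, test_s, base_s, pseudocount = 0)
  expect_equal(fc$fold_change[fc$gene == "a"], 4, tolerance = 1e-9)
})

test_that("expressed calls apply both thresholds strictly", {
  stats <- tibble::tibble(gene = c("a", "b", "c", "d"),
                          rpkm = c(4.0, 10, 10, 5),
                          count = c(500, 300, 301, 1000))
  out <- call_expressed(stats)
  expect_equal(out$expressed, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(call_expressed(tibble::tibble(gene = "a", rpkm = 5)), "count")
})

test_that("enrichment calls use strict thresholds and report direction", {
  comparison <- tibble::tibble(gene = c("a", "b", "c", "d"),
                               fold_change = c(1.5, 1.6, 0.6, 1.0))
  out <- call_enriched(comparison, expressed = rep(TRUE, 4))
  expect_equal(out$enriched, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("none", "up", "down", "none"))
  # enriched implies expressed
  out2 <- call_enriched(comparison, expressed = rep(FALSE, 4))
  expect_true(all(!out2$enriched))
  expect_error(call_enriched(comparison, rep(TRUE, 4), fc_threshold = 1),
               "fc_threshold")
})

test_that("raising the fold-change threshold never adds enriched genes", {
  set.seed(99)
  comparison <- tibble::tibble(gene = paste0("g", 1:200),
                               fold_change = exp(rnorm(200, 0, 1)))
  expressed <- runif(200) > 0.3
  prev <- call_enriched(comparison, expressed, fc_threshold = 1.2)
  for (t in c(1.5, 2, 3)) {
    cur <- call_enriched(comparison, expressed, fc_threshold = t)
    expect_true(all(cur$gene[cur$enriched] %in% prev$gene[prev$enriched]))
    prev <- cur
  }
})

test_that("blind test gives p near 1 for identical samples and needs exactly two", {
  m <- matrix(c(100, 300, 50, 100, 300, 50), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  res <- blind_variance_test(expr_from_matrix(m))
  expect_true(all(res$p_value >= 0.99))
  m3 <- cbind(m, c = m[, 1])
  expect_error(blind_variance_test(expr_from_matrix(m3)), "exactly 2")
})

test_that("blind test is conservative on simulated null pairs", {
  stages <- c("0ss", "5-6ss")
  cfg <- sim_config(seed = 21, n_genes = 2, n_tiers = 2, stages = stages,
                    dispersion = 0.05, size_factor_sd = 0.1,
                    baseline_mean = 500)
  # 2000 null genes at varied expression levels, two unreplicated samples
  act <- tibble::tibble(gene = sprintf("n%04d", 1:2000), stage = stages[1],
                        activity = rep(c(0, 0.5, 1), length.out = 2000))
  attr(act, "condition") <- "null_pair"
  x <- simulate_counts(act, cfg, assay = "rnaseq_like", n_replicates = 2,
                       stages = stages[1])
  res <- blind_variance_test(x)
  expect_lte(mean(res$p_adj < 0.1), 0.02)
})

test_that("significance filtering is a strict subset of the fold-change filter", {
  cfg <- sim_config(seed = 8)
  model <- generate_network(cfg)
  series <- simulate_stage_series(model, cfg, n_replicates = 1)
  combined <- bind_expr(series$otic, series$reference)
  test_s <- series$otic$meta$sample_id[series$otic$meta$stage == "11-12ss"]
  base_s <- series$reference$meta$sample_id[series$reference$meta$stage == "0ss"]
  fc <- fold_changes(combined, test_s, base_s)
  pair <- expr_matrix(combined$values[, c("gene", base_s, test_s)],
                      combined$meta[combined$meta$sample_id %in% c(base_s, test_s), ])
  blind <- blind_variance_test(pair)
  fc_genes <- fc$gene[fc$fold_change > 1.5]
  both <- intersect(fc_genes, blind$gene[blind$p_adj < 0.1])
  expect_true(all(both %in% fc_genes))
  expect_lte(length(both), length(fc_genes))
})
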