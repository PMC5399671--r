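# Count, qPCR and in situ read-out simulators.

test_that("dispersion 0 gives Poisson counts (variance/mean near 1)", {
  stages <- c("0ss", "5-6ss")
  cfg <- sim_config(seed = 5, n_genes = 2, n_tiers = 2, stages = stages,
                    dispersion = 0, size_factor_sd = 0, baseline_mean = 100)
  act <- tibble::tibble(gene = "g1", stage = stages[1], activity = 0)
  attr(act, "condition") <- "poisson_check"
  x <- simulate_counts(act, cfg, assay = "nanostring_like",
                       n_replicates = 10000, stages = stages[1])
  counts <- as.numeric(as.matrix(x$values[1, -1]))
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("zero activity everywhere gives baseline means exactly in expectation mode", {
  cfg <- tiny_config(size_factor_sd = 0)
  model <- generate_network(cfg)
  ref <- reference_activities(model, cfg)
  x <- simulate_counts(ref, cfg, assay = "nanostring_like", exact = TRUE)
  expect_true(all(as.matrix(x$values[, -1]) == cfg$baseline_mean))
})

test_that("count simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 9)
  model <- generate_network(cfg)
  wt <- propagate_activities(model, cfg)
  a <- simulate_counts(wt, cfg, assay = "rnaseq_like")
  b <- simulate_counts(wt, cfg, assay = "rnaseq_like")
  expect_identical(a$values, b$values)
  expect_identical(a$rpkm, b$rpkm)
  # a different condition label draws from a distinct stream
  wt2 <- wt
  attr(wt2, "condition") <- "other"
  c2 <- simulate_counts(wt2, cfg, assay = "rnaseq_like")
  expect_false(identical(c2$values[, -1], a$values[, -1]))
})

test_that("negative-binomial counts show the configured overdispersion", {
  stages <- c("0ss", "5-6ss")
  cfg <- sim_config(seed = 6, n_genes = 2, n_tiers = 2, stages = stages,
                    dispersion = 0.1, size_factor_sd = 0, baseline_mean = 500)
  act <- tibble::tibble(gene = "g1", stage = stages[1], activity = 0)
  attr(act, "condition") <- "nb_check"
  x <- simulate_counts(act, cfg, assay = "nanostring_like",
                       n_replicates = 10000, stages = stages[1])
  counts <- as.numeric(as.matrix(x$values[1, -1]))
  m <- mean(counts)
  expect_equal(var(counts), m + 0.1 * m^2, tolerance = 0.1)
})

test_that("Ct values are log2-linked to abundance", {
  stages <- c("0ss", "5-6ss")
  cfg <- sim_config(seed = 1, n_genes = 2, n_tiers = 2, stages = stages,
                    ct_noise_sd = 0, amplitude = 2)
  # activity 1 vs activity 0: abundance halves, Ct rises by exactly 1 cycle
  act_hi <- tibble::tibble(gene = "g1", stage = stages[2], activity = 1)
  act_lo <- tibble::tibble(gene = "g1", stage = stages[2], activity = 0)
  ct <- simulate_qpcr(list(control = act_hi, knockdown = act_lo), cfg,
                      genes = "g1", stage = stages[2])
  hi <- unique(ct$ct[ct$condition == "control" & ct$gene == "g1"])
  lo <- unique(ct$ct[ct$condition == "knockdown" & ct$gene == "g1"])
  expect_equal(lo - hi, 1)
  # reference genes identical across conditions with zero noise
  refs <- ct[ct$gene == "Gapdh", ]
  expect_equal(length(unique(refs$ct)), 1L)
})

test_that("noise-free qPCR round-trips the amplitude ratio through the ddCt method", {
  cfg <- tiny_config(ct_noise_sd = 0, knockdown_efficiency = 1)
  model <- chain_model()
  wt <- propagate_activities(model, cfg)
  kd <- propagate_activities(model, cfg, knockdown = "a")
  ct <- simulate_qpcr(list(control = wt, knockdown = kd), cfg,
                      genes = c("b", "c"))
  res <- qpcr_test(ct, genes = c("b", "c"))
  # b drops from activity 1 to 0: true fold change = amplitude^-1
  expect_equal(res$fold_change[res$gene == "b"], 1 / cfg$amplitude,
               tolerance = 1e-9)
  expect_equal(res$ddct[res$gene == "b"], log2(cfg$amplitude),
               tolerance = 1e-9)
})

test_that("qPCR simulation rejects genes absent from the activities", {
  cfg <- tiny_config()
  wt <- propagate_activities(chain_model(), cfg)
  expect_error(simulate_qpcr(wt, cfg, genes = "nope"), "absent")
})

test_that("in situ scores sit at the background floor without an effect", {
  stages <- c("0ss", "5-6ss")
  base <- tibble::tibble(gene = "g1", stage = stages[2], activity = 1)
  fracs <- vapply(1:1000, function(s) {
    cfg <- sim_config(seed = s, n_genes = 2, n_tiers = 2, stages = stages,
                      ish_embryos = 12)
    tab <- simulate_ish(list(control = base, knockdown = base), cfg,
                        regulator = "r", genes = "g1")
    tab$affected / tab$total
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("a huge effect with high sensitivity saturates the in situ score", {
  stages <- c("0ss", "5-6ss")
  cfg <- sim_config(seed = 3, n_genes = 2, n_tiers = 2, stages = stages,
                    ish_sensitivity = 100, amplitude = 64)
  hi <- tibble::tibble(gene = "g1", stage = stages[2], activity = 1)
  lo <- tibble::tibble(gene = "g1", stage = stages[2], activity = 0)
  tab <- simulate_ish(list(control = hi, knockdown = lo), cfg,
                      regulator = "r", genes = "g1")
  expect_equal(tab$affected, tab$total)
  expect_equal(tab$direction, "reduced")
  # fixed seed: identical table on re-run
  expect_identical(tab, simulate_ish(list(control = hi, knockdown = lo), cfg,
                                     regulator = "r", genes = "g1"))
})
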