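test_that("the count filter excludes weak genes from panel calls", {
  withr::with_seed(44, {
    ctrl <- matrix(rpois(30 * 3, 500), ncol = 3)
    kd <- matrix(rpois(30 * 3, 500), ncol = 3)
    # gene 1: mean ~250 with a 4-fold drop -> filtered out, call none
    ctrl[1, ] <- c(400, 410, 390)
    kd[1, ] <- c(100, 105, 95)
    res <- nanostring_test(make_panel(ctrl, kd))
    expect_equal(res$call[1], "none")
    expect_false(res$tested[1])
    expect_true(is.na(res$p_value[1]))
  })
})

test_that("fold changes below the 1.2-fold threshold are never called", {
  # noiseless panel: knockdown = control * 1.19 for one gene
  ctrl <- matrix(rep(1000, 20 * 3), ncol = 3)
  kd <- ctrl
  kd[1, ] <- round(1000 * 1.19)
  res <- nanostring_test(make_panel(ctrl, kd))
  expect_true(abs(res$log2_fc[1]) < log2(1.2))
  expect_equal(res$call[1], "none")
})

test_that("a direct activator knockdown is detected in at least 9 of 10 seeds", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, knockdown_efficiency = 0.8,
                      amplitude = 4, dispersion = 0.05, n_replicates = 3L)
    model <- generate_network(cfg)
    # first tier-1 regulator with a directly activated target
    act <- model$edges[model$edges$sign == 1L, ]
    t1 <- model$genes$gene[model$genes$tier == 1]
    reg <- intersect(act$source, t1)[1]
    target <- act$target[act$source == reg][1]
    res <- nanostring_test(simulate_screen(model, cfg, reg))
    res$call[res$gene == target] == "down"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("panel testing is invariant to replicate relabelling", {
  withr::with_seed(55, {
    ctrl <- matrix(rpois(60, 800), ncol = 3)
    kd <- matrix(rpois(60, 500), ncol = 3)
  })
  a <- nanostring_test(make_panel(ctrl, kd))
  b <- nanostring_test(make_panel(ctrl[, c(2, 3, 1)], kd[, c(3, 1, 2)]))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$call, b$call)
})

test_that("tightening any panel threshold never converts none into a call", {
  cfg <- sim_config(seed = 12, n_genes = 12)
  model <- generate_network(cfg)
  panel <- simulate_screen(model, cfg, screen_regulators(model)[1])
  base <- nanostring_test(panel)
  tighter <- list(
    nanostring_test(panel, count_min = 400),
    nanostring_test(panel, fold_min = 1.5),
    nanostring_test(panel, p_adj_max = 0.01))
  for (t in tighter) {
    gained <- t$call != "none" & base$call == "none"
    expect_false(any(gained))
  }
})

test_that("the ddCt closed forms hold exactly", {
  expect_equal(qpcr_test(make_ct(0), genes = "t")$fold_change, 1)
  res1 <- qpcr_test(make_ct(1, noise = 0.05), genes = "t")
  expect_equal(res1$fold_change, 0.5, tolerance = 0.15)
  # noise-free: FC(1) = 0.5 exactly and a significant call is down
  exact <- qpcr_test(make_ct(1), genes = "t")
  expect_equal(exact$fold_change, 0.5)
  expect_equal(exact$call, "down")
  expect_equal(qpcr_test(make_ct(-1), genes = "t")$fold_change, 2)
})

test_that("ddCt is invariant to a constant Ct shift", {
  ct <- make_ct(1.3, noise = 0.2)
  shifted <- dplyr::mutate(ct, ct = ct + 5)
  a <- qpcr_test(ct, genes = "t")
  b <- qpcr_test(shifted, genes = "t")
  expect_identical(a$ddct, b$ddct)
  expect_identical(a$fold_change, b$fold_change)
})

test_that("qPCR calling requires both the fold and significance thresholds", {
  # large shift but only noise-driven significance; drop p threshold to force none
  res <- qpcr_test(make_ct(1, noise = 0.05), genes = "t", p_max = 1e-12)
  expect_equal(res$call, "none")
  # sub-threshold fold change with tiny noise: no call despite tiny p
  res2 <- qpcr_test(make_ct(0.3, noise = 0.01), genes = "t")
  expect_equal(res2$call, "none")
})

test_that("qPCR errors on missing references or replicates", {
  ct <- make_ct(1)
  expect_error(qpcr_test(dplyr::filter(ct, gene != "Gapdh"), genes = "t"),
               "Gapdh")
  expect_error(qpcr_test(dplyr::filter(ct, bio_rep == 1), genes = "t"),
               "replicates")
})

test_that("in situ calls follow the majority rule on the reported fractions", {
  expect_equal(ish_call(8, 12, "reduced")$call, "down")
  expect_equal(ish_call(4, 4, "reduced")$call, "down")
  expect_equal(ish_call(2, 6, "reduced")$call, "none")
  expect_equal(ish_call(3, 6, "reduced")$call, "none")  # exactly half: no call
  expect_equal(ish_call(2, 3, "reduced")$call, "none")  # fewer than 4 embryos
  expect_equal(ish_call(5, 6, "enhanced")$call, "up")
  expect_error(ish_call(7, 6, "reduced"), "exceed")
  expect_error(ish_call(1, 0, "reduced"), "total")
})

test_that("evidence integration follows agreement and in situ precedence", {
  row <- function(mod, call) tibble::tibble(regulator = "r", target = "t",
                                            modality = mod, call = call)
  run <- function(...) integrate_evidence(dplyr::bind_rows(...))

  # agreement across two modalities
  both <- run(row("nanostring", "down"), row("qpcr", "down"))
  expect_equal(both$integrated, "activated")
  expect_false(both$conflict)

  # conflict with in situ present: in situ wins, conflict flagged
  ish_wins <- run(row("nanostring", "up"), row("qpcr", "down"),
                  row("ish", "down"))
  expect_equal(ish_wins$integrated, "activated")
  expect_true(ish_wins$conflict)

  # two-method rule unmet without in situ: unresolved
  split2 <- run(row("nanostring", "down"), row("qpcr", "none"))
  expect_equal(split2$integrated, "unresolved")

  # two methods agreeing define the interaction even if in situ saw nothing
  two_agree <- run(row("nanostring", "down"), row("qpcr", "down"),
                   row("ish", "none"))
  expect_equal(two_agree$integrated, "activated")
  expect_true(two_agree$conflict)

  # single-modality evidence stands
  single <- run(row("nanostring", "up"))
  expect_equal(single$integrated, "repressed")

  # full three-way disagreement with uninformative in situ: unresolved
  chaos <- run(row("nanostring", "down"), row("qpcr", "up"), row("ish", "none"))
  expect_equal(chaos$integrated, "unresolved")

  expect_error(integrate_evidence(tibble::tibble()), "modality")
  expect_error(run(row("qpcr", "down"), row("qpcr", "up")), "duplicate")
})
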