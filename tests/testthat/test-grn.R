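test_that("edges are derived from integrated calls with the right signs", {
  calls <- tibble::tibble(
    regulator = c("Pax2", "Pax2", "Pax2", "Pax2"),
    target = c("Lmx1a", "Foxi3", "Sox13", "Gbx2"),
    integrated = c("activated", "repressed", "none", "unresolved"),
    modalities = "ish;nanostring", conflict = FALSE)
  edges <- edges_from_calls(calls)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$sign[edges$target == "Lmx1a"], 1L)
  expect_equal(edges$sign[edges$target == "Foxi3"], -1L)
  expect_true(all(edges$provenance == "perturbation"))

  expect_equal(nrow(edges_from_calls(calls[0, ])), 0)
  dup <- dplyr::bind_rows(calls[1, ],
                          dplyr::mutate(calls[1, ], integrated = "repressed"))
  expect_error(edges_from_calls(dup), "conflicting")
})

test_that("the worked three-gene parsimony example reduces correctly", {
  e <- tibble::tibble(source = c("g1", "g1", "g2"),
                      target = c("g2", "g3", "g3"), sign = 1L)
  out <- transitive_reduce(e)
  removed <- out[out$removed_by_parsimony, ]
  expect_equal(nrow(removed), 1)
  expect_equal(removed$source, "g1")
  expect_equal(removed$target, "g3")
})

test_that("a two-gene positive feedback loop survives reduction", {
  e <- tibble::tibble(source = c("Pax2", "Lmx1a"),
                      target = c("Lmx1a", "Pax2"), sign = 1L)
  out <- transitive_reduce(e)
  expect_false(any(out$removed_by_parsimony))
})

test_that("repressive shortcuts are never removed", {
  e <- tibble::tibble(source = c("a", "a", "b"), target = c("b", "c", "c"),
                      sign = c(1L, -1L, -1L))
  out <- transitive_reduce(e)
  expect_false(any(out$removed_by_parsimony))
})

test_that("reduction is idempotent and preserves reachability on random graphs", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      n <- sample(4:15, 1)
      density <- runif(1, 0.1, 0.4)
      adj <- matrix(runif(n * n) < density, n, n) * 1
      diag(adj) <- 0
      nodes <- paste0("n", seq_len(n))
      idx <- which(adj > 0, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      e <- tibble::tibble(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                          sign = 1L)
      out <- transitive_reduce(e)
      disp <- out[!out$removed_by_parsimony, ]
      # reachability of displayed graph equals that of the full graph
      full_adj <- edges_to_adj(e, n)
      disp_adj <- edges_to_adj(disp, n)
      expect_identical(closure_bool(disp_adj), closure_bool(full_adj))
      # idempotence on the displayed edge set
      again <- transitive_reduce(disp[, c("source", "target", "sign")])
      expect_false(any(again$removed_by_parsimony))
    }
  })
})

test_that("parallel edges into a kept component link are retained", {
  # a feeds both members of a 2-cycle; both parallel edges stay displayed
  e <- tibble::tibble(source = c("a", "a", "x", "y"),
                      target = c("x", "y", "y", "x"), sign = 1L)
  out <- transitive_reduce(e)
  expect_false(any(out$removed_by_parsimony))
})

test_that("gate annotation flags unserializable dual inputs", {
  # Pax2 receives Etv4 and Six1 with no path between them: AND candidate
  e1 <- transitive_reduce(tibble::tibble(
    source = c("Etv4", "Six1"), target = c("Pax2", "Pax2"), sign = 1L))
  g1 <- annotate_gates(e1)
  expect_equal(g1$gate[g1$gene == "Pax2"], "AND-candidate")

  # single input: unknown
  e2 <- transitive_reduce(tibble::tibble(source = "Etv4", target = "Pax2",
                                         sign = 1L))
  expect_equal(annotate_gates(e2)$gate, "unknown")

  # serializable inputs (a -> b exists): unknown
  e3 <- transitive_reduce(tibble::tibble(
    source = c("a", "b", "a"), target = c("b", "t", "t"), sign = 1L))
  g3 <- annotate_gates(e3)
  expect_equal(g3$gate[g3$gene == "t"], "unknown")
})

test_that("feed-forward ambiguity triples are enumerated", {
  e <- tibble::tibble(
    source = c("Etv4", "Etv4", "Pax2", "Etv4", "Pax2"),
    target = c("Pax2", "Sall4", "Sall4", "Irx5", "Irx5"),
    sign = 1L)
  amb <- detect_ffl_ambiguity(e)
  expect_setequal(amb$target, c("Sall4", "Irx5"))
  expect_true(all(amb$a == "Etv4" & amb$b == "Pax2"))
  # a pure chain has no ambiguity
  expect_equal(nrow(detect_ffl_ambiguity(tibble::tibble(
    source = c("a", "b"), target = c("b", "c"), sign = 1L))), 0)
  # sign-discordant shortcut is not ambiguous
  e_mixed <- tibble::tibble(source = c("a", "a", "b"),
                            target = c("b", "t", "t"), sign = c(1L, -1L, 1L))
  expect_equal(nrow(detect_ffl_ambiguity(e_mixed)), 0)
})

test_that("stage of onset is the earliest expressed-and-enriched stage", {
  stages <- c("0ss", "5-6ss", "8-9ss", "11-12ss")
  calls <- tibble::tibble(
    gene = rep(c("late", "never"), each = 4),
    stage = rep(stages, 2),
    expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    enriched = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  out <- assign_stage_of_onset(calls, stages)
  expect_equal(out$stage_of_onset[out$gene == "late"], "8-9ss")
  expect_true(is.na(out$stage_of_onset[out$gene == "never"]))
  expect_equal(unique(out$region), "unassigned")
  expect_error(assign_stage_of_onset(dplyr::mutate(calls, stage = "bogus"),
                                     stages), "unknown stage")
})

test_that("simulated onsets are recovered from noise-free expression", {
  cfg <- tiny_config(size_factor_sd = 0)
  model <- generate_network(cfg)
  series <- simulate_stage_series(model, cfg, n_replicates = 1, exact = TRUE)
  combined <- bind_expr(series$otic, series$reference)
  base_s <- series$reference$meta$sample_id[series$reference$meta$stage == "0ss"]
  calls <- dplyr::bind_rows(lapply(cfg$stages, function(s) {
    test_s <- series$otic$meta$sample_id[series$otic$meta$stage == s]
    fcs <- fold_changes(combined, test_s, base_s)
    call_enriched(fcs, expressed = fcs$mean_test > 300, stage = s)
  }))
  onsets <- assign_stage_of_onset(calls, cfg$stages)
  truth <- model$genes
  activated <- setdiff(truth$gene, unique(model$edges$target[model$edges$sign == -1L]))
  for (g in activated) {
    expect_equal(onsets$stage_of_onset[onsets$gene == g],
                 truth$stage_of_onset[truth$gene == g])
  }
})

test_that("literature merge unions edges, honours sign and direct flags", {
  inferred <- assemble_network(tibble::tibble(
    source = c("Pax2", "Pax2"), target = c("Sox10", "Lmx1a"),
    sign = c(-1L, 1L), evidence = "nanostring", provenance = "perturbation"))
  curated <- tibble::tibble(
    source = c("Pax2", "Sox8"), target = c("Sox10", "Sox10"),
    sign = c(1L, 1L), direct = TRUE, citation = c("ref1", "ref2"))
  expect_message(merged <- merge_literature(inferred, curated), "overrides")
  e <- merged$edges
  expect_equal(nrow(e), 3)
  sox10 <- e[e$source == "Pax2" & e$target == "Sox10", ]
  expect_equal(sox10$sign, 1L)  # literature sign wins
  expect_true(sox10$direct)
  expect_match(sox10$provenance, "perturbation;literature")
  # the untouched inferred edge keeps its provenance
  expect_equal(e$provenance[e$target == "Lmx1a"], "perturbation")
  conf <- attr(merged, "sign_conflicts")
  expect_equal(nrow(conf), 1)

  # empty curated table leaves the network unchanged
  unchanged <- merge_literature(inferred, curated[0, ])
  expect_identical(unchanged$edges, inferred$edges)

  # malformed rows are reported by line number
  bad <- tibble::tibble(source = c("a", ""), target = c("b", "c"),
                        sign = c(1L, 3L), direct = FALSE, citation = "x")
  expect_error(merge_literature(inferred, bad), "row")
})
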