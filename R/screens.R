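#' Run one simulated knockdown screen and call targets
#'
#' Simulates the requested read-outs for a single regulator's knockdown
#' (count panel, qPCR, in situ hybridization), applies each modality's
#' calling rules at the supplied thresholds, and integrates the evidence.
#'
#' @param model An `otog_truth` model.
#' @param config The matching [sim_config()].
#' @param regulator Gene to knock down.
#' @param modalities Subset of `c("nanostring", "qpcr", "ish")`.
#' @param thresholds Named list overriding calling thresholds: `count_min`,
#'   `ns_fold`, `ns_p_adj`, `qpcr_fold`, `qpcr_p`, `ish_min_n`,
#'   `ish_min_fraction`.
#' @return Integrated call tibble from [integrate_evidence()], with the
#'   per-modality tables attached as attribute `"modality_results"`.
#' @export
run_knockdown_screen <- function(model, config, regulator,
                                 modalities = c("nanostring", "qpcr", "ish"),
                                 thresholds = list()) {
  modalities <- match.arg(modalities, c("nanostring", "qpcr", "ish"),
                          several.ok = TRUE)
  th <- modifyList(list(count_min = 300, ns_fold = 1.2, ns_p_adj = 0.1,
                        qpcr_fold = 1.5, qpcr_p = 0.05,
                        ish_min_n = 4, ish_min_fraction = 0.5), thresholds)
  targets <- setdiff(model$genes$gene, regulator)
  results <- list()
  call_rows <- list()

  if ("nanostring" %in% modalities) {
    panel <- simulate_screen(model, config, regulator)
    ns <- nanostring_test(panel, count_min = th$count_min,
                          fold_min = th$ns_fold, p_adj_max = th$ns_p_adj)
    results$nanostring <- ns
    call_rows$nanostring <- ns |>
      filter(.data$gene %in% targets) |>
      transmute(regulator = regulator, target = .data$gene,
                modality = "nanostring", call = .data$call)
  }

  if ("qpcr" %in% modalities || "ish" %in% modalities) {
    wt <- propagate_activities(model, config)
    kd <- propagate_activities(model, config, knockdown = regulator)
  }

  if ("qpcr" %in% modalities) {
    ct <- simulate_qpcr(list(control = wt, knockdown = kd), config,
                        genes = targets)
    qp <- qpcr_test(ct, genes = targets, fold_min = th$qpcr_fold,
                    p_max = th$qpcr_p)
    results$qpcr <- qp
    call_rows$qpcr <- qp |>
      transmute(regulator = regulator, target = .data$gene,
                modality = "qpcr", call = .data$call)
  }

  if ("ish" %in% modalities) {
    ish <- simulate_ish(list(control = wt, knockdown = kd), config,
                        regulator = regulator, genes = targets)
    ic <- ish_call(ish$affected, ish$total, ish$direction,
                   min_n = th$ish_min_n, min_fraction = th$ish_min_fraction)
    results$ish <- bind_cols(ish |> select("regulator", "gene"), ic)
    call_rows$ish <- results$ish |>
      transmute(regulator = .data$regulator, target = .data$gene,
                modality = "ish", call = .data$call)
  }

  integrated <- integrate_evidence(bind_rows(call_rows))
  attr(integrated, "modality_results") <- results
  integrated
}

#' Infer a network from a full knockdown screen of a truth model
#'
#' Runs [run_knockdown_screen()] for every screened regulator (default: all
#' tier-1/2 regulators), converts integrated calls to signed edges, applies
#' the parsimony reduction, and assembles the network with gate and
#' feed-forward annotations.
#'
#' @inheritParams run_knockdown_screen
#' @param regulators Regulators to knock down (default [screen_regulators()]).
#' @return An `otog_network`.
#' @export
infer_network <- function(model, config,
                          regulators = screen_regulators(model),
                          modalities = c("nanostring", "qpcr", "ish"),
                          thresholds = list()) {
  calls <- bind_rows(lapply(regulators, function(r) {
    run_knockdown_screen(model, config, r, modalities = modalities,
                         thresholds = thresholds)
  }))
  edges <- edges_from_calls(calls)
  ffl <- detect_ffl_ambiguity(edges)
  edges <- transitive_reduce(edges)
  assemble_network(edges, ambiguities = ffl)
}

#' End-to-end recovery of a simulated truth network
#'
#' Generates a ground-truth network, runs the full knockdown screen and the
#' inference pipeline, and scores the inferred network against the truth.
#'
#' @inheritParams infer_network
#' @return One-row tibble from [score_recovery()], with the network and truth
#'   attached as attributes.
#' @examples
#' \donttest{
#' screen_recovery(sim_config(seed = 3, n_genes = 12))
#' }
#' @export
screen_recovery <- function(config,
                            modalities = c("nanostring", "qpcr", "ish"),
                            thresholds = list()) {
  model <- generate_network(config)
  net <- infer_network(model, config, modalities = modalities,
                       thresholds = thresholds)
  metrics <- score_recovery(net, model)
  attr(metrics, "network") <- net
  attr(metrics, "truth") <- model
  metrics
}

#' Volcano-style plot of a panel screen result
#'
#' @param result Output of [nanostring_test()].
#' @param fold_min,p_adj_max Thresholds drawn as guide lines.
#' @return A ggplot of log2 fold change against -log10 adjusted p.
#' @export
plot_screen <- function(result, fold_min = 1.2, p_adj_max = 0.1) {
  d <- result |> filter(.data$tested)
  ggplot(d, aes(x = .data$log2_fc, y = -log10(.data$p_adj),
                colour = .data$call)) +
    geom_point() +
    geom_vline(xintercept = c(-1, 1) * log2(fold_min), linetype = 2) +
    geom_hline(yintercept = -log10(p_adj_max), linetype = 2) +
    scale_colour_manual(values = c(down = "#2a9d2a", up = "#d62728",
                                   none = "grey60")) +
    labs(x = "log2 fold change (knockdown / control)",
         y = "-log10 adjusted p", colour = "call") +
    theme_minimal()
}
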