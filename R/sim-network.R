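#' Construct a ground-truth regulatory model
#'
#' Low-level constructor used by [generate_network()] and by tests that need a
#' hand-built truth network (including degenerate ones such as a zero-edge
#' network for null-screen calibration).
#'
#' @param genes Tibble with columns `gene`, `tier` (integer),
#'   `stage_of_onset` (stage label) and `gate` (`"AND"` or `"OR"`).
#' @param edges Tibble with columns `source`, `target`, `sign` (+1/-1).
#' @param feedback Tibble with columns `gene_a`, `gene_b` designating
#'   mutual-activation pairs (the only tolerated cycles).
#' @param stages Ordered stage labels the model lives on.
#'
#' @return An object of class `otog_truth`.
#' @export
truth_model <- function(genes, edges = NULL, feedback = NULL,
                        stages = c("0ss", "5-6ss", "8-9ss", "11-12ss")) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "tier", "stage_of_onset") %in% names(genes)))
  if (!"gate" %in% names(genes)) genes$gate <- "AND"
  if (anyDuplicated(genes$gene)) abort("gene ids must be unique")
  if (!all(genes$stage_of_onset %in% stages)) {
    abort("stage_of_onset labels must be drawn from `stages`")
  }
  edges <- if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    tibble(source = character(), target = character(), sign = integer())
  } else {
    as_tibble(edges) |> mutate(sign = as.integer(.data$sign))
  }
  feedback <- if (is.null(feedback)) {
    tibble(gene_a = character(), gene_b = character())
  } else {
    as_tibble(feedback)
  }
  model <- structure(
    list(genes = genes, edges = edges, feedback = feedback, stages = stages),
    class = "otog_truth"
  )
  validate_truth(model)
}

validate_truth <- function(model) {
  genes <- model$genes
  edges <- model$edges
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) abort("self-edges are not allowed")
    if (!all(c(edges$source, edges$target) %in% genes$gene)) {
      abort("edge endpoints must be model genes")
    }
    if (!all(edges$sign %in% c(-1L, 1L))) abort("edge signs must be +1 or -1")
    tier <- setNames(genes$tier, genes$gene)
    fb_pairs <- c(paste(model$feedback$gene_a, model$feedback$gene_b),
                  paste(model$feedback$gene_b, model$feedback$gene_a))
    ok <- tier[edges$source] <= tier[edges$target] |
      paste(edges$source, edges$target) %in% fb_pairs
    if (!all(ok)) {
      abort("tier(source) must be <= tier(target) except for feedback pairs")
    }
  }
  model
}

#' Generate a tiered signed ground-truth network
#'
#' Draws a hierarchical signed regulatory network that mirrors the deep
#' structure of embryonic networks: a small set of tier-1 inputs, middle-tier
#' regulators, and downstream effectors. Non-input genes come in two kinds:
#'
#' * **activated targets** receive one essential activating parent from a
#'   strictly lower tier (guaranteeing reachability from the inputs) plus a
#'   Poisson number of additional activators, integrated through an AND
#'   (product) gate by default or an OR (max) gate with probability
#'   `or_gate_fraction`;
#' * **repressed targets** (probability `repressor_fraction`) are
#'   intrinsically expressed genes — alternative-fate or progenitor factors
#'   that the network clears — with exactly one repressive input from a lower
#'   tier and no activators.
#'
#' A designated number of two-gene mutual-activation feedback pairs is placed
#' in tier 2, modelling loops such as the mutual maintenance of otic identity
#' genes. Repressed targets never serve as regulators.
#'
#' Activated genes switch on at the stage matching their tier (tier-1 inputs
#' at the first stage, etc., capped at the final stage), so the
#' stage-of-onset annotation of the truth model is recoverable from
#' noise-free expression.
#'
#' @param config An [sim_config()] object.
#' @return An `otog_truth` model (see [truth_model()]).
#' @examples
#' net <- generate_network(sim_config(seed = 7, n_genes = 12))
#' tidy(net)
#' @export
generate_network <- function(config) {
  validate_config(config)
  with_seed(seed_salt(config$seed, "network"), {
    n <- config$n_genes
    n_tiers <- config$n_tiers
    gene_ids <- sprintf("g%02d", seq_len(n))

    # tier sizes proportional to tier index (pyramidal hierarchy), each >= 1
    raw <- n * seq_len(n_tiers) / sum(seq_len(n_tiers))
    sizes <- pmax(1L, floor(raw))
    while (sum(sizes) < n) sizes[which.max(raw - sizes)] <- sizes[which.max(raw - sizes)] + 1L
    while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    tier <- rep(seq_len(n_tiers), times = sizes)

    nontier1 <- gene_ids[tier > 1]
    repressed <- nontier1[runif(length(nontier1)) < config$repressor_fraction]
    regulators_pool <- setdiff(gene_ids, repressed)  # repressed genes are terminal
    activated <- setdiff(nontier1, repressed)

    onset_idx <- pmin(tier, length(config$stages))
    genes <- tibble(
      gene = gene_ids,
      tier = as.integer(tier),
      stage_of_onset = config$stages[onset_idx],
      gate = ifelse(runif(n) < config$or_gate_fraction, "OR", "AND")
    )

    n_fb <- min(config$n_feedback, floor(sum(gene_ids %in% regulators_pool &
                                               tier == 2) / 2))
    # calibrate extra activator edges so total edge count hits the target
    lambda <- max(0, (config$edges_per_gene * n - length(activated) -
                        length(repressed) - 2 * n_fb) /
                    max(1L, length(activated)))

    edge_list <- list()
    for (g in activated) {
      lower <- regulators_pool[tier[match(regulators_pool, gene_ids)] <
                                 tier[match(g, gene_ids)]]
      essential <- sample(lower, 1L)
      pool <- setdiff(lower, essential)
      k <- min(rpois(1L, lambda), length(pool))
      extra <- if (k > 0) sample(pool, k) else character()
      edge_list[[g]] <- tibble(source = c(essential, extra), target = g,
                               sign = 1L)
    }
    for (g in repressed) {
      lower <- regulators_pool[tier[match(regulators_pool, gene_ids)] <
                                 tier[match(g, gene_ids)]]
      edge_list[[g]] <- tibble(source = sample(lower, 1L), target = g,
                               sign = -1L)
    }
    edges <- bind_rows(edge_list)

    # feedback pairs: mutual activation inside tier 2
    feedback <- tibble(gene_a = character(), gene_b = character())
    if (n_fb > 0) {
      t2 <- gene_ids[tier == 2 & gene_ids %in% regulators_pool]
      picked <- sample(t2, 2L * n_fb)
      feedback <- tibble(gene_a = picked[seq_len(n_fb) * 2 - 1],
                         gene_b = picked[seq_len(n_fb) * 2])
      fb_edges <- bind_rows(
        tibble(source = feedback$gene_a, target = feedback$gene_b, sign = 1L),
        tibble(source = feedback$gene_b, target = feedback$gene_a, sign = 1L)
      )
      edges <- edges |>
        anti_join(fb_edges, by = c("source", "target")) |>
        bind_rows(fb_edges)
    }

    edges <- edges |> distinct(.data$source, .data$target, .keep_all = TRUE) |>
      arrange(.data$source, .data$target)

    truth_model(genes, edges, feedback, stages = config$stages)
  })
}

#' @export
print.otog_truth <- function(x, ...) {
  cat("<otog_truth>\n")
  cat(sprintf("  %d genes in %d tiers, %d signed edges (%d repressive)\n",
              nrow(x$genes), max(x$genes$tier), nrow(x$edges),
              sum(x$edges$sign == -1L)))
  if (nrow(x$feedback)) {
    cat(sprintf("  feedback pairs: %s\n",
                paste(x$feedback$gene_a, x$feedback$gene_b,
                      sep = "<->", collapse = ", ")))
  }
  invisible(x)
}

#' @rdname truth_model
#' @param x An `otog_truth` model.
#' @param ... Unused.
#' @export
tidy.otog_truth <- function(x, ...) x$edges

#' @rdname truth_model
#' @export
glance.otog_truth <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_tiers = max(x$genes$tier),
    n_edges = nrow(x$edges),
    n_repressive = sum(x$edges$sign == -1L),
    n_feedback_pairs = nrow(x$feedback),
    mean_in_degree = nrow(x$edges) / nrow(x$genes)
  )
}

#' Regulators eligible for a knockdown screen
#'
#' Returns the genes whose knockdown is informative in a tiered screen: by
#' default everything below the final tier (the tier-1 and tier-2 regulators
#' of the default three-tier hierarchy).
#'
#' @param model An `otog_truth` model.
#' @param max_tier Highest tier to include (default one below the deepest).
#' @return Character vector of gene ids.
#' @export
screen_regulators <- function(model, max_tier = max(model$genes$tier) - 1L) {
  model$genes$gene[model$genes$tier <= max_tier]
}
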