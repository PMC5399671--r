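#' Signed edges from integrated regulatory calls
#'
#' `activated` targets yield a positive edge regulator -> target, `repressed`
#' targets a negative one; `none` and `unresolved` produce no edge. The
#' contributing modalities are carried along as evidence.
#'
#' @param calls Integrated calls from [integrate_evidence()] (possibly
#'   concatenated over several regulators' screens).
#' @return Edge tibble: `source`, `target`, `sign`, `evidence`, `provenance`.
#' @export
edges_from_calls <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(tibble(source = character(), target = character(), sign = integer(),
                  evidence = character(), provenance = character()))
  }
  dup <- calls |>
    filter(.data$integrated %in% c("activated", "repressed")) |>
    distinct(.data$regulator, .data$target, .data$integrated) |>
    count(.data$regulator, .data$target) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("conflicting duplicate calls for pair(s): %s",
                  paste(dup$regulator, dup$target, sep = "->", collapse = ", ")))
  }
  calls |>
    filter(.data$integrated %in% c("activated", "repressed"),
           .data$regulator != .data$target) |>
    transmute(source = .data$regulator, target = .data$target,
              sign = ifelse(.data$integrated == "activated", 1L, -1L),
              evidence = .data$modalities %||% "perturbation",
              provenance = "perturbation") |>
    distinct(.data$source, .data$target, .keep_all = TRUE)
}

#' Parsimony (transitive) reduction of activation chains
#'
#' Implements the most-parsimonious-pathway rule: if gene 1 regulates genes 2
#' and 3, and gene 2 regulates gene 3, the direct link 1 -> 3 is assumed to
#' run through gene 2 and is withdrawn from the displayed graph. The rule
#' applies to the activation (+) subgraph only — repressive shortcuts are
#' never removed. Cycles are handled by condensing strongly connected
#' components: all intra-component edges are kept (there is no principled
#' basis to drop edges inside a feedback loop), the transitive reduction is
#' computed on the acyclic condensation, and when a component-to-component
#' link is kept all parallel original edges between those components are
#' kept. Removed edges are flagged `removed_by_parsimony`, never deleted, so
#' downstream reports can still cite them; reachability of the displayed
#' graph equals that of the full called graph.
#'
#' @param edges Edge tibble with columns `source`, `target`, `sign` (and any
#'   others, carried through).
#' @return The same tibble with a logical `removed_by_parsimony` column.
#' @examples
#' e <- tibble::tibble(source = c("g1", "g1", "g2"),
#'                     target = c("g2", "g3", "g3"), sign = 1L)
#' transitive_reduce(e)
#' @export
transitive_reduce <- function(edges) {
  edges <- as_tibble(edges)
  edges$removed_by_parsimony <- FALSE
  pos <- edges$sign == 1L
  if (sum(pos) < 2) return(edges)

  pe <- edges[pos, c("source", "target")]
  verts <- unique(c(pe$source, pe$target))
  g <- igraph::graph_from_data_frame(pe, directed = TRUE, vertices = verts)
  comp <- igraph::components(g, mode = "strong")$membership

  src_c <- comp[pe$source]
  tgt_c <- comp[pe$target]
  inter <- src_c != tgt_c
  cedges <- unique(cbind(src_c[inter], tgt_c[inter]))
  if (nrow(cedges) == 0) return(edges)

  # condensation DAG and its reachability
  nc <- max(comp)
  cg <- igraph::graph_from_edgelist(matrix(as.character(cedges), ncol = 2),
                                    directed = TRUE)
  reach <- !is.infinite(igraph::distances(cg, mode = "out"))
  vn <- igraph::V(cg)$name
  succ <- lapply(seq_len(nrow(cedges)), function(i) {
    cedges[cedges[, 1] == cedges[i, 1] & cedges[, 2] != cedges[i, 2], 2]
  })
  redundant <- vapply(seq_len(nrow(cedges)), function(i) {
    w <- succ[[i]]
    any(reach[match(as.character(w), vn), match(as.character(cedges[i, 2]), vn)])
  }, logical(1))

  red_keys <- paste(cedges[redundant, 1], cedges[redundant, 2])
  edge_comp_key <- rep(NA_character_, nrow(edges))
  edge_comp_key[pos] <- paste(src_c, tgt_c)
  edges$removed_by_parsimony <- !is.na(edge_comp_key) & edge_comp_key %in% red_keys
  edges
}

#' Detect feed-forward ambiguity triples
#'
#' Lists every ordered triple (A, B, T) with called edges A -> B, A -> T and
#' B -> T where A -> T and B -> T carry the same sign: knockdown data alone
#' cannot distinguish the feed-forward loop from the linear chain
#' A -> B -> T, so both hypotheses are retained.
#'
#' @param edges Called edge tibble (before reduction).
#' @return Tibble: `a`, `b`, `target`, `sign`, `note`.
#' @export
detect_ffl_ambiguity <- function(edges) {
  edges <- as_tibble(edges)
  e2 <- edges |> select(a = "source", b = "target")
  at <- edges |> select(a = "source", target = "target", sign_at = "sign")
  bt <- edges |> select(b = "source", target = "target", sign_bt = "sign")
  e2 |>
    inner_join(at, by = "a", relationship = "many-to-many") |>
    inner_join(bt, by = c("b", "target"), relationship = "many-to-many") |>
    filter(.data$target != .data$a, .data$target != .data$b,
           .data$sign_at == .data$sign_bt) |>
    transmute(a = .data$a, b = .data$b, target = .data$target,
              sign = .data$sign_at,
              note = "linear-vs-FFL unresolvable from knockdown data alone") |>
    distinct()
}

#' Annotate AND-gate candidate targets
#'
#' A target is an AND-gate candidate when it has two or more activating
#' inputs whose sources are not connected by any displayed path in either
#' direction — parsimony could not serialize the inputs into a chain, so
#' simultaneous input is the simplest explanation (the configuration
#' described for the control of otic commitment genes by posterior PPR
#' factors together with the FGF mediator).
#'
#' @param edges Edge tibble carrying a `removed_by_parsimony` flag (from
#'   [transitive_reduce()]; absent flag means all displayed).
#' @return Tibble: `gene`, `gate` (`"AND-candidate"` or `"unknown"`) for every
#'   target in the edge set.
#' @export
annotate_gates <- function(edges) {
  edges <- as_tibble(edges)
  if (!"removed_by_parsimony" %in% names(edges)) edges$removed_by_parsimony <- FALSE
  displayed <- edges[!edges$removed_by_parsimony, ]
  targets <- unique(edges$target)
  if (nrow(displayed) == 0) {
    return(tibble(gene = targets, gate = "unknown"))
  }
  verts <- unique(c(displayed$source, displayed$target))
  g <- igraph::graph_from_data_frame(displayed[, c("source", "target")],
                                     directed = TRUE, vertices = verts)
  reach <- !is.infinite(igraph::distances(g, mode = "out"))
  gate <- vapply(targets, function(tg) {
    ins <- unique(displayed$source[displayed$target == tg & displayed$sign == 1L])
    if (length(ins) < 2) return("unknown")
    ii <- match(ins, verts)
    for (p in seq_along(ins)) {
      for (q in seq_along(ins)) {
        if (p < q && !reach[ii[p], ii[q]] && !reach[ii[q], ii[p]]) {
          return("AND-candidate")
        }
      }
    }
    "unknown"
  }, character(1))
  tibble(gene = targets, gate = unname(gate))
}

#' Stage-of-onset and region annotation for network nodes
#'
#' The stage of onset is the earliest stage at which a gene is both expressed
#' and enriched; genes never enriched are left unassigned. Region labels are
#' taken from a user-supplied spatial annotation table when available.
#'
#' @param enrich_calls Tibble of per-stage calls with columns `gene`, `stage`,
#'   `expressed`, `enriched` (from [call_enriched()], stacked over stages).
#' @param stages Ordered stage labels.
#' @param regions Optional tibble `gene`, `region` with labels among
#'   PPR/OEP/otic/epibranchial/both.
#' @return Tibble: `gene`, `stage_of_onset` (NA when unassigned), `region`.
#' @export
assign_stage_of_onset <- function(enrich_calls, stages, regions = NULL) {
  enrich_calls <- as_tibble(enrich_calls)
  unknown <- setdiff(unique(enrich_calls$stage), stages)
  if (length(unknown)) {
    abort(sprintf("unknown stage label(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- enrich_calls |>
    mutate(stage_idx = match(.data$stage, stages)) |>
    summarise(
      stage_of_onset = if (any(.data$expressed & .data$enriched)) {
        stages[min(.data$stage_idx[.data$expressed & .data$enriched])]
      } else NA_character_,
      .by = "gene"
    )
  region_lvls <- c("PPR", "OEP", "otic", "epibranchial", "both", "unassigned")
  if (!is.null(regions)) {
    out <- out |> left_join(as_tibble(regions), by = "gene") |>
      mutate(region = ifelse(is.na(.data$region), "unassigned", .data$region))
    if (!all(out$region %in% region_lvls)) abort("invalid region label")
  } else {
    out$region <- "unassigned"
  }
  out
}

#' Assemble a signed, stage-annotated regulatory network
#'
#' Bundles called edges (after [transitive_reduce()]), node annotations, gate
#' labels and feed-forward ambiguities into a single network object.
#'
#' @param edges Edge tibble with `source`, `target`, `sign`, optional
#'   `evidence`, `provenance`, `direct`, `removed_by_parsimony`.
#' @param nodes Optional tibble `gene`, `stage_of_onset`, `region`; genes
#'   appearing only in edges are added unassigned.
#' @param gates Optional gate tibble (default: [annotate_gates()] on edges).
#' @param ambiguities Optional FFL tibble (default: [detect_ffl_ambiguity()]).
#' @return An object of class `otog_network`.
#' @export
assemble_network <- function(edges, nodes = NULL, gates = NULL,
                             ambiguities = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L))) {
    abort("edge signs must be +1 or -1")
  }
  for (col in c("evidence", "provenance")) {
    if (!col %in% names(edges)) edges[[col]] <- rep("unspecified", nrow(edges))
  }
  if (!"direct" %in% names(edges)) edges$direct <- rep(FALSE, nrow(edges))
  if (!"removed_by_parsimony" %in% names(edges)) {
    edges$removed_by_parsimony <- rep(FALSE, nrow(edges))
  }
  edges <- edges |> mutate(sign = as.integer(.data$sign)) |>
    select("source", "target", "sign", "evidence", "provenance", "direct",
           "removed_by_parsimony") |>
    arrange(.data$source, .data$target)

  all_genes <- unique(c(edges$source, edges$target,
                        if (!is.null(nodes)) as_tibble(nodes)$gene))
  base_nodes <- tibble(gene = all_genes, stage_of_onset = NA_character_,
                       region = "unassigned")
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    idx <- match(nodes$gene, base_nodes$gene)
    if ("stage_of_onset" %in% names(nodes)) {
      base_nodes$stage_of_onset[idx] <- nodes$stage_of_onset
    }
    if ("region" %in% names(nodes)) {
      base_nodes$region[idx] <- ifelse(is.na(nodes$region), "unassigned",
                                       nodes$region)
    }
  }
  base_nodes <- base_nodes |> arrange(.data$gene)

  gates <- if (is.null(gates)) annotate_gates(edges) else as_tibble(gates)
  ambiguities <- if (is.null(ambiguities)) detect_ffl_ambiguity(edges) else as_tibble(ambiguities)

  structure(list(nodes = base_nodes, edges = edges,
                 gates = gates |> arrange(.data$gene),
                 ambiguities = ambiguities),
            class = "otog_network")
}

#' @export
print.otog_network <- function(x, ...) {
  disp <- sum(!x$edges$removed_by_parsimony)
  cat(sprintf("<otog_network> %d nodes, %d edges displayed (%d withdrawn by parsimony)\n",
              nrow(x$nodes), disp, nrow(x$edges) - disp))
  cat(sprintf("  %d repressive edge(s), %d AND-gate candidate(s), %d FFL ambiguity triple(s)\n",
              sum(x$edges$sign == -1L & !x$edges$removed_by_parsimony),
              sum(x$gates$gate == "AND-candidate"),
              nrow(x$ambiguities)))
  invisible(x)
}

#' Tidiers for assembled networks
#'
#' @param x An `otog_network`.
#' @param ... Unused.
#' @return `tidy()`: the edge table (including withdrawn edges, flagged);
#'   `glance()`: one-row network summary.
#' @export
tidy.otog_network <- function(x, ...) x$edges

#' @rdname tidy.otog_network
#' @export
glance.otog_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges_displayed = sum(!x$edges$removed_by_parsimony),
    n_edges_withdrawn = sum(x$edges$removed_by_parsimony),
    n_repressive = sum(x$edges$sign == -1L & !x$edges$removed_by_parsimony),
    n_and_candidates = sum(x$gates$gate == "AND-candidate"),
    n_ffl_ambiguities = nrow(x$ambiguities)
  )
}

#' Merge curated literature edges into an inferred network
#'
#' Takes the union of inferred and curated edges. A curated edge marked
#' direct sets the edge's direct flag (the highest-confidence tier of the
#' displayed network); when the two sources disagree on sign, the curated
#' sign wins and the conflict is reported. Provenance is recorded per edge.
#'
#' @param network An `otog_network`.
#' @param curated Tibble with columns `source`, `target`, `sign` (+1/-1),
#'   `direct` (logical), `citation`.
#' @return The merged `otog_network`; sign conflicts are attached as the
#'   `"sign_conflicts"` attribute and reported via a message.
#' @export
merge_literature <- function(network, curated) {
  stopifnot(inherits(network, "otog_network"))
  curated <- as_tibble(curated)
  need <- c("source", "target", "sign", "direct", "citation")
  bad <- which(!complete.cases(curated[, intersect(need, names(curated))]) |
                 !curated$sign %in% c(-1, 1) |
                 curated$source == "" | curated$target == "")
  if (length(setdiff(need, names(curated)))) {
    abort(sprintf("curated table lacks column(s): %s",
                  paste(setdiff(need, names(curated)), collapse = ", ")))
  }
  if (length(bad)) {
    abort(sprintf("malformed curated row(s): %s", paste(bad, collapse = ", ")))
  }
  if (nrow(curated) == 0) return(network)

  edges <- network$edges
  key <- paste(edges$source, edges$target)
  conflicts <- list()
  for (i in seq_len(nrow(curated))) {
    k <- paste(curated$source[i], curated$target[i])
    j <- match(k, key)
    if (is.na(j)) {
      edges <- bind_rows(edges, tibble(
        source = curated$source[i], target = curated$target[i],
        sign = as.integer(curated$sign[i]),
        evidence = curated$citation[i], provenance = "literature",
        direct = isTRUE(curated$direct[i]), removed_by_parsimony = FALSE))
      key <- c(key, k)
    } else {
      if (edges$sign[j] != curated$sign[i]) {
        conflicts[[length(conflicts) + 1]] <- tibble(
          source = curated$source[i], target = curated$target[i],
          inferred_sign = edges$sign[j],
          curated_sign = as.integer(curated$sign[i]))
        edges$sign[j] <- as.integer(curated$sign[i])
      }
      edges$direct[j] <- edges$direct[j] || isTRUE(curated$direct[i])
      edges$provenance[j] <- paste(unique(c(
        str_split(edges$provenance[j], ";")[[1]], "literature")), collapse = ";")
      edges$evidence[j] <- paste(unique(c(
        str_split(edges$evidence[j], ";")[[1]], curated$citation[i])), collapse = ";")
    }
  }
  conflicts <- bind_rows(conflicts)
  if (nrow(conflicts)) {
    inform(sprintf("literature sign overrides %d inferred edge(s)", nrow(conflicts)))
  }
  out <- assemble_network(edges, nodes = network$nodes)
  attr(out, "sign_conflicts") <- conflicts
  out
}

#' Plot an assembled network
#'
#' Nodes are layered by stage of onset (unassigned genes in a final layer);
#' activating edges are drawn in blue, repressive in red, withdrawn edges are
#' omitted.
#'
#' @param object An `otog_network`.
#' @param stages Ordered stage labels used for layering.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.otog_network <- function(object,
                                  stages = c("0ss", "5-6ss", "8-9ss", "11-12ss"),
                                  ...) {
  nodes <- object$nodes |>
    mutate(layer = match(.data$stage_of_onset, stages),
           layer = ifelse(is.na(.data$layer), length(stages) + 1L, .data$layer)) |>
    group_by(.data$layer) |>
    mutate(y = seq_len(n()) - (n() + 1) / 2) |>
    ungroup()
  disp <- object$edges |> filter(!.data$removed_by_parsimony) |>
    left_join(nodes |> select(source = "gene", x0 = "layer", y0 = "y"), by = "source") |>
    left_join(nodes |> select(target = "gene", x1 = "layer", y1 = "y"), by = "target") |>
    mutate(sign_lab = ifelse(.data$sign == 1L, "activates", "represses"))
  ggplot() +
    geom_segment(data = disp,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1, colour = .data$sign_lab),
                 alpha = 0.6) +
    geom_point(data = nodes, aes(x = .data$layer, y = .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       aes(x = .data$layer, y = .data$y, label = .data$gene),
                       vjust = -0.8, size = 2.8) +
    scale_colour_manual(values = c(activates = "#3366cc", represses = "#cc3333")) +
    labs(x = "stage layer", y = NULL, colour = NULL) +
    theme_minimal()
}
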