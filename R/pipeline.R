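#' Default pipeline configuration
#'
#' All thresholds default to the study's stated cut-offs: enrichment fold
#' change 1.5, RPKM 4, normalized count 300, panel |log2FC| > log2(1.2) with
#' adjusted p < 0.1, qPCR fold change 1.5 with p < 0.05, and 5 temporal
#' clusters.
#'
#' @return Nested named list with sections `seed`, `simulation`,
#'   `thresholds`, `clustering`, `paths`.
#' @export
default_pipeline_config <- function() {
  sim <- unclass(sim_config())
  sim$seed <- NULL
  list(
    seed = 1,
    simulation = sim,
    thresholds = list(
      fc = 1.5, rpkm_min = 4, count_min = 300,
      ns_fold = 1.2, ns_p_adj = 0.1,
      qpcr_fold = 1.5, qpcr_p = 0.05,
      ish_min_n = 4, ish_min_fraction = 0.5,
      pseudocount = 1
    ),
    clustering = list(
      k = 5, metric = "euclidean", linkage = "complete",
      top_fraction = 0.5, drop_early_downregulated = TRUE
    ),
    paths = list(curated = "")
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML or JSON (by extension), fills every omitted key with its
#' default, and rejects unknown keys and wrong types by name. An empty file
#' yields the full default configuration.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Validated configuration list (class `otog_pipeline_config`).
#' @export
load_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    user <- user %||% list()
  }
  cfg <- merge_config(defaults, user, prefix = NULL)
  validate_config(do.call(sim_config, c(list(seed = cfg$seed), cfg$simulation)))
  structure(cfg, class = "otog_pipeline_config")
}

merge_config <- function(defaults, user, prefix = NULL) {
  keypath <- function(k) paste(c(prefix, k), collapse = ".")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(vapply(unknown, keypath, character(1)), collapse = ", ")))
  }
  out <- defaults
  for (k in names(user)) {
    dval <- defaults[[k]]
    uval <- user[[k]]
    if (is.list(dval) && !is.null(names(dval))) {
      out[[k]] <- merge_config(dval, as.list(uval), prefix = c(prefix, k))
    } else {
      if (!is.null(dval) && !is.null(uval)) {
        ok <- (is.numeric(dval) && is.numeric(uval)) ||
          (is.character(dval) && is.character(uval)) ||
          (is.logical(dval) && is.logical(uval))
        if (!ok) {
          abort(sprintf("configuration key `%s` has the wrong type (expected %s)",
                        keypath(k), class(dval)[1]))
        }
      }
      out[[k]] <- uval
    }
  }
  out
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

sim_config_from <- function(config) {
  do.call(sim_config, c(list(seed = config$seed), config$simulation))
}

require_input <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage `%s` requires missing input file: %s", stage, path))
  }
  path
}

#' Run the full pipeline into an artifact directory
#'
#' Executes the selected stages in order — `simulate` (ground truth, stage
#' series, knockdown screen read-outs), `enrich` (stage-wise enrichment
#' against the whole-embryo reference plus the Venn partition), `cluster`
#' (temporal synexpression clusters), `perturb` (per-modality calls and
#' evidence integration), `assemble` (signed network with parsimony
#' reduction, gates, feed-forward ambiguities, optional literature merge) and
#' `recover` (ground-truth recovery metrics) — writing each stage's tables
#' under `outdir` and finishing with a manifest (seed, thresholds, MD5 of
#' every artifact) so any run is reproducible byte for byte.
#'
#' @param config Configuration from [load_config()] (or `NULL` for defaults).
#' @param outdir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "enrich", "cluster", "perturb", "assemble", "recover")`.
#' @return Path to the manifest JSON, invisibly.
#' @export
run_pipeline <- function(config = NULL, outdir,
                         stages = c("simulate", "enrich", "cluster",
                                    "perturb", "assemble", "recover")) {
  config <- config %||% load_config()
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "screens"), showWarnings = FALSE)
  scfg <- sim_config_from(config)
  th <- config$thresholds
  p <- function(...) file.path(outdir, ...)

  if ("simulate" %in% stages) {
    model <- generate_network(scfg)
    truth_net <- assemble_network(
      model$edges |> mutate(evidence = "simulated", provenance = "truth"),
      nodes = model$genes |> select("gene", "stage_of_onset"))
    export_network(truth_net, p("truth.json"))
    export_network(truth_net, p("truth.sif"))
    series <- simulate_stage_series(model, scfg,
                                    n_replicates = scfg$n_replicates)
    write_expr(series$otic, p("otic.tsv"))
    write_expr(series$reference, p("reference.tsv"))
    for (r in screen_regulators(model)) {
      panel <- simulate_screen(model, scfg, r)
      write_expr(panel, p("screens", paste0(r, "_counts.tsv")))
      wt <- propagate_activities(model, scfg)
      kd <- propagate_activities(model, scfg, knockdown = r)
      targets <- setdiff(model$genes$gene, r)
      readr::write_csv(
        simulate_qpcr(list(control = wt, knockdown = kd), scfg, targets),
        p("screens", paste0(r, "_ct.csv")))
      readr::write_csv(
        simulate_ish(list(control = wt, knockdown = kd), scfg, r, targets),
        p("screens", paste0(r, "_ish.csv")))
    }
    readr::write_csv(tibble(regulator = screen_regulators(model)),
                     p("screens", "regulators.csv"))
  }

  if ("enrich" %in% stages) {
    otic <- read_expr(require_input(p("otic.tsv"), "enrich"),
                      assay = "rnaseq_like")
    ref <- read_expr(require_input(p("reference.tsv"), "enrich"),
                     assay = "rnaseq_like")
    combined <- bind_expr(otic, ref)
    ref_samples <- ref$meta$sample_id[ref$meta$stage == scfg$stages[1]]
    nm <- normalized_values(combined)
    per_stage <- lapply(scfg$stages, function(s) {
      test_samples <- otic$meta$sample_id[otic$meta$stage == s]
      fcs <- fold_changes(combined, test_samples, ref_samples,
                          pseudocount = th$pseudocount)
      rpkm_mean <- setNames(
        rowMeans(as.matrix(otic$rpkm[, test_samples, drop = FALSE])),
        otic$rpkm$gene)
      stats <- tibble(gene = fcs$gene,
                      rpkm = rpkm_mean[fcs$gene],
                      count = rowMeans(nm[fcs$gene, test_samples, drop = FALSE]))
      expressed <- call_expressed(stats, rpkm_min = th$rpkm_min,
                                  count_min = th$count_min)
      call_enriched(fcs, expressed, fc_threshold = th$fc, stage = s) |>
        left_join(stats, by = "gene") |>
        left_join(fcs |> select("gene", "mean_baseline", "mean_test", "log2_fc"),
                  by = "gene")
    })
    enrichment <- bind_rows(per_stage)
    readr::write_tsv(enrichment, p("enrichment.tsv"))
    later <- scfg$stages[-1]
    venn_sets <- lapply(setNames(later, later), function(s) {
      enrichment$gene[enrichment$stage == s & enrichment$enriched]
    })
    readr::write_csv(stage_intersections(venn_sets), p("venn.csv"))
  }

  if ("cluster" %in% stages) {
    enrichment <- readr::read_tsv(require_input(p("enrichment.tsv"), "cluster"),
                                  show_col_types = FALSE)
    cl_cfg <- config$clustering
    later <- setdiff(unique(enrichment$stage), scfg$stages[1])
    keep <- enrichment |>
      filter(.data$stage %in% later) |>
      summarise(any_enriched = any(.data$enriched), .by = "gene") |>
      filter(.data$any_enriched)
    genes <- keep$gene
    if (isTRUE(cl_cfg$drop_early_downregulated)) {
      early <- later[1]
      down_early <- enrichment$gene[enrichment$stage == early &
                                      enrichment$direction == "down"]
      genes <- setdiff(genes, down_early)
    }
    profiles <- enrichment |>
      filter(.data$gene %in% genes, .data$stage %in% later) |>
      select("gene", "stage", "fold_change") |>
      pivot_wider(names_from = "stage", values_from = "fold_change")
    if (nrow(profiles) < cl_cfg$k) {
      abort(sprintf("only %d clusterable genes for k = %d",
                    nrow(profiles), cl_cfg$k))
    }
    z <- zscore_profiles(profiles)
    part <- hierarchical_partition(z, k = cl_cfg$k, metric = cl_cfg$metric,
                                   linkage = cl_cfg$linkage)
    levels_tbl <- enrichment |>
      filter(.data$gene %in% genes, .data$stage %in% later) |>
      select("gene", "stage", "mean_test") |>
      pivot_wider(names_from = "stage", values_from = "mean_test")
    readr::write_csv(tidy(part), p("clusters.csv"))
    readr::write_csv(cluster_profiles(part, levels_tbl,
                                      top_fraction = cl_cfg$top_fraction),
                     p("trajectories.csv"))
  }

  if ("perturb" %in% stages) {
    regs <- readr::read_csv(
      require_input(p("screens", "regulators.csv"), "perturb"),
      show_col_types = FALSE)$regulator
    calls <- bind_rows(lapply(regs, function(r) {
      panel <- read_expr(
        require_input(p("screens", paste0(r, "_counts.tsv")), "perturb"),
        assay = "nanostring_like")
      ns <- nanostring_test(panel, count_min = th$count_min,
                            fold_min = th$ns_fold, p_adj_max = th$ns_p_adj)
      ct <- readr::read_csv(
        require_input(p("screens", paste0(r, "_ct.csv")), "perturb"),
        show_col_types = FALSE)
      qp <- qpcr_test(ct, fold_min = th$qpcr_fold, p_max = th$qpcr_p)
      ish <- readr::read_csv(
        require_input(p("screens", paste0(r, "_ish.csv")), "perturb"),
        show_col_types = FALSE)
      ic <- ish_call(ish$affected, ish$total, ish$direction,
                     min_n = th$ish_min_n, min_fraction = th$ish_min_fraction)
      targets <- setdiff(panel$values$gene, r)
      modal <- bind_rows(
        ns |> filter(.data$gene %in% targets) |>
          transmute(regulator = r, target = .data$gene,
                    modality = "nanostring", call = .data$call),
        qp |> transmute(regulator = r, target = .data$gene,
                        modality = "qpcr", call = .data$call),
        tibble(regulator = r, target = ish$gene, modality = "ish",
               call = ic$call)
      )
      integrate_evidence(modal)
    }))
    readr::write_tsv(calls, p("calls.tsv"))
  }

  if ("assemble" %in% stages) {
    calls <- readr::read_tsv(require_input(p("calls.tsv"), "assemble"),
                             show_col_types = FALSE)
    edges <- edges_from_calls(calls)
    ffl <- detect_ffl_ambiguity(edges)
    edges <- transitive_reduce(edges)
    nodes <- NULL
    if (file.exists(p("enrichment.tsv"))) {
      enrichment <- readr::read_tsv(p("enrichment.tsv"), show_col_types = FALSE)
      nodes <- assign_stage_of_onset(enrichment, scfg$stages)
    }
    net <- assemble_network(edges, nodes = nodes, ambiguities = ffl)
    if (!is.null(config$paths$curated) && nzchar(config$paths$curated)) {
      net <- merge_literature(net, read_curated_edges(config$paths$curated))
    }
    export_network(net, p("network.json"))
    export_network(net, p("network.sif"))
    export_network(net, p("network.graphml"))
  }

  if ("recover" %in% stages) {
    net <- import_network(require_input(p("network.json"), "recover"))
    truth <- import_network(require_input(p("truth.json"), "recover"))
    metrics <- score_recovery(net, truth$edges)
    jsonlite::write_json(as.list(metrics), p("recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  artifacts <- sort(setdiff(
    list.files(outdir, recursive = TRUE, full.names = FALSE),
    "manifest.json"))
  manifest <- list(
    seed = config$seed,
    stages = stages,
    thresholds = th,
    clustering = config$clustering,
    simulation = config$simulation,
    artifacts = setNames(
      as.list(unname(tools::md5sum(file.path(outdir, artifacts)))),
      artifacts)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}
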