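#' Expression matrix container
#'
#' A light container pairing a gene-by-sample value table with per-sample
#' metadata, the substrate of the enrichment, clustering and panel-calling
#' steps. Values are nonnegative; counts must be integral (`value_kind =
#' "expected"` marks deterministic expectation-mode output, which may be
#' fractional).
#'
#' @param values Tibble: first column `gene`, remaining columns one per
#'   sample.
#' @param meta Tibble with columns `sample_id`, `stage`, `condition`,
#'   `replicate`; `sample_id` must match the value columns.
#' @param value_kind One of `"counts"`, `"rpkm"`, `"expected"`.
#' @param assay Free-text assay tag (e.g. `"nanostring_like"`).
#' @param lengths Optional named vector of gene lengths (bp) for RPKM-like
#'   values.
#' @param rpkm Optional tibble of RPKM-like values matching `values`.
#' @return An object of class `otog_expr`.
#' @export
expr_matrix <- function(values, meta, value_kind = c("counts", "rpkm", "expected"),
                        assay = "generic", lengths = NULL, rpkm = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as_tibble(values)
  meta <- as_tibble(meta)
  if (names(values)[1] != "gene") abort("first column of `values` must be `gene`")
  if (anyDuplicated(values$gene)) abort("gene ids must be unique")
  sample_ids <- names(values)[-1]
  if (!setequal(sample_ids, meta$sample_id)) {
    abort("`meta$sample_id` must match the sample columns of `values`")
  }
  meta <- meta[match(sample_ids, meta$sample_id), ]
  vals <- as.matrix(values[, -1])
  if (any(vals < 0)) abort("expression values must be nonnegative")
  if (value_kind == "counts" && any(vals != floor(vals))) {
    abort("counts must be integral")
  }
  structure(list(values = values, meta = meta, value_kind = value_kind,
                 assay = assay, lengths = lengths, rpkm = rpkm),
            class = "otog_expr")
}

#' @export
print.otog_expr <- function(x, ...) {
  cat(sprintf("<otog_expr> %d genes x %d samples (%s, %s)\n",
              nrow(x$values), nrow(x$meta), x$assay, x$value_kind))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$meta$condition), collapse = ", ")))
  invisible(x)
}

# numeric matrix view, genes as rownames
expr_values <- function(x) {
  m <- as.matrix(x$values[, -1])
  rownames(m) <- x$values$gene
  m
}

#' Combine two expression matrices sample-wise
#'
#' @param a,b `otog_expr` objects over the same gene panel.
#' @return A combined `otog_expr`.
#' @export
bind_expr <- function(a, b) {
  if (!identical(a$values$gene, b$values$gene)) {
    abort("expression matrices must share the same gene panel, in order")
  }
  if (any(names(b$values)[-1] %in% names(a$values)[-1])) {
    abort("sample ids overlap between the two matrices")
  }
  expr_matrix(bind_cols(a$values, b$values[, -1]),
              bind_rows(a$meta, b$meta),
              value_kind = a$value_kind, assay = a$assay,
              lengths = a$lengths,
              rpkm = if (!is.null(a$rpkm) && !is.null(b$rpkm)) {
                bind_cols(a$rpkm, b$rpkm[, -1])
              })
}

#' Simulate assay counts from an activity table
#'
#' Draws negative-binomial counts for every gene/sample with mean
#' `sf_j * baseline_mean * amplitude^activity` and variance `m + alpha m^2`,
#' where the per-sample size factors `sf_j` are log-normal around 1. With
#' `dispersion = 0` counts are Poisson. `exact = TRUE` returns the noise-free
#' expected means (size factors 1), useful for closed-form round trips.
#'
#' RNA-seq-like output additionally carries an RPKM-like table computed from a
#' stored per-gene length drawn once from the configuration seed.
#'
#' @param activities Activity tibble from [propagate_activities()].
#' @param config The [sim_config()].
#' @param assay `"nanostring_like"` or `"rnaseq_like"`.
#' @param n_replicates Replicates per stage (defaults to the config value).
#' @param stages Stage labels to simulate (default: all stages present).
#' @param condition Condition label for sample metadata; defaults to the
#'   condition attribute of `activities`.
#' @param exact Return deterministic expected values instead of random draws.
#' @return An [expr_matrix()] object.
#' @export
simulate_counts <- function(activities, config,
                            assay = c("nanostring_like", "rnaseq_like"),
                            n_replicates = config$n_replicates,
                            stages = NULL, condition = NULL, exact = FALSE) {
  assay <- match.arg(assay)
  check_field(is_count(n_replicates), "n_replicates", "must be a positive integer")
  condition <- condition %||% attr(activities, "condition") %||% "sample"
  stages <- stages %||% unique(activities$stage)

  act <- activities |> filter(.data$stage %in% stages)
  wide <- act |> pivot_wider(names_from = "stage", values_from = "activity")
  genes <- wide$gene
  a_mat <- as.matrix(wide[, stages, drop = FALSE])
  mu <- config$baseline_mean * config$amplitude^a_mat  # gene x stage means

  meta <- expand_grid(stage = stages, replicate = seq_len(n_replicates)) |>
    mutate(condition = condition,
           sample_id = sprintf("%s_%s_r%d", condition,
                               gsub("[^0-9A-Za-z]+", "", .data$stage),
                               .data$replicate)) |>
    select("sample_id", "stage", "condition", "replicate")

  salt <- paste("counts", assay, condition, paste(stages, collapse = "|"),
                n_replicates)
  counts <- with_seed(seed_salt(config$seed, salt), {
    sf <- if (exact || config$size_factor_sd == 0) {
      rep(1, nrow(meta))
    } else {
      rlnorm(nrow(meta), 0, config$size_factor_sd)
    }
    m <- matrix(0, nrow = length(genes), ncol = nrow(meta))
    for (j in seq_len(nrow(meta))) {
      mu_j <- sf[j] * mu[, match(meta$stage[j], stages)]
      m[, j] <- if (exact) {
        mu_j
      } else if (config$dispersion == 0) {
        rpois(length(mu_j), mu_j)
      } else {
        rnbinom(length(mu_j), mu = mu_j, size = 1 / config$dispersion)
      }
    }
    m
  })
  colnames(counts) <- meta$sample_id
  values <- bind_cols(tibble(gene = genes), as_tibble(counts))

  lengths <- NULL
  rpkm <- NULL
  if (assay == "rnaseq_like") {
    lengths <- with_seed(seed_salt(config$seed, "gene_lengths"), {
      setNames(round(runif(length(genes), 500, 3000)), genes)
    })
    totals <- colSums(counts)
    rpkm_m <- counts / (lengths[genes] / 1e3) /
      matrix(totals / 1e6, nrow = length(genes), ncol = ncol(counts), byrow = TRUE)
    rpkm <- bind_cols(tibble(gene = genes), as_tibble(rpkm_m))
  }

  expr_matrix(values, meta,
              value_kind = if (exact) "expected" else "counts",
              assay = assay, lengths = lengths, rpkm = rpkm)
}

#' Simulate a single-regulator knockdown screen (count panel)
#'
#' Control and knockdown conditions at the assay stage (default: the final
#' stage, when the screen read-out is taken), combined into one panel. The
#' panel also carries stable background probes — markers of other lineages
#' and states, unaffected by the knockdown — mirroring a real probe set in
#' which network genes are a minority; knocking a top-tier regulator can
#' move most network genes at once, and the median-of-ratios normalization
#' is anchored by the unchanged probes.
#'
#' @inheritParams simulate_counts
#' @param model An `otog_truth` model.
#' @param regulator Gene to knock down.
#' @param stage Stage at which the panel is read out.
#' @param n_background Number of stable background probes (ids `bg001`, ...).
#' @return An [expr_matrix()] with conditions `"control"` and `"knockdown"`.
#' @export
simulate_screen <- function(model, config, regulator,
                            assay = "nanostring_like",
                            stage = utils::tail(model$stages, 1),
                            n_replicates = config$n_replicates,
                            exact = FALSE, n_background = 60L) {
  bg <- NULL
  if (n_background > 0) {
    bg_level <- with_seed(seed_salt(config$seed, "panel_background"),
                          runif(n_background))
    bg <- tibble(gene = sprintf("bg%03d", seq_len(n_background)),
                 stage = stage, activity = bg_level)
  }
  wt <- bind_rows(propagate_activities(model, config), bg)
  kd <- bind_rows(propagate_activities(model, config, knockdown = regulator), bg)
  ctrl <- simulate_counts(wt, config, assay = assay, stages = stage,
                          n_replicates = n_replicates,
                          condition = paste0(regulator, ".control"),
                          exact = exact)
  kdx <- simulate_counts(kd, config, assay = assay, stages = stage,
                         n_replicates = n_replicates,
                         condition = paste0(regulator, ".knockdown"),
                         exact = exact)
  out <- bind_expr(ctrl, kdx)
  out$meta$condition <- ifelse(grepl("\\.control$", out$meta$condition),
                               "control", "knockdown")
  attr(out, "regulator") <- regulator
  out
}

#' Simulate a wild-type stage series with a whole-embryo reference
#'
#' Alongside the network genes, the series carries a majority of stable
#' background transcripts at a spread of constant expression levels,
#' identical between the otic tissue and the whole-embryo reference. A real
#' transcriptome is dominated by such genes, and the median-of-ratios
#' normalization is only meaningful when most genes do not change; without
#' the background the normalization would absorb the enrichment signal
#' itself.
#'
#' @inheritParams simulate_screen
#' @param n_replicates Replicates per stage (1 mimics the unreplicated design
#'   the conservative no-replicate test was built for).
#' @param n_background Number of stable background transcripts (gene ids
#'   `bg001`, ...).
#' @return A list with elements `otic` and `reference`, both [expr_matrix()]
#'   objects (RNA-seq-like).
#' @export
simulate_stage_series <- function(model, config, n_replicates = 1L,
                                  exact = FALSE, n_background = 100L) {
  bg <- NULL
  if (n_background > 0) {
    bg_level <- with_seed(seed_salt(config$seed, "background"),
                          runif(n_background))
    bg <- expand_grid(gene = sprintf("bg%03d", seq_len(n_background)),
                      stage = model$stages) |>
      mutate(activity = rep(bg_level, each = length(model$stages)))
  }
  wt <- bind_rows(propagate_activities(model, config), bg)
  attr(wt, "condition") <- "wild_type"
  ref <- bind_rows(reference_activities(model, config), bg)
  attr(ref, "condition") <- "reference"
  list(
    otic = simulate_counts(wt, config, assay = "rnaseq_like",
                           n_replicates = n_replicates, condition = "otic",
                           exact = exact),
    reference = simulate_counts(ref, config, assay = "rnaseq_like",
                                n_replicates = n_replicates,
                                condition = "reference", exact = exact)
  )
}
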