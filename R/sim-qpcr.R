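#' Simulate qPCR Ct values
#'
#' Ct values are log2-linked to transcript abundance:
#' `Ct = ct_intercept - log2(mean) + Normal(0, ct_noise_sd)`, with technical
#' triplicates nested in biological replicates. Reference genes are held at
#' constant abundance (`baseline_mean * amplitude`) in every condition, as
#' expected of stable housekeeping transcripts.
#'
#' @param activities A single activity tibble or a named list of them, one per
#'   condition (e.g. `list(control = wt, knockdown = kd)`).
#' @param config The [sim_config()].
#' @param genes Target genes to assay (must be present in the activities).
#' @param reference_genes Names for the constant reference transcripts.
#' @param stage Stage at which tissue is collected (default: final stage).
#' @param bio_replicates,tech_replicates Replication structure per condition.
#' @return A tibble with columns `gene`, `condition`, `bio_rep`, `tech_rep`,
#'   `ct`.
#' @export
simulate_qpcr <- function(activities, config, genes,
                          reference_genes = c("Gapdh", "Hprt", "Rplp1"),
                          stage = NULL,
                          bio_replicates = config$qpcr_bio_replicates,
                          tech_replicates = config$qpcr_tech_replicates) {
  if (is.data.frame(activities)) {
    activities <- setNames(list(activities),
                           attr(activities, "condition") %||% "control")
  }
  mu_ref <- config$baseline_mean * config$amplitude

  rows <- imap(activities, function(act, cond) {
    stage_use <- stage %||% utils::tail(unique(act$stage), 1)
    act_s <- act |> filter(.data$stage == stage_use)
    missing <- setdiff(genes, act_s$gene)
    if (length(missing)) {
      abort(sprintf("genes absent from activities: %s",
                    paste(missing, collapse = ", ")))
    }
    a <- setNames(act_s$activity, act_s$gene)[genes]
    mu <- c(config$baseline_mean * config$amplitude^a,
            setNames(rep(mu_ref, length(reference_genes)), reference_genes))
    grid <- expand_grid(gene = names(mu),
                        bio_rep = seq_len(bio_replicates),
                        tech_rep = seq_len(tech_replicates)) |>
      mutate(condition = cond, true_ct = config$ct_intercept - log2(mu[.data$gene]))
    noise <- with_seed(
      seed_salt(config$seed, paste("qpcr", cond, stage_use, bio_replicates,
                                   tech_replicates,
                                   paste(genes, collapse = "|"))),
      rnorm(nrow(grid), 0, config$ct_noise_sd)
    )
    grid |> mutate(ct = .data$true_ct + noise) |>
      select("gene", "condition", "bio_rep", "tech_rep", "ct")
  })
  bind_rows(rows)
}
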