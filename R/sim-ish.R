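#' Simulate in situ hybridization embryo scores
#'
#' For each target gene, the number of embryos showing a visible expression
#' change after knockdown is drawn from
#' `Binomial(ish_embryos, p)`, where the per-embryo detection probability is a
#' squashed logistic in the effect size:
#' `p = 0.05 + 0.95 * (2 * logistic(ish_sensitivity * |d|) - 1)` with
#' `d = log2(mean_kd / mean_control)` under the activity-driven count model.
#' The 0.05 floor models background scoring noise in the absence of any
#' effect (control morpholinos show no effect, but scoring is not noise-free).
#'
#' @param activities Named list with `control` and `knockdown` activity
#'   tibbles (from [propagate_activities()]).
#' @param config The [sim_config()].
#' @param regulator Knocked-down regulator (recorded in the output).
#' @param genes Genes scored.
#' @param stage Stage scored (default: final stage).
#' @return Tibble with columns `regulator`, `gene`, `affected`, `total`,
#'   `direction` (`"reduced"`, `"enhanced"`).
#' @export
simulate_ish <- function(activities, config, regulator, genes, stage = NULL) {
  stopifnot(all(c("control", "knockdown") %in% names(activities)))
  check_field(config$ish_embryos >= 1, "ish_embryos", "must be >= 1")
  stage_use <- stage %||% utils::tail(unique(activities$control$stage), 1)

  get_act <- function(tab) {
    tab_s <- tab |> filter(.data$stage == stage_use)
    setNames(tab_s$activity, tab_s$gene)[genes]
  }
  a_ctrl <- get_act(activities$control)
  a_kd <- get_act(activities$knockdown)
  d <- unname(a_kd - a_ctrl) * log2(config$amplitude)  # log2 fold effect on means

  p <- 0.05 + 0.95 * (2 * plogis(config$ish_sensitivity * abs(d)) - 1)
  affected <- with_seed(
    seed_salt(config$seed, paste("ish", regulator, stage_use,
                                 paste(genes, collapse = "|"))),
    rbinom(length(genes), config$ish_embryos, p)
  )
  tibble(
    regulator = regulator,
    gene = genes,
    affected = as.integer(affected),
    total = as.integer(config$ish_embryos),
    direction = ifelse(d > 0, "enhanced", "reduced")
  )
}
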