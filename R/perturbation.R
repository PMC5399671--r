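#' Negative-binomial panel test for a knockdown screen
#'
#' Compares knockdown against control counts on a fixed gene panel. Samples
#' are normalized with median-of-ratios size factors across all samples; the
#' expressed-count filter (strict mean normalized count > `count_min`) is
#' applied before testing so that BH correction runs over tested genes only.
#' Gene-wise negative-binomial dispersions are moment-estimated from the
#' pooled within-condition variances and shrunk 50/50 toward a parametric
#' mean-variance trend fitted across the panel; the condition effect is
#' assessed with a Wald test on the log2 fold change (delta-method standard
#' error, t reference with `n1 + n2 - 2` degrees of freedom to stay
#' calibrated at triplicate scale). A gene is called `down`/`up` when it passes the count filter,
#' `|log2FC| > log2(fold_min)` strictly, and `p_adj < p_adj_max` strictly.
#'
#' @param x An [expr_matrix()] with conditions `"control"` and `"knockdown"`,
#'   at least two replicates each.
#' @param count_min Mean normalized count filter (default 300, strict).
#' @param fold_min Fold-change threshold (default 1.2).
#' @param p_adj_max BH-adjusted p-value threshold (default 0.1, strict).
#' @param pseudocount Pseudocount for the log fold change (default 0: tested
#'   genes sit far above zero counts, and a zero pseudocount keeps boundary
#'   fold changes exact).
#' @return Tibble: `gene`, `base_mean`, `log2_fc`, `dispersion`, `p_value`,
#'   `p_adj`, `tested`, `call` in `{"down", "up", "none"}`.
#' @export
nanostring_test <- function(x, count_min = 300, fold_min = 1.2,
                            p_adj_max = 0.1, pseudocount = 0) {
  stopifnot(inherits(x, "otog_expr"))
  ctrl_s <- x$meta$sample_id[x$meta$condition == "control"]
  kd_s <- x$meta$sample_id[x$meta$condition == "knockdown"]
  if (length(ctrl_s) < 2 || length(kd_s) < 2) {
    abort("need at least 2 replicates in each of control and knockdown")
  }
  nm <- normalized_values(x)
  mc <- rowMeans(nm[, ctrl_s, drop = FALSE])
  mk <- rowMeans(nm[, kd_s, drop = FALSE])
  vc <- apply(nm[, ctrl_s, drop = FALSE], 1, var)
  vk <- apply(nm[, kd_s, drop = FALSE], 1, var)
  n_c <- length(ctrl_s)
  n_k <- length(kd_s)

  base_mean <- rowMeans(nm)
  pooled_var <- (vc * (n_c - 1) + vk * (n_k - 1)) / (n_c + n_k - 2)

  # moment dispersion per gene, floored at 0
  disp_gene <- pmax(0, (pooled_var - base_mean) / base_mean^2)
  # parametric trend v = m + alpha m^2 across the panel
  keep <- base_mean > 0
  alpha_trend <- max(0, sum((pooled_var[keep] - base_mean[keep]) * base_mean[keep]^2) /
                       sum(base_mean[keep]^4))
  disp <- 0.5 * disp_gene + 0.5 * alpha_trend

  log2_fc <- log2((mk + pseudocount) / (mc + pseudocount))
  var_log <- function(m, n) ifelse(m > 0, (m + disp * m^2) / (n * m^2), Inf)
  se <- sqrt(var_log(mc, n_c) + var_log(mk, n_k)) / log(2)
  z <- ifelse(is.finite(se) & se > 0, log2_fc / se, 0)

  tested <- base_mean > count_min
  # t reference with the residual df: the dispersion entering the Wald
  # statistic is estimated from n_c + n_k - 2 residual degrees of freedom,
  # and a normal reference is badly anti-conservative at triplicate scale
  p <- ifelse(tested, 2 * stats::pt(-abs(z), df = n_c + n_k - 2), NA_real_)
  p_adj <- bh_adjust(p)

  call <- rep("none", nrow(nm))
  hit <- tested & abs(log2_fc) > log2(fold_min) & !is.na(p_adj) & p_adj < p_adj_max
  call[hit & log2_fc < 0] <- "down"
  call[hit & log2_fc > 0] <- "up"

  tibble(gene = rownames(nm), base_mean = unname(base_mean),
         log2_fc = unname(log2_fc), dispersion = unname(disp),
         p_value = unname(p), p_adj = unname(p_adj),
         tested = unname(tested), call = call)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Technical replicates are averaged first; per biological replicate,
#' `dCt = Ct_gene - mean(Ct of reference genes)`; then
#' `ddCt = mean(dCt knockdown) - mean(dCt control)` and `FC = 2^(-ddCt)`.
#' Significance is a two-tailed Student's t-test (pooled variance) on the
#' per-replicate dCt values. A gene is called when `FC >= fold_min` or
#' `FC <= 1/fold_min` and `p < p_max` strictly. Adding a constant to every Ct
#' leaves ddCt (hence FC) unchanged.
#'
#' @param ct Tibble with columns `gene`, `condition`, `bio_rep`, `tech_rep`,
#'   `ct` (conditions `"control"` and `"knockdown"`).
#' @param genes Target genes (default: every non-reference gene present).
#' @param reference_genes Reference gene ids, all must be present.
#' @param fold_min Fold-change threshold (default 1.5, inclusive).
#' @param p_max P-value threshold (default 0.05, strict).
#' @return Tibble: `gene`, `ddct`, `fold_change`, `p_value`, `call`.
#' @export
qpcr_test <- function(ct, genes = NULL,
                      reference_genes = c("Gapdh", "Hprt", "Rplp1"),
                      fold_min = 1.5, p_max = 0.05) {
  ct <- as_tibble(ct)
  missing_ref <- setdiff(reference_genes, unique(ct$gene))
  if (length(missing_ref)) {
    abort(sprintf("missing reference gene(s): %s",
                  paste(missing_ref, collapse = ", ")))
  }
  genes <- genes %||% setdiff(unique(ct$gene), reference_genes)

  bio <- ct |>
    summarise(ct = mean(.data$ct), .by = c("gene", "condition", "bio_rep"))
  refs <- bio |>
    filter(.data$gene %in% reference_genes) |>
    summarise(ref_ct = mean(.data$ct), .by = c("condition", "bio_rep"))
  dct <- bio |>
    filter(.data$gene %in% genes) |>
    left_join(refs, by = c("condition", "bio_rep")) |>
    mutate(dct = .data$ct - .data$ref_ct)

  reps_per_cond <- dct |> distinct(.data$condition, .data$bio_rep) |> count(.data$condition)
  if (any(reps_per_cond$n < 2) || nrow(reps_per_cond) < 2) {
    abort("need >= 2 biological replicates in each condition")
  }

  rows <- lapply(genes, function(g) {
    d <- dct |> filter(.data$gene == g)
    d_c <- d$dct[d$condition == "control"]
    d_k <- d$dct[d$condition == "knockdown"]
    ddct <- mean(d_k) - mean(d_c)
    fc <- 2^(-ddct)
    p <- if (sd(c(d_c - mean(d_c), d_k - mean(d_k))) == 0) {
      # degenerate noise-free replicates: exact equality or certainty
      if (isTRUE(all.equal(mean(d_c), mean(d_k)))) 1 else 0
    } else {
      t.test(d_k, d_c, var.equal = TRUE)$p.value
    }
    call <- if ((fc >= fold_min || fc <= 1 / fold_min) && p < p_max) {
      if (fc < 1) "down" else "up"
    } else "none"
    tibble(gene = g, ddct = ddct, fold_change = fc, p_value = p, call = call)
  })
  bind_rows(rows)
}

#' Call in situ hybridization outcomes from embryo scores
#'
#' The qualitative scoring used for whole-mount in situ read-outs is reduced
#' to a numeric rule induced from the reported fractions: a change is called
#' in the observed direction when at least `min_n` embryos were scored and a
#' strict majority (`affected/total > min_fraction`) shows the change.
#'
#' @param affected,total Integer vectors of affected and scored embryos.
#' @param direction Observed direction per experiment: `"reduced"`,
#'   `"enhanced"` or `"none"`.
#' @param min_n Minimum embryos scored (default 4).
#' @param min_fraction Strict lower bound on the affected fraction (default 0.5).
#' @return Tibble: `affected`, `total`, `direction`, `call`.
#' @examples
#' ish_call(8, 12, "reduced")   # down
#' ish_call(2, 6, "reduced")    # none
#' @export
ish_call <- function(affected, total, direction, min_n = 4,
                     min_fraction = 0.5) {
  if (any(total < 1)) abort("total embryos must be >= 1")
  if (any(affected > total)) abort("affected cannot exceed total")
  if (any(affected < 0)) abort("affected must be nonnegative")
  ok <- total >= min_n & affected / total > min_fraction
  call <- rep("none", length(affected))
  call[ok & direction == "reduced"] <- "down"
  call[ok & direction == "enhanced"] <- "up"
  tibble(affected = as.integer(affected), total = as.integer(total),
         direction = direction, call = call)
}

#' Integrate evidence across assay modalities
#'
#' Combines per-target calls from the count panel, qPCR and in situ
#' hybridization into one regulatory call per (regulator, target) pair:
#'
#' * all present modalities agree: that call;
#' * in situ hybridization detected a change: its call (conflict flagged if
#'   any other modality disagrees) — spatially resolved evidence takes
#'   precedence;
#' * otherwise, if at least two modalities agree on the same result
#'   ("no change" counts as a result): that call, conflict flagged when a
#'   third disagrees;
#' * otherwise unresolved.
#'
#' A single-modality result stands on its own. `down` after knockdown maps to
#' `activated` (the regulator was required), `up` to `repressed`.
#'
#' @param calls Tibble with columns `regulator`, `target`, `modality`
#'   (`"nanostring"`, `"qpcr"`, `"ish"`), `call` (`"down"`, `"up"`, `"none"`).
#' @return Tibble: `regulator`, `target`, `integrated`
#'   (`activated`/`repressed`/`none`/`unresolved`), `modalities`, `conflict`.
#' @export
integrate_evidence <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) abort("at least one modality result is required")
  dup <- calls |> count(.data$regulator, .data$target, .data$modality) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate modality results for pair(s): %s",
                  paste(dup$regulator, dup$target, sep = "->", collapse = ", ")))
  }

  integrate_one <- function(modality, call) {
    if (length(unique(call)) == 1) {
      return(list(res = call[1], conflict = FALSE))
    }
    ish <- call[modality == "ish"]
    if (length(ish) == 1 && ish != "none") {
      return(list(res = ish, conflict = TRUE))
    }
    tab <- sort(table(call), decreasing = TRUE)
    if (tab[1] >= 2) {
      return(list(res = names(tab)[1], conflict = TRUE))
    }
    list(res = "unresolved", conflict = TRUE)
  }

  calls |>
    summarise(
      out = list(integrate_one(.data$modality, .data$call)),
      modalities = paste(sort(.data$modality), collapse = ";"),
      .by = c("regulator", "target")
    ) |>
    mutate(
      raw = map_chr(.data$out, "res"),
      conflict = map_lgl(.data$out, "conflict"),
      integrated = case_when(
        raw == "down" ~ "activated",
        raw == "up" ~ "repressed",
        raw == "none" ~ "none",
        .default = "unresolved"
      )
    ) |>
    select("regulator", "target", "integrated", "modalities", "conflict")
}
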