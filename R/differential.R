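#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's factor is the median, over
#' genes with an all-positive geometric mean, of the ratio of that sample's
#' count to the gene's geometric mean across samples. Doubling every count in
#' a sample exactly doubles its factor.
#'
#' @param x An [expr_matrix()] of counts (or a gene-by-sample tibble whose
#'   first column is `gene`).
#' @return Named numeric vector of strictly positive factors, one per sample.
#' @examples
#' m <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 20), s2 = c(20, 40))
#' size_factors(m)
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "otog_expr")) expr_values(x) else {
    d <- as_tibble(x)
    mm <- as.matrix(d[, -1])
    rownames(mm) <- d[[1]]
    mm
  }
  if (ncol(m) < 2) abort("size factors need at least 2 samples")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider adding a pseudocount before normalization"))
  }
  log_geo <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  setNames(sf, colnames(m))
}

# size-factor-normalized value matrix; rpkm input is left untouched
normalized_values <- function(x) {
  m <- expr_values(x)
  if (x$value_kind == "rpkm") return(m)
  sf <- size_factors(x)
  sweep(m, 2, sf, "/")
}

#' Fold changes between two sample groups
#'
#' Group means are computed on size-factor-normalized values; the fold change
#' is `(mean_test + pc) / (mean_baseline + pc)` with pseudocount `pc`
#' (default 1 on the normalized count scale) so it is bounded and defined for
#' silent genes.
#'
#' @param x An [expr_matrix()].
#' @param test,baseline Sample groups: either vectors of sample ids or single
#'   labels matched against the metadata `stage` (then `condition`) columns.
#' @param pseudocount Nonnegative pseudocount (default 1).
#' @return Tibble: `gene`, `mean_baseline`, `mean_test`, `fold_change`,
#'   `log2_fc`, plus attributes `test` and `baseline`.
#' @export
fold_changes <- function(x, test, baseline, pseudocount = 1) {
  stopifnot(inherits(x, "otog_expr"))
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  resolve <- function(g) {
    if (all(g %in% x$meta$sample_id)) return(g)
    hit <- x$meta$sample_id[x$meta$stage %in% g]
    if (!length(hit)) hit <- x$meta$sample_id[x$meta$condition %in% g]
    if (!length(hit)) abort(sprintf("group `%s` matches no samples", paste(g, collapse = ",")))
    hit
  }
  test_s <- resolve(test)
  base_s <- resolve(baseline)
  if (!length(test_s) || !length(base_s)) abort("both groups must be nonempty")
  if (length(intersect(test_s, base_s))) abort("test and baseline groups overlap")

  nm <- normalized_values(x)
  mt <- rowMeans(nm[, test_s, drop = FALSE])
  mb <- rowMeans(nm[, base_s, drop = FALSE])
  fc <- (mt + pseudocount) / (mb + pseudocount)
  out <- tibble(gene = rownames(nm), mean_baseline = unname(mb),
                mean_test = unname(mt), fold_change = unname(fc),
                log2_fc = log2(unname(fc)))
  attr(out, "test") <- test_s
  attr(out, "baseline") <- base_s
  out
}

#' Expressed-gene calls for RNA-seq-like data
#'
#' A gene counts as expressed in the otic tissue when its RPKM exceeds 4 AND
#' its normalized count exceeds 300 — both strict inequalities, so values at
#' the boundary are not expressed. The count cut-off is empirical: transcripts
#' absent or weak in the tissue sit below ~300 normalized counts.
#'
#' @param stats Tibble with columns `gene`, `rpkm`, `count` (mean normalized
#'   count).
#' @param rpkm_min,count_min Thresholds (defaults 4 and 300).
#' @return `stats` with a logical `expressed` column appended.
#' @export
call_expressed <- function(stats, rpkm_min = 4, count_min = 300) {
  stats <- as_tibble(stats)
  missing <- setdiff(c("rpkm", "count"), names(stats))
  if (length(missing)) {
    abort(sprintf("missing statistic column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(stats$rpkm) || anyNA(stats$count)) {
    abort("expressed calls require both rpkm and count for every gene")
  }
  stats |> mutate(expressed = .data$rpkm > rpkm_min & .data$count > count_min)
}

#' Enrichment calls from a stage comparison
#'
#' A gene is enriched when it is expressed AND its fold change strictly
#' exceeds the threshold (default 1.5); direction is `up` above the threshold,
#' `down` below its reciprocal, `none` otherwise. Raising the threshold never
#' adds genes.
#'
#' @param comparison Output of [fold_changes()].
#' @param expressed Either a logical vector aligned with `comparison`, or a
#'   tibble with columns `gene`, `expressed` (e.g. from [call_expressed()]).
#' @param fc_threshold Fold-change threshold, must be > 1.
#' @param stage Optional stage label stamped on the calls.
#' @return Tibble: `gene`, `stage`, `fold_change`, `expressed`, `enriched`,
#'   `direction`.
#' @export
call_enriched <- function(comparison, expressed, fc_threshold = 1.5,
                          stage = NA_character_) {
  if (fc_threshold <= 1) abort("fc_threshold must be > 1")
  comparison <- as_tibble(comparison)
  if (is.data.frame(expressed)) {
    expressed <- expressed$expressed[match(comparison$gene, expressed$gene)]
  }
  stopifnot(length(expressed) == nrow(comparison))
  fc <- comparison$fold_change
  tibble(
    gene = comparison$gene,
    stage = stage,
    fold_change = fc,
    expressed = expressed,
    enriched = expressed & fc > fc_threshold,
    direction = case_when(
      fc > fc_threshold ~ "up",
      fc < 1 / fc_threshold ~ "down",
      .default = "none"
    )
  )
}
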