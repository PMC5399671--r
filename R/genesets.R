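#' Venn partition of enrichment calls across stages
#'
#' Partitions the union of k gene sets into the 2^k - 1 disjoint membership
#' regions of the k-set Venn diagram (e.g. enriched at 5-6ss only, at 5-6ss
#' and 8-9ss but not 11-12ss, ...). Region counts always sum to the size of
#' the union.
#'
#' @param sets Named list of k >= 2 character vectors (gene sets per stage).
#' @return Tibble with one logical membership column per set plus `n`, one
#'   row per region (all 2^k - 1 regions, including empty ones).
#' @examples
#' stage_intersections(list(a = c("x", "y"), b = c("y", "z")))
#' @export
stage_intersections <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- expand_grid(!!!setNames(rep(list(c(TRUE, FALSE)), length(sets)),
                                      names(sets))) |>
    filter(rowSums(across(everything())) > 0)
  patterns$n <- vapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, names(sets)])
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(row) all(row == pat)))
  }, integer(1))
  patterns
}

#' Gene-set over/under-representation (one-sided Fisher tests)
#'
#' For each named gene set, tests whether the selection over- or
#' under-represents it relative to the universe, using one-sided Fisher exact
#' (hypergeometric) tails; the direction with the smaller p-value is
#' reported and BH correction is applied across sets. Sets are intersected
#' with the universe first.
#'
#' @param selection Character vector of selected genes (subset of universe).
#' @param universe Character vector, the background.
#' @param gene_sets Named list of character vectors.
#' @return Tibble: `set`, `k` (overlap), `K` (set size in universe),
#'   `n` (selection size), `N` (universe size), `direction`
#'   (`"enrichment"`/`"depletion"`), `p_value`, `p_enrichment`,
#'   `p_depletion`, `p_adj`.
#' @export
geneset_overrepresentation <- function(selection, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe must be nonempty")
  selection <- unique(selection)
  if (!all(selection %in% universe)) {
    abort("selection must be a subset of the universe")
  }
  n <- length(selection)
  N <- length(universe)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  in_universe <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  K <- vapply(in_universe, length, integer(1))
  k <- vapply(in_universe, function(s) sum(s %in% selection), integer(1))
  # one-sided hypergeometric tails (equivalent to one-sided Fisher exact)
  p_enr <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_dep <- phyper(k, K, N - K, n, lower.tail = TRUE)
  tibble(
    set = names(gene_sets), k = unname(k), K = unname(K), n = n, N = N,
    direction = unname(ifelse(p_enr <= p_dep, "enrichment", "depletion")),
    p_value = unname(pmin(p_enr, p_dep)),
    p_enrichment = unname(p_enr), p_depletion = unname(p_dep),
    p_adj = unname(p.adjust(pmin(p_enr, p_dep), method = "BH"))
  )
}
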