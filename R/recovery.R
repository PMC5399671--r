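#' Score recovery of an inferred network against the ground truth
#'
#' Precision and recall are computed over directed edges ignoring sign;
#' sign accuracy over the correctly recovered edges only. An edge flagged
#' `removed_by_parsimony` during transitive reduction still counts as correct
#' when it matches a truth edge (the reduction withdrew it only as redundant),
#' while displayed edges that exist only as indirect chains in the truth are
#' false positives.
#'
#' @param inferred An `otog_network`, or an edge tibble with columns
#'   `source`, `target`, `sign` (and optionally `removed_by_parsimony`).
#' @param truth An `otog_truth` model (or edge tibble).
#' @return One-row tibble: `edge_precision`, `edge_recall`, `sign_accuracy`
#'   (NA when undefined, with `precision_defined` flag), plus TP/FP/FN counts.
#' @examples
#' truth <- truth_model(
#'   tibble::tibble(gene = c("a", "b"), tier = 1:2,
#'                  stage_of_onset = c("0ss", "5-6ss")),
#'   tibble::tibble(source = "a", target = "b", sign = 1)
#' )
#' score_recovery(tidy(truth), truth)
#' @export
score_recovery <- function(inferred, truth) {
  truth_edges <- if (inherits(truth, "otog_truth")) truth$edges else as_tibble(truth)
  if (nrow(truth_edges) == 0) abort("truth network has no edges; recovery is undefined")

  inf_edges <- if (inherits(inferred, "otog_network")) inferred$edges else as_tibble(inferred)
  if (!"removed_by_parsimony" %in% names(inf_edges)) {
    inf_edges$removed_by_parsimony <- FALSE
  }
  if (nrow(inf_edges)) {
    genes_overlap <- length(intersect(
      unique(c(inf_edges$source, inf_edges$target)),
      unique(c(truth_edges$source, truth_edges$target))))
    if (genes_overlap == 0) {
      warn("inferred and truth gene universes do not overlap")
    }
  }

  key <- function(d) paste(d$source, d$target, sep = "\r")
  truth_key <- key(truth_edges)
  displayed <- inf_edges[!inf_edges$removed_by_parsimony, ]
  removed_true <- inf_edges[inf_edges$removed_by_parsimony &
                              key(inf_edges) %in% truth_key, ]
  scored <- bind_rows(displayed, removed_true) |>
    distinct(.data$source, .data$target, .keep_all = TRUE)

  tp_idx <- key(scored) %in% truth_key
  tp <- sum(tp_idx)
  fp <- sum(!tp_idx)
  fn <- nrow(truth_edges) - tp

  sign_acc <- NA_real_
  if (tp > 0) {
    truth_sign <- setNames(truth_edges$sign, truth_key)
    matched <- scored[tp_idx, ]
    sign_acc <- mean(matched$sign == truth_sign[key(matched)])
  }

  tibble(
    edge_precision = if (nrow(scored)) tp / nrow(scored) else NA_real_,
    precision_defined = nrow(scored) > 0,
    edge_recall = tp / nrow(truth_edges),
    sign_accuracy = sign_acc,
    n_true_edges = nrow(truth_edges),
    n_inferred = nrow(scored),
    true_positives = tp,
    false_positives = fp,
    false_negatives = fn
  )
}
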