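#' Row z-score temporal profiles
#'
#' Standardizes each gene's fold-change profile across stages to mean 0 and
#' unit sample standard deviation (n-1 denominator). Rows with zero variance
#' cannot be standardized; they are returned as all-zero and flagged.
#'
#' @param profiles Tibble: `gene` column plus one numeric column per stage
#'   (fold changes relative to the earliest-stage reference), in stage order.
#' @return Tibble of the same shape with z-values plus a logical
#'   `zero_variance` column; stage order kept as an attribute.
#' @examples
#' zscore_profiles(tibble::tibble(gene = "g", s1 = 1, s2 = 2, s3 = 3))
#' @export
zscore_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  stage_cols <- setdiff(names(profiles), "gene")
  if (length(stage_cols) < 2) abort("need at least 2 stages per gene")
  m <- as.matrix(profiles[, stage_cols])
  bad <- !complete.cases(m) | apply(m, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    abort(sprintf("non-finite profile values for genes: %s",
                  paste(profiles$gene[bad], collapse = ", ")))
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  zero_var <- s == 0
  z <- (m - mu) / ifelse(zero_var, 1, s)
  z[zero_var, ] <- 0
  out <- bind_cols(tibble(gene = profiles$gene), as_tibble(z)) |>
    mutate(zero_variance = zero_var)
  attr(out, "stages") <- stage_cols
  out
}

#' Hierarchical partition of temporal profiles
#'
#' Agglomerative clustering of row z-scored profiles, cut into exactly `k`
#' groups. Cluster labels are renumbered canonically by the stage at which
#' each cluster's mean trajectory peaks (ties broken by the alphabetically
#' first member gene), so the labelling is reproducible and invariant to the
#' row order of the input.
#'
#' @param z Output of [zscore_profiles()] (or a `gene` + stage-column tibble).
#' @param k Number of clusters, at most the number of genes.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return An object of class `otog_clusters`: assignment tibble plus cluster
#'   mean trajectories; see [tidy.otog_clusters()].
#' @export
hierarchical_partition <- function(z, k,
                                   metric = c("euclidean", "correlation"),
                                   linkage = c("complete", "average", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  z <- as_tibble(z)
  stage_cols <- attr(z, "stages") %||% setdiff(names(z), c("gene", "zero_variance"))
  m <- as.matrix(z[, stage_cols])
  rownames(m) <- z$gene
  if (k > nrow(m)) abort(sprintf("k = %d exceeds the %d genes", k, nrow(m)))

  # sort rows by gene id so dendrogram tie-breaking is input-order invariant
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]

  d <- if (metric == "euclidean") dist(m) else as.dist(1 - cor(t(m)))
  method <- c(complete = "complete", average = "average", ward = "ward.D2")[linkage]
  labels_raw <- cutree(hclust(d, method = method), k = k)

  # canonical renumbering by mean-trajectory peak stage
  traj <- t(vapply(seq_len(k), function(cl) {
    colMeans(m[labels_raw == cl, , drop = FALSE])
  }, numeric(ncol(m))))
  peak <- apply(traj, 1, which.max)
  first_gene <- vapply(seq_len(k), function(cl) min(rownames(m)[labels_raw == cl]),
                       character(1))
  new_order <- order(peak, first_gene)
  relabel <- match(seq_len(k), new_order)
  labels <- relabel[labels_raw]

  assignment <- tibble(gene = rownames(m), cluster = labels) |>
    arrange(.data$gene)
  trajectories <- bind_cols(
    tibble(cluster = seq_len(k)),
    as_tibble(traj[new_order, , drop = FALSE])
  )
  names(trajectories)[-1] <- stage_cols

  structure(list(assignment = assignment, trajectories = trajectories,
                 k = k, metric = metric, linkage = linkage,
                 stages = stage_cols),
            class = "otog_clusters")
}

#' @export
print.otog_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat(sprintf("<otog_clusters> k = %d (%s/%s); sizes: %s\n",
              x$k, x$metric, x$linkage,
              paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}

#' Tidiers for cluster partitions
#'
#' @param x An `otog_clusters` object.
#' @param ... Unused.
#' @return `tidy()`: the gene-to-cluster assignment; `glance()`: one row of
#'   partition-level summaries.
#' @export
tidy.otog_clusters <- function(x, ...) x$assignment

#' @rdname tidy.otog_clusters
#' @export
glance.otog_clusters <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignment),
         metric = x$metric, linkage = x$linkage,
         min_size = min(table(x$assignment$cluster)),
         max_size = max(table(x$assignment$cluster)))
}

#' Mean trajectory of the top-expressed cluster members
#'
#' Within each cluster, genes are ranked by mean expression across stages;
#' the top `ceil(top_fraction * n)` genes are kept and their stage profiles
#' averaged — the summary used to display cluster expression profiles.
#'
#' @param clusters An `otog_clusters` object (or assignment tibble with
#'   `gene`, `cluster`).
#' @param levels Tibble: `gene` plus one numeric expression column per stage.
#' @param top_fraction Fraction of members kept, in (0, 1].
#' @return Tibble: `cluster`, `n_used`, one column per stage.
#' @export
cluster_profiles <- function(clusters, levels, top_fraction = 0.5) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("top_fraction must be in (0, 1]")
  }
  assignment <- if (inherits(clusters, "otog_clusters")) clusters$assignment else as_tibble(clusters)
  levels <- as_tibble(levels)
  stage_cols <- setdiff(names(levels), "gene")
  rows <- lapply(sort(unique(assignment$cluster)), function(cl) {
    members <- assignment$gene[assignment$cluster == cl]
    sub <- levels[levels$gene %in% members, ]
    if (nrow(sub) == 0) abort(sprintf("cluster %s has no expression data", cl))
    mean_expr <- rowMeans(as.matrix(sub[, stage_cols]))
    n_keep <- ceiling(top_fraction * nrow(sub))
    top <- sub[order(-mean_expr, sub$gene)[seq_len(n_keep)], ]
    bind_cols(tibble(cluster = cl, n_used = n_keep),
              as_tibble(t(colMeans(as.matrix(top[, stage_cols])))))
  })
  bind_rows(rows)
}

#' Plot cluster mean trajectories
#'
#' @param object An `otog_clusters` object.
#' @param ... Unused.
#' @return A ggplot: one line per cluster across stages.
#' @export
autoplot.otog_clusters <- function(object, ...) {
  long <- object$trajectories |>
    pivot_longer(-"cluster", names_to = "stage", values_to = "z") |>
    mutate(stage = factor(.data$stage, levels = object$stages),
           cluster = factor(.data$cluster))
  ggplot(long, aes(x = .data$stage, y = .data$z,
                   colour = .data$cluster, group = .data$cluster)) +
    geom_line() + geom_point() +
    labs(x = "stage", y = "mean row z-score", colour = "cluster") +
    theme_minimal()
}
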