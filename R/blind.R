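#' Conservative no-replicate ("blind") variance test
#'
#' For a comparison of exactly two unreplicated samples, the two samples are
#' pooled as pseudo-replicates to fit a negative-binomial mean-variance trend
#' `v(m) = m + alpha * m^2` across genes (alpha by least squares of the
#' pairwise sample variance minus the mean on the squared mean, floored at 0).
#' Each gene's two normalized counts are then tested two-sidedly against a
#' common mean using that trend variance. Because the between-condition
#' difference inflates the fitted variance whenever real changes exist, the
#' test is deliberately conservative and calls few genes — the price of
#' having no biological replicates.
#'
#' @param x An [expr_matrix()] restricted to exactly two samples.
#' @return Tibble: `gene`, `base_mean`, `log2_fc`, `p_value`, `p_adj` (BH),
#'   with the fitted `alpha` as an attribute.
#' @export
blind_variance_test <- function(x) {
  stopifnot(inherits(x, "otog_expr"))
  m <- expr_values(x)
  if (ncol(m) != 2) {
    abort(sprintf("blind test requires exactly 2 samples, got %d", ncol(m)))
  }
  nm <- normalized_values(x)
  mean_g <- rowMeans(nm)
  var_g <- (nm[, 1] - nm[, 2])^2 / 2  # n-1 denominator with two points

  # trend fit: (var - mean) ~ mean^2 through the origin, alpha floored at 0
  keep <- mean_g > 0
  alpha <- max(0, sum((var_g[keep] - mean_g[keep]) * mean_g[keep]^2) /
                 sum(mean_g[keep]^4))

  v <- mean_g + alpha * mean_g^2
  z <- ifelse(v > 0, (nm[, 1] - nm[, 2]) / sqrt(2 * v), 0)
  p <- 2 * pnorm(-abs(z))
  out <- tibble(
    gene = rownames(nm),
    base_mean = unname(mean_g),
    log2_fc = log2((nm[, 2] + 1) / (nm[, 1] + 1)),
    p_value = unname(p),
    p_adj = p.adjust(p, method = "BH")
  )
  attr(out, "alpha") <- alpha
  out
}
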