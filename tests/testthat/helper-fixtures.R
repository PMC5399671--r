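# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 9, ...)
}

# linear chain a -> b -> c, one gene per tier
chain_model <- function(stages = c("0ss", "5-6ss", "8-9ss", "11-12ss")) {
  truth_model(
    tibble::tibble(gene = c("a", "b", "c"), tier = 1:3,
                   stage_of_onset = stages[1:3], gate = "AND"),
    tibble::tibble(source = c("a", "b"), target = c("b", "c"), sign = 1L),
    stages = stages
  )
}

# zero-edge truth over n tier-1 genes (null-screen calibration)
null_model <- function(n = 30, stages = c("0ss", "5-6ss", "8-9ss", "11-12ss")) {
  truth_model(
    tibble::tibble(gene = sprintf("g%02d", seq_len(n)), tier = 1L,
                   stage_of_onset = stages[1], gate = "AND"),
    NULL, NULL, stages = stages
  )
}

# hand-built expression matrix from a plain count matrix
expr_from_matrix <- function(m, stage = "0ss", condition = "control",
                             value_kind = "counts") {
  genes <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  samples <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  values <- dplyr::bind_cols(tibble::tibble(gene = genes),
                             tibble::as_tibble(`colnames<-`(m, samples)))
  meta <- tibble::tibble(sample_id = samples,
                         stage = rep_len(stage, ncol(m)),
                         condition = rep_len(condition, ncol(m)),
                         replicate = seq_len(ncol(m)))
  expr_matrix(values, meta, value_kind = value_kind)
}

# control/knockdown count panel from two plain matrices
make_panel <- function(ctrl, kd) {
  m <- cbind(ctrl, kd)
  colnames(m) <- c(paste0("c", seq_len(ncol(ctrl))), paste0("k", seq_len(ncol(kd))))
  genes <- rownames(ctrl) %||% paste0("g", seq_len(nrow(ctrl)))
  rownames(m) <- genes
  values <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
  meta <- tibble::tibble(
    sample_id = colnames(m), stage = "11-12ss",
    condition = rep(c("control", "knockdown"), c(ncol(ctrl), ncol(kd))),
    replicate = c(seq_len(ncol(ctrl)), seq_len(ncol(kd))))
  expr_matrix(values, meta)
}

# qPCR fixture: one target gene plus three references; the knockdown
# condition shifts the target's Ct by `ddct_shift` cycles
make_ct <- function(ddct_shift = 0, noise = 0, bio = 3) {
  grid <- tidyr::expand_grid(
    gene = c("t", "Gapdh", "Hprt", "Rplp1"),
    condition = c("control", "knockdown"),
    bio_rep = seq_len(bio), tech_rep = 1:3)
  base_ct <- c(t = 24, Gapdh = 20, Hprt = 22, Rplp1 = 21)
  withr::with_seed(101, {
    grid |>
      dplyr::mutate(ct = base_ct[gene] +
                      ifelse(gene == "t" & condition == "knockdown",
                             ddct_shift, 0) +
                      rnorm(dplyr::n(), 0, noise))
  })
}

# two planted trajectory archetypes (falling = truth 1, rising = truth 2)
planted_profiles <- function(seed, n_per = 10, noise_sd = 0.1) {
  withr::with_seed(seed, {
    rising <- c(1, 2, 3)
    falling <- c(3, 2, 1)
    tibble::tibble(
      gene = sprintf("g%02d", 1:(2 * n_per)),
      truth = rep(c(1L, 2L), each = n_per)
    ) |>
      dplyr::mutate(
        a = rep(c(falling[1], rising[1]), each = n_per) + rnorm(2 * n_per, 0, noise_sd),
        b = rep(c(falling[2], rising[2]), each = n_per) + rnorm(2 * n_per, 0, noise_sd),
        c = rep(c(falling[3], rising[3]), each = n_per) + rnorm(2 * n_per, 0, noise_sd)
      )
  })
}

# ---- independent graph oracles -------------------------------------------

# boolean reachability closure by repeated matrix multiplication
closure_bool <- function(adj) {
  n <- nrow(adj)
  r <- (adj | diag(n)) * 1
  repeat {
    r2 <- ((r %*% r) > 0) * 1
    if (identical(r2, r)) break
    r <- r2
  }
  r > 0
}

# greedy-deletion minimal equivalent graph; unique for DAGs, so an
# independent oracle for the transitive reduction
oracle_meg <- function(adj) {
  target <- closure_bool(adj)
  cur <- adj
  idx <- which(adj > 0)
  for (e in idx) {
    trial <- cur
    trial[e] <- 0
    if (identical(closure_bool(trial), target)) cur <- trial
  }
  cur
}

# all DAG adjacency matrices on n nodes with topological order 1 < ... < n
enumerate_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(bits) {
    adj <- matrix(0, n, n)
    on <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
    adj[pairs[on, , drop = FALSE]] <- 1
    adj
  })
}

adj_to_edges <- function(adj) {
  idx <- which(adj > 0, arr.ind = TRUE)
  tibble::tibble(source = paste0("n", idx[, 1]),
                 target = paste0("n", idx[, 2]), sign = 1L)
}

edges_to_adj <- function(edges, n) {
  adj <- matrix(0, n, n)
  if (nrow(edges)) {
    adj[cbind(as.integer(sub("n", "", edges$source)),
              as.integer(sub("n", "", edges$target)))] <- 1
  }
  adj
}
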