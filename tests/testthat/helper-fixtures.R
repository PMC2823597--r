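# Shared fixture builders; everything is generated in code at test time.

# Down-scaled array design: 15 genes spanning all oligo multiplicities,
# 8 features per gene.
small_design <- function() {
  make_design(cbind(n_genes = c(6L, 2L, 6L, 1L),
                    n_oligos = c(2L, 3L, 4L, 1L)),
              features_per_gene = 8L)
}

small_config <- function(seed = 1L, n_arrays_per_group = 3L, ...) {
  simulation_config(design = small_design(),
                    n_arrays_per_group = n_arrays_per_group,
                    seed = seed, ...)
}

# Minimal hand-built feature table: n experimental features on one gene
# per probe, plus optionally one control row.
toy_table <- function(array_id = "a1", probe = "p1", gene = "g1",
                      mean_signal = c(10, 20, 30), bgsub = mean_signal - 5,
                      detected = rep(1L, length(mean_signal)),
                      with_control = FALSE) {
  n <- length(mean_signal)
  df <- data.frame(probe_id = rep(probe, length.out = n),
                   gene_id = rep(gene, length.out = n),
                   mean_signal = mean_signal,
                   bgsub_signal = bgsub,
                   control_type = 0L,
                   is_gene_detected = detected,
                   row = seq_len(n), col = rep(1L, n))
  if (with_control)
    df <- rbind(df, data.frame(probe_id = "NC_probe", gene_id = "NegativeControl_1",
                               mean_signal = 5, bgsub_signal = 0,
                               control_type = -1L, is_gene_detected = 0L,
                               row = n + 1L, col = 1L))
  feature_table(array_id, df)
}

# A two-array toy experiment over explicit per-feature values.
# `values` is a feature x array matrix; probes/genes are parallel vectors.
toy_experiment <- function(values, probes, genes,
                           detected = NULL) {
  stopifnot(nrow(values) == length(probes))
  if (is.null(detected))
    detected <- matrix(1L, nrow(values), ncol(values))
  lapply(seq_len(ncol(values)), function(j) {
    feature_table(paste0("arr", j), data.frame(
      probe_id = probes, gene_id = genes,
      mean_signal = abs(values[, j]) + 100,
      bgsub_signal = values[, j],
      control_type = 0L,
      is_gene_detected = detected[, j],
      row = seq_along(probes), col = rep(1L, length(probes))))
  })
}

# Natural cubic spline least-squares oracle on the explicit
# truncated-power basis (Hastie-Tibshirani-Friedman form): basis
# functions 1, x, and d_k(x) - d_{K-1}(x) for k = 1..K-2 with
# d_k(x) = [(x - k_k)_+^3 - (x - k_K)_+^3] / (k_K - k_k).
ns_oracle_fit <- function(x, y, knots, grid) {
  K <- length(knots)
  dk <- function(z, k) {
    (pmax(z - knots[k], 0)^3 - pmax(z - knots[K], 0)^3) /
      (knots[K] - knots[k])
  }
  basis <- function(z) {
    b <- cbind(1, z)
    for (k in seq_len(K - 2L)) b <- cbind(b, dk(z, k) - dk(z, K - 1L))
    b
  }
  beta <- qr.solve(basis(x), y)
  drop(basis(grid) %*% beta)
}
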