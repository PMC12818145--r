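# Independent oracles and small model builders shared across tests.

# Oracle for first-principal-component weights: SVD of the centered data
# matrix (a different numerical route than the eigendecomposition of the
# covariance matrix used by the implementation).
svd_block_weights <- function(block) {
  block <- as.matrix(block)
  xc <- sweep(block, 2, colMeans(block))
  s <- svd(xc)
  v <- s$v[, 1]
  # same sign convention as the package (tolerance-robust largest component)
  k <- which(abs(v) >= max(abs(v)) * (1 - 1e-8))[1]
  if (v[k] < 0) v <- -v
  list(weights = v / sum(abs(v)),
       eigenvalue = s$d[1]^2 / (nrow(block) - 1))
}

# Oracle for total effects: explicit enumeration of every directed route by
# depth-first search, multiplying coefficients along each route.
enumerate_total_effect <- function(edges_df, from, to) {
  step <- function(node, acc) {
    if (node == to) return(acc)
    out <- edges_df[edges_df$source == node, , drop = FALSE]
    if (!nrow(out)) return(0)
    sum(vapply(seq_len(nrow(out)), function(i)
      step(out$target[i], acc * out$estimate[i]), 0))
  }
  if (from == to) return(0)
  step(from, 1)
}

# two correlated latents A -> B, three reflective indicators each
two_block_spec <- function() {
  model_spec(
    latents = list(list(name = "A", indicators = c("a1", "a2", "a3")),
                   list(name = "B", indicators = c("b1", "b2", "b3"))),
    paths = list(c("A", "B")),
    ipma_target = "B")
}

two_block_config <- function(path = 0.5, loading = 0.9, n = 200, seed = 1) {
  spec <- two_block_spec()
  ind <- c("a1", "a2", "a3", "b1", "b2", "b3")
  sim_config(spec,
             paths = c("A -> B" = path),
             loadings = stats::setNames(rep(loading, 6), ind),
             n_obs = n, seed = seed)
}

# loadings printed for the reference malnutrition study, used as desk-scale
# inputs to the evaluation formulas
printed_loadings <- list(
  socioeconomic = c(0.966, 0.966),
  health_environment = c(0.639, 0.469, 0.779, 0.192, 0.052, 0.411, 0.765),
  malnutrition = c(0.892, 0.879, 0.975))

printed_r2 <- c(0.216, 0.519, 0.264, 0.033)
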