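# fixtures and independent oracles used across test files

# brute-force mean-field pmf: enumerate all 2^n spin configurations and
# weight each by exp(lambda * n^2 / n_eff^2); independent of synchrony_pmf()
brute_force_pmf <- function(n_eff, lambda) {
  configs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_eff)))
  n <- rowSums(configs)
  w <- exp(lambda * n^2 / n_eff^2)
  support <- seq(-n_eff, n_eff, by = 2)
  p <- vapply(support, function(k) sum(w[n == k]), numeric(1))
  p / sum(p)
}

# exact stationary synchrony distribution of a graph Ising system with
# per-edge log-weight j_edge, by enumeration over all 2^n states
brute_force_graph_pmf <- function(g, j_edge) {
  n <- g$n_nodes
  configs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  e <- g$edges
  logw <- apply(configs, 1L, function(sp) {
    j_edge * sum(sp[e[, 1]] * sp[e[, 2]])
  })
  w <- exp(logw - max(logw))
  tot <- rowSums(configs)
  support <- seq(-n, n, by = 2)
  p <- vapply(support, function(k) sum(w[tot == k]), numeric(1))
  list(support = support, p = p / sum(p))
}

total_variation <- function(p, q) sum(abs(p - q)) / 2

# small deterministic region_ts fixture
tiny_ts <- function() {
  region_ts(
    rbind(
      c(1.0, 2.0, 1.5, 1.5, 3.0),
      c(0.0, -1.0, 3.0, 2.0, 2.5),
      c(5.0, 5.0, 5.0, 6.0, 5.0),
      c(2.0, 1.0, 0.5, 0.2, 0.1)
    ),
    subject_id = "tiny", age = 42, sex = "F", handedness = "R"
  )
}
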