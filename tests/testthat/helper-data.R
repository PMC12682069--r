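# Shared fixture builders. Everything is generated in code at test time.

# Linear regression fixture: k planted predictors (unit coefficients) among
# p - k independent noise features.
make_linear_fixture <- function(seed, n = 200, p = 100, k = 10,
                                noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("F%03d", seq_len(p))))
  beta <- c(rep(1, k), rep(0, p - k))
  y <- as.numeric(X %*% beta + stats::rnorm(n, sd = noise_sd))
  list(X = X, y = y, planted = sprintf("F%03d", seq_len(k)))
}

# Small planted-cascade simulation used by the recovery tests; noise TFs act
# as transcriptome ballast so FPKM column totals are stable.
make_cascade <- function(seed, n_samples = 300, n_top = 1, n_mid = 2,
                         n_genes = 4, n_noise = 200, noise_sd = 0.15,
                         coeff_range = c(0.9, 1.1)) {
  cfg <- simulation_config(
    n_samples = n_samples, n_top_tfs = n_top, n_mid_tfs = n_mid,
    n_genes = n_genes, n_noise_tfs = n_noise, n_unexpressed_tfs = 0,
    coeff_range = coeff_range, noise_sd = noise_sd, de_fraction = 0,
    target_parent_count = 1, seed = seed)
  net <- sample_planted_network(cfg)
  ds <- simulate_expression(net, cfg)
  el <- log_transform(suppressMessages(
    drop_unexpressed(fpkm(ds$counts, ds$gene_lengths))))
  list(cfg = cfg, net = net, ds = ds, expr_log = el)
}

# Random positive-definite correlation matrix.
random_corr <- function(seed, p) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.1
  r <- stats::cov2cor(S)
  dimnames(r) <- list(sprintf("g%02d", seq_len(p)),
                      sprintf("g%02d", seq_len(p)))
  r
}

# Random symmetric adjacency with entries in [0, 1], zero diagonal.
random_adjacency <- function(seed, p) {
  set.seed(seed)
  a <- matrix(stats::runif(p * p), p)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", seq_len(p)),
                      sprintf("g%02d", seq_len(p)))
  a
}

# Check that a layered network is strictly layered and acyclic.
expect_strictly_layered <- function(net) {
  nodes <- unlist(net$layers)
  expect_equal(anyDuplicated(nodes), 0L)
  if (nrow(net$edges)) {
    layer_of <- stats::setNames(
      rep(seq_along(net$layers) - 1L, vapply(net$layers, length, integer(1))),
      nodes)
    expect_true(all(layer_of[net$edges$tf] == layer_of[net$edges$target] + 1L))
    g <- as_igraph(net)
    expect_true(igraph::is_dag(g))
  }
}
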