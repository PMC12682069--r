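# Independent re-implementation of the binned scale-free fit regression,
# structured differently from the package's (explicit loop over bins).
oracle_fit_index <- function(k, nbins = 15) {
  if (stats::sd(k) == 0) return(0)
  edges <- seq(min(k), max(k), length.out = nbins + 1)
  xs <- ys <- c()
  for (b in seq_len(nbins)) {
    lo <- edges[b]; hi <- edges[b + 1]
    inb <- if (b == 1) k >= lo & k <= hi else k > lo & k <= hi
    if (!any(inb)) next
    km <- mean(k[inb]); pk <- sum(inb) / length(k)
    if (km > 0 && pk > 0) { xs <- c(xs, log10(km)); ys <- c(ys, log10(pk)) }
  }
  if (length(xs) < 2 || stats::sd(xs) == 0 || stats::sd(ys) == 0) return(0)
  stats::cor(xs, ys)^2
}

test_that("soft-power scan handles degenerate and singleton candidate sets", {
  p <- 6
  corr <- matrix(1, p, p, dimnames = list(letters[1:p], letters[1:p]))
  scan <- pick_soft_power(corr, candidates = c(4, 6, 8))
  expect_true(all(scan$scan$fit_index == 0))
  expect_equal(scan$chosen_power, 4L)  # degenerate tie-break: smallest

  r <- random_corr(1, 10)
  expect_equal(pick_soft_power(r, candidates = 6)$chosen_power, 6L)
})

test_that("scale-free fit index matches an independent binned regression", {
  set.seed(10)
  # five latent factors each driving 60 genes
  n <- 100
  blocks <- lapply(1:5, function(i) {
    f <- rnorm(n)
    t(sapply(1:60, function(j) f + rnorm(n, sd = 0.6)))
  })
  expr <- do.call(rbind, blocks)
  rownames(expr) <- sprintf("g%03d", 1:300)
  colnames(expr) <- sprintf("s%03d", 1:n)
  corr <- stats::cor(t(expr))
  scan <- pick_soft_power(corr, candidates = c(2, 4, 6))
  for (i in seq_len(nrow(scan$scan))) {
    a <- abs(corr)^scan$scan$power[i]
    diag(a) <- 0
    expect_equal(scan$scan$fit_index[i], oracle_fit_index(rowSums(a)),
                 tolerance = 1e-10)
  }
})

test_that("TOM is exact on degenerate graphs", {
  p <- 5
  a0 <- matrix(0, p, p, dimnames = list(letters[1:p], letters[1:p]))
  t0 <- tom(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))
  expect_true(all(diag(t0) == 1))

  a1 <- matrix(1, p, p, dimnames = dimnames(a0))
  diag(a1) <- 0
  t1 <- tom(a1)
  expect_true(all(abs(t1 - 1) < 1e-12))
})

test_that("TOM equals the triple-loop brute force", {
  a <- random_adjacency(2, 30)
  got <- tom(a)
  p <- nrow(a)
  k <- rowSums(a)
  want <- diag(p)
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    s <- 0
    for (u in 1:p) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    want[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(want) <- dimnames(a)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, t(got), tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1 + 1e-12))
  expect_error(tom(a * 2), "\\[0, 1\\]")
})

test_that("raising the soft power weakly decreases adjacency", {
  r <- random_corr(3, 15)
  a3 <- abs(r)^3; a5 <- abs(r)^5
  diag(a3) <- diag(a5) <- 0
  expect_true(all(a5 <= a3 + 1e-15))
})

test_that("module detection respects min size and recovers planted blocks", {
  small <- random_corr(4, 20)
  ma <- detect_modules(small, min_size = 30)
  expect_true(all(ma$assignment$module == "unassigned"))

  set.seed(20)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(t(sapply(1:40, function(i) f1 + rnorm(n, sd = 0.05))),
                t(sapply(1:40, function(i) f2 + rnorm(n, sd = 0.05))))
  rownames(expr) <- sprintf("g%02d", 1:80)
  colnames(expr) <- sprintf("s%03d", 1:n)
  a <- abs(stats::cor(t(expr)))^6
  diag(a) <- 0
  tm <- tom(a)
  ma <- detect_modules(tm, min_size = 30)
  labs <- ma$assignment$module
  expect_setequal(unique(labs), c("M1", "M2"))
  expect_equal(length(unique(labs[1:40])), 1L)
  expect_equal(length(unique(labs[41:80])), 1L)
  expect_false(labs[1] == labs[41])

  # permutation equivariance up to label renaming
  perm <- sample(80)
  ma_p <- detect_modules(tm[perm, perm], min_size = 30)
  orig <- stats::setNames(ma$assignment$module, ma$assignment$gene)
  permuted <- stats::setNames(ma_p$assignment$module, ma_p$assignment$gene)
  tab <- table(orig[names(permuted)], permuted)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("eigengene matches the SVD oracle with a stable sign", {
  set.seed(30)
  n <- 50
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("s%02d", 1:n)))
  ma <- structure(list(
    assignment = data.frame(gene = rownames(expr),
                            module = rep("M1", 40),
                            stringsAsFactors = FALSE),
    min_size = 30, cut_height = 0.5), class = "module_assignment")
  e <- eigengene(expr, ma)
  z <- t(scale(t(expr)))
  v1 <- svd(z)$v[, 1]
  if (stats::cor(v1, colMeans(z)) < 0) v1 <- -v1
  expect_equal(unname(e["M1", ]), v1, tolerance = 1e-8)

  # identical profiles: eigengene is the shared z-scored profile
  prof <- rnorm(n)
  same <- matrix(rep(prof, each = 10), 10, n,
                 dimnames = list(sprintf("h%02d", 1:10), colnames(expr)))
  ma2 <- structure(list(
    assignment = data.frame(gene = rownames(same), module = "M1",
                            stringsAsFactors = FALSE),
    min_size = 5, cut_height = 0.5), class = "module_assignment")
  e2 <- eigengene(same, ma2)
  zp <- as.numeric(scale(prof))
  expect_equal(abs(stats::cor(e2["M1", ], zp)), 1, tolerance = 1e-10)
  expect_gte(stats::cor(e2["M1", ], zp), 0)  # sign rule
})

test_that("module-trait correlation matches cor.test", {
  set.seed(40)
  eig <- matrix(rnorm(3 * 30), 3, 30,
                dimnames = list(c("M1", "M2", "M3"), sprintf("s%02d", 1:30)))
  trait <- rnorm(30)
  mt <- module_trait_cor(eig, trait)
  for (i in 1:3) {
    ct <- stats::cor.test(eig[i, ], trait)
    expect_equal(mt$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mt$p_value[i], ct$p.value, tolerance = 1e-10)
  }
  expect_equal(module_trait_cor(eig, eig["M2", ])$r[2], 1, tolerance = 1e-12)
  expect_equal(module_trait_cor(eig, -eig["M2", ])$r[2], -1, tolerance = 1e-12)
  expect_error(module_trait_cor(eig, rep(1, 30)), "zero variance")
})

test_that("gene significance screens on |r| with exact t-transform p", {
  set.seed(50)
  n <- 40
  trait <- rnorm(n)
  expr <- rbind(trait, matrix(rnorm(5 * n), 5, n))
  rownames(expr) <- c("hit", sprintf("g%d", 1:5))
  colnames(expr) <- sprintf("s%02d", 1:n)
  gs <- gene_significance(expr, trait, gs_min = 0.65, p_max = 1e-5)
  expect_equal(gs$table$GS[gs$table$gene == "hit"], 1)
  expect_true("hit" %in% gs$selected)
  for (i in 2:6) {
    ct <- stats::cor.test(expr[i, ], trait)
    expect_equal(gs$table$p_value[i], ct$p.value, tolerance = 1e-10)
  }
  # all-subthreshold input: empty filtered set; filter is monotone
  weak <- matrix(rnorm(8 * n), 8, n,
                 dimnames = list(sprintf("w%d", 1:8), colnames(expr)))
  gsw <- gene_significance(weak, trait)
  expect_true(all(abs(stats::cor(t(weak), trait)) < 0.65))
  expect_length(gsw$selected, 0L)
  loose <- gene_significance(expr, trait, gs_min = 0.3, p_max = 0.1)
  strict <- gene_significance(expr, trait, gs_min = 0.65, p_max = 1e-5)
  expect_true(all(strict$selected %in% loose$selected))
  expect_true(all(strict$selected %in% strict$table$gene))
  # zero-variance gene
  expr0 <- rbind(expr, flat = rep(2, n))
  gs0 <- gene_significance(expr0, trait)
  expect_equal(gs0$table$GS[gs0$table$gene == "flat"], 0)
  expect_equal(gs0$table$p_value[gs0$table$gene == "flat"], 1)
})

test_that("all planted parents of the target pass the GS screen", {
  flagged_all <- logical(10)
  for (s in 1:10) {
    cfg <- simulation_config(n_samples = 87, n_top_tfs = 1, n_mid_tfs = 10,
                             n_genes = 10, n_noise_tfs = 60,
                             n_unexpressed_tfs = 0, coeff_range = c(1, 1),
                             noise_sd = 0.2, de_fraction = 0,
                             target_parent_count = 5, seed = 100 + s)
    net <- sample_planted_network(cfg)
    ds <- simulate_expression(net, cfg)
    el <- log_transform(suppressMessages(
      drop_unexpressed(fpkm(ds$counts, ds$gene_lengths))))
    trait <- el[net$target_gene, ]
    tf_expr <- el[intersect(ds$tf_list, rownames(el)), ]
    gs <- gene_significance(tf_expr, trait, gs_min = 0.65, p_max = 1e-5)
    flagged_all[s] <- all(net$target_parents %in% gs$selected)
  }
  expect_true(all(flagged_all))
})
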