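test_that("pearson_matrix matches the covariance-formula oracle", {
  set.seed(1)
  expr <- matrix(rnorm(10 * 25), 10, 25,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sprintf("s%02d", 1:25)))
  r <- pearson_matrix(expr)
  for (i in 1:10) for (j in 1:10) {
    x <- expr[i, ]; y <- expr[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(unname(diag(r)), rep(1, 10))
  expr2 <- rbind(expr, neg = -expr["g01", ], flat = rep(3, 25))
  r2 <- pearson_matrix(expr2)
  expect_equal(r2["g01", "neg"], -1, tolerance = 1e-12)
  expect_equal(r2["flat", "g01"], 0)
  expect_true("flat" %in% attr(r2, "zero_variance"))
  expect_error(pearson_matrix(expr[, 1:2, drop = FALSE]), "3 samples")
})

test_that("coexpressed_pairs equals the exhaustive double loop", {
  r <- random_corr(5, 20)
  bottom <- rownames(r)[1:12]
  got <- coexpressed_pairs(r, bottom, cc_min = 0.2)
  want <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    if (r[bottom[i], bottom[j]] >= 0.2) {
      want <- want + 1L
      expect_true(any(got$x == bottom[i] & got$y == bottom[j]))
    }
  }
  expect_equal(nrow(got), want)

  flat <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 1
  expect_equal(nrow(coexpressed_pairs(flat, letters[1:4], 0.8)), 0L)
  one <- flat; one["a", "b"] <- one["b", "a"] <- 0.85
  pr <- coexpressed_pairs(one, letters[1:4], 0.8)
  expect_equal(nrow(pr), 1L)
  expect_equal(c(pr$x, pr$y), c("a", "b"))
})

test_that("partial correlation reproduces the printed formula exactly", {
  expect_equal(partial_corr(0.9, 0, 0), 0.9)
  expect_equal(partial_corr(0.72, 0.9, 0.8), 0, tolerance = 1e-15)
  # symmetry in x and y
  expect_equal(partial_corr(0.5, 0.3, 0.7), partial_corr(0.5, 0.7, 0.3))
  expect_error(partial_corr(0.5, 1, 0.2), "degenerate")
  expect_error(partial_corr(1.5, 0.1, 0.2), "\\[-1, 1\\]")
})

test_that("formula path agrees with the regress-out-residuals oracle", {
  set.seed(99)
  for (rep_i in 1:200) {
    n <- 200
    z <- rnorm(n)
    x <- 0.8 * z + rnorm(n, sd = runif(1, 0.3, 1.5))
    y <- -0.5 * z + rnorm(n, sd = runif(1, 0.3, 1.5))
    got <- partial_corr(stats::cor(x, y), stats::cor(x, z), stats::cor(y, z))
    oracle <- stats::cor(stats::residuals(stats::lm(x ~ z)),
                         stats::residuals(stats::lm(y ~ z)))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("partial correlations from a PSD matrix stay within [-1, 1]", {
  for (s in 1:20) {
    r <- random_corr(s, 8)
    for (i in 1:6) {
      pc <- partial_corr(r[1, 2], r[1, 2 + i %% 6 + 1], r[2, 2 + i %% 6 + 1])
      expect_lte(abs(pc), 1 + 1e-9)
    }
  }
})

test_that("regulator inference emits edges only when conditioning collapses", {
  cn <- c("x", "y", "z")
  r_indep <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3,
                    dimnames = list(cn, cn))
  pairs <- data.frame(x = "x", y = "y", r_xy = 0.9, stringsAsFactors = FALSE)
  e <- infer_layer_regulators(pairs, "z", r_indep)
  expect_equal(nrow(e), 0L)  # pcc stays 0.9

  r_common <- matrix(c(1, 0.81, 0.9, 0.81, 1, 0.9, 0.9, 0.9, 1), 3,
                     dimnames = list(cn, cn))
  pairs2 <- data.frame(x = "x", y = "y", r_xy = 0.81, stringsAsFactors = FALSE)
  e2 <- infer_layer_regulators(pairs2, "z", r_common)
  expect_setequal(e2$target, c("x", "y"))
  expect_true(all(e2$tf == "z"))
  expect_equal(e2$pcc, c(0, 0), tolerance = 1e-12)
})

test_that("duplicate edges are merged keeping the smallest |pcc|", {
  cn <- c("x", "y", "w", "z")
  r <- diag(4); dimnames(r) <- list(cn, cn)
  r["x", "y"] <- r["y", "x"] <- 0.81
  r["x", "w"] <- r["w", "x"] <- 0.81
  r["y", "w"] <- r["w", "y"] <- 0.81
  r["x", "z"] <- r["z", "x"] <- 0.9
  r["y", "z"] <- r["z", "y"] <- 0.9
  r["w", "z"] <- r["z", "w"] <- 0.85
  pairs <- coexpressed_pairs(r, c("x", "y", "w"), 0.8)
  e <- infer_layer_regulators(pairs, "z", r, pcc_max = 0.5,
                              prune_proxies = FALSE)
  # x participates in pairs (x,y) and (x,w); the z->x record keeps min |pcc|
  ex <- e[e$target == "x", ]
  expect_equal(nrow(ex), 1L)
  pcc_xy <- partial_corr(0.81, 0.9, 0.9)
  pcc_xw <- partial_corr(0.81, 0.9, 0.85)
  expect_equal(ex$pcc, min(abs(c(pcc_xy, pcc_xw))) *
                 sign(c(pcc_xy, pcc_xw)[which.min(abs(c(pcc_xy, pcc_xw)))]),
               tolerance = 1e-12)
})

test_that("a planted mid-TF with two children is recovered", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    n <- 200
    z <- rnorm(n)
    expr <- rbind(TF_z = z,
                  g1 = z + rnorm(n, sd = 0.2),
                  g2 = z + rnorm(n, sd = 0.2))
    colnames(expr) <- sprintf("s%03d", 1:n)
    corr <- pearson_matrix(expr)
    pairs <- coexpressed_pairs(corr, c("g1", "g2"), 0.8)
    e <- infer_layer_regulators(pairs, "TF_z", corr, 0.3)
    if (nrow(e) == 2 && all(e$tf == "TF_z") &&
        setequal(e$target, c("g1", "g2"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("build_network degenerates gracefully and is deterministic", {
  cas <- make_cascade(31, n_samples = 100, n_noise = 50)
  bottom <- grep("^GENE", rownames(cas$expr_log), value = TRUE)
  empty_pool <- suppressMessages(
    build_network(bottom, character(), cas$expr_log))
  expect_length(empty_pool$layers, 1L)
  expect_equal(nrow(empty_pool$edges), 0L)

  n1 <- suppressMessages(build_network(bottom, cas$ds$tf_list, cas$expr_log))
  n2 <- suppressMessages(build_network(bottom, cas$ds$tf_list, cas$expr_log))
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$layers, n2$layers)
  expect_strictly_layered(n1)
})

test_that("edge sets are monotone in the screening thresholds", {
  cas <- make_cascade(32, n_samples = 150, n_noise = 50)
  bottom <- grep("^GENE", rownames(cas$expr_log), value = TRUE)
  corr <- pearson_matrix(cas$expr_log)
  p_loose <- coexpressed_pairs(corr, bottom, 0.7)
  p_tight <- coexpressed_pairs(corr, bottom, 0.9)
  key <- function(df) paste(df$x, df$y)
  expect_true(all(key(p_tight) %in% key(p_loose)))

  pool <- setdiff(cas$ds$tf_list, bottom)
  e_loose <- infer_layer_regulators(p_loose, pool, corr, pcc_max = 0.4,
                                    prune_proxies = FALSE)
  e_tight <- infer_layer_regulators(p_loose, pool, corr, pcc_max = 0.2,
                                    prune_proxies = FALSE)
  ekey <- function(df) paste(df$tf, df$target)
  expect_true(all(ekey(e_tight) %in% ekey(e_loose)))
})

test_that("network export writes consistent edge, layer and graph files", {
  cas <- make_cascade(33, n_samples = 150, n_noise = 40)
  bottom <- grep("^GENE", rownames(cas$expr_log), value = TRUE)
  nw <- suppressMessages(build_network(bottom, cas$ds$tf_list, cas$expr_log))
  out <- file.path(tempdir(), "nw_export")
  paths <- write_network(nw, out)
  expect_true(all(file.exists(paths)))
  edges <- utils::read.delim(paths["edges"])
  expect_equal(nrow(edges), nrow(nw$edges))
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::gorder(g), length(unlist(nw$layers)))
  expect_equal(igraph::gsize(g), nrow(nw$edges))
})
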