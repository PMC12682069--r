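# Compact co-expression module stage: soft-threshold selection by scale-free
# fit, unsigned |r|^beta adjacency, topological overlap, average-linkage
# module detection with a minimum module size, module eigengenes and
# gene-significance screening against a continuous trait.

# R^2 of the log10 degree-distribution regression over equal-width bins.
scale_free_fit_index <- function(k, nbins = 15) {
  if (length(k) < 2 || stats::sd(k) == 0) return(0)
  breaks <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(k, bin, length)
  means <- tapply(k, bin, mean)
  keep <- !is.na(counts) & counts > 0 & !is.na(means) & means > 0
  if (sum(keep) < 2) return(0)
  p <- counts[keep] / length(k)
  x <- log10(means[keep])
  y <- log10(p)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  summary(stats::lm(y ~ x))$r.squared
}

#' Select a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power beta, forms the unsigned adjacency `|r|^beta`,
#' computes each gene's connectivity `k_i = sum_{j != i} a_ij`, and scores
#' the scale-free fit index: the R-squared of regressing `log10 p(k)` on
#' `log10 k` over 15 equal-width connectivity bins (empty bins dropped).
#' The chosen power is the smallest candidate whose fit reaches
#' `target_fit`; if none does, the candidate with the maximal fit (ties go
#' to the smaller power). Degenerate scans with constant connectivity score
#' a fit of 0.
#'
#' @param corr symmetric gene correlation matrix with unit diagonal.
#' @param candidates integer candidate powers.
#' @param target_fit minimum acceptable fit index (default 0.8).
#' @param nbins number of connectivity bins for the fit regression.
#' @return An object of class `soft_power_scan`: data.frame `scan` (power,
#'   fit_index, mean_connectivity) and `chosen_power`.
#' @export
pick_soft_power <- function(corr, candidates = c(1:10, seq(12, 20, 2)),
                            target_fit = 0.8, nbins = 15) {
  assert_matrix_like(corr, "corr")
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("corr must be symmetric with unit diagonal", call. = FALSE)
  }
  candidates <- as.integer(candidates)
  a0 <- abs(corr)
  diag(a0) <- 0
  scan <- data.frame(power = candidates, fit_index = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(candidates)) {
    a <- a0^candidates[i]
    k <- rowSums(a)
    scan$fit_index[i] <- scale_free_fit_index(k, nbins)
    scan$mean_connectivity[i] <- mean(k)
  }
  ok <- which(scan$fit_index >= target_fit)
  chosen <- if (length(ok)) candidates[min(ok)] else
    candidates[which.max(scan$fit_index)]
  structure(list(scan = scan, chosen_power = chosen,
                 target_fit = target_fit), class = "soft_power_scan")
}

#' @export
print.soft_power_scan <- function(x, ...) {
  cat(sprintf("Soft-power scan over %d candidates; chosen power = %d (fit %.3f)\n",
              nrow(x$scan), x$chosen_power,
              x$scan$fit_index[x$scan$power == x$chosen_power]))
  invisible(x)
}

#' Topological overlap matrix
#'
#' For an unsigned adjacency with entries in \[0, 1\] (the diagonal is
#' zeroed internally), computes
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `TOM_ii = 1`. Shared-neighbor weight thus augments direct
#' adjacency.
#'
#' @param adjacency symmetric numeric matrix, entries in \[0, 1\].
#' @return TOM matrix of the same shape, unit diagonal.
#' @export
tom <- function(adjacency) {
  assert_matrix_like(adjacency, "adjacency")
  a <- adjacency
  diag(a) <- 0
  if (any(a < 0 | a > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(a - t(a))) > 1e-10) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  shared <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  out <- (shared + a) / (kmin + 1 - a)
  diag(out) <- 1
  out
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height `cut_fraction * max merge height`; clusters smaller
#' than `min_size` are relabeled `"unassigned"`. Kept modules are labeled
#' `M1, M2, ...` in decreasing size order, so labels are deterministic given
#' the input (and equivariant under gene reordering, up to renaming).
#'
#' @param tom_matrix TOM (or any similarity in \[0, 1\] with unit diagonal).
#' @param min_size minimum module size (default 30).
#' @param cut_fraction static cut height as a fraction of the maximal merge
#'   height (default 0.99).
#' @return An object of class `module_assignment`: data.frame `assignment`
#'   (gene, module), plus `min_size` and the cut height used.
#' @export
detect_modules <- function(tom_matrix, min_size = 30, cut_fraction = 0.99) {
  assert_matrix_like(tom_matrix, "tom_matrix")
  genes <- rownames(tom_matrix)
  if (length(genes) < min_size) {
    assignment <- data.frame(gene = genes, module = "unassigned",
                             stringsAsFactors = FALSE)
    return(structure(list(assignment = assignment, min_size = min_size,
                          cut_height = NA_real_),
                     class = "module_assignment"))
  }
  d <- stats::as.dist(1 - tom_matrix)
  tree <- stats::hclust(d, method = "average")
  h <- cut_fraction * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep("unassigned", length(genes))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) {
      module[cl == as.integer(ord[i])] <- sprintf("M%d", i)
    }
  }
  structure(list(
    assignment = data.frame(gene = genes, module = module,
                            stringsAsFactors = FALSE),
    min_size = min_size, cut_height = h
  ), class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$assignment$module)
  cat(sprintf("Module assignment: %d genes, %d modules (min size %d)\n",
              nrow(x$assignment), sum(names(tab) != "unassigned"),
              x$min_size))
  print(tab)
  invisible(x)
}

module_members <- function(modules, label) {
  modules$assignment$gene[modules$assignment$module == label]
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across samples
#' of the per-gene z-scored module submatrix; its sign is fixed so that its
#' correlation with the module's mean expression profile is nonnegative.
#' Zero-variance genes are dropped before standardization.
#'
#' @param expr_log log-scale expression matrix, genes x samples.
#' @param modules a [detect_modules()] result.
#' @return matrix, modules x samples.
#' @export
eigengene <- function(expr_log, modules) {
  assert_matrix_like(expr_log, "expr_log")
  stopifnot(inherits(modules, "module_assignment"))
  labels <- setdiff(sort(unique(modules$assignment$module)), "unassigned")
  if (!length(labels)) stop("no assigned modules", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(labels), ncol = ncol(expr_log),
                dimnames = list(labels, colnames(expr_log)))
  for (m in labels) {
    genes <- intersect(module_members(modules, m), rownames(expr_log))
    sub <- expr_log[genes, , drop = FALSE]
    v <- apply(sub, 1, stats::sd)
    sub <- sub[v > 0, , drop = FALSE]
    if (nrow(sub) == 0) stop("module ", m, " has no varying genes", call. = FALSE)
    z <- t(scale(t(sub)))
    e <- svd(z, nu = 0, nv = 1)$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    out[m, ] <- e
  }
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (typically the target gene's expression), with a two-sided p-value from
#' the exact t-transform of r.
#'
#' @param eigengenes matrix from [eigengene()], modules x samples.
#' @param trait numeric vector, one value per sample.
#' @return data.frame with module, r, p_value.
#' @export
module_trait_cor <- function(eigengenes, trait) {
  if (ncol(eigengenes) < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(trait) != ncol(eigengenes)) {
    stop("trait length must match sample count", call. = FALSE)
  }
  if (stats::sd(trait) == 0) stop("trait has zero variance", call. = FALSE)
  r <- as.numeric(stats::cor(t(eigengenes), trait))
  data.frame(module = rownames(eigengenes), r = r,
             p_value = cor_pvalue(r, length(trait)),
             stringsAsFactors = FALSE)
}

#' Gene significance against a trait
#'
#' Gene significance (GS) is the absolute Pearson correlation between a
#' gene's expression and the trait; its p-value comes from the two-sided
#' t-transform of r at the sample size. Genes pass the screen when
#' `GS >= gs_min` and `p < p_max` (defaults GS >= 0.65, P < 1e-5).
#' Zero-variance genes get GS 0 and p 1.
#'
#' @param expr_log log-scale expression matrix, genes x samples.
#' @param trait numeric per-sample vector.
#' @param gs_min minimum GS for the filtered set.
#' @param p_max maximum p-value for the filtered set.
#' @return list with `table` (gene, GS, p_value, flagged) and `selected`
#'   (character vector of passing genes).
#' @export
gene_significance <- function(expr_log, trait, gs_min = 0.65, p_max = 1e-5) {
  assert_matrix_like(expr_log, "expr_log")
  if (ncol(expr_log) < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(trait) != ncol(expr_log)) {
    stop("trait length must match sample count", call. = FALSE)
  }
  v <- apply(expr_log, 1, stats::sd)
  r <- rep(0, nrow(expr_log))
  if (stats::sd(trait) > 0 && any(v > 0)) {
    r[v > 0] <- as.numeric(stats::cor(t(expr_log[v > 0, , drop = FALSE]), trait))
  }
  gs <- abs(r)
  p <- ifelse(v > 0, cor_pvalue(r, length(trait)), 1)
  flagged <- gs >= gs_min & p < p_max
  tab <- data.frame(gene = rownames(expr_log), GS = gs, p_value = p,
                    flagged = flagged, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, selected = tab$gene[tab$flagged])
}
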