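# Bottom-up Gaussian-graphical-model construction of a multilayered
# regulatory network: Pearson screening of co-expressed gene pairs, per-TF
# partial correlation to find common regulators, and iterative promotion of
# placed TFs to the next layer.

#' Pearson correlation matrix over selected genes
#'
#' @param expr_log log-scale expression matrix, genes x samples.
#' @param genes genes to include (default: all rows).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   genes get r = 0 against everything and are listed in the
#'   `"zero_variance"` attribute. The sample count is attached as `"n"`.
#' @export
pearson_matrix <- function(expr_log, genes = rownames(expr_log)) {
  assert_matrix_like(expr_log, "expr_log")
  if (ncol(expr_log) < 3) stop("need at least 3 samples", call. = FALSE)
  missing <- setdiff(genes, rownames(expr_log))
  if (length(missing)) {
    stop("gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- expr_log[genes, , drop = FALSE]
  v <- apply(sub, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(sub)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  attr(r, "n") <- ncol(expr_log)
  attr(r, "zero_variance") <- genes[v == 0]
  r
}

#' Co-expressed gene pairs above a correlation threshold
#'
#' Enumerates unordered pairs of bottom-layer genes whose signed Pearson
#' correlation reaches `cc_min` (default 0.8, the CC > 0.8 screening rule;
#' set `use_abs = TRUE` to screen on |r| instead).
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param bottom character vector of bottom-layer genes (subset of `corr`).
#' @param cc_min correlation threshold.
#' @param use_abs screen on absolute correlation.
#' @return data.frame with columns x, y, r_xy (x < y lexicographically,
#'   each pair once).
#' @export
coexpressed_pairs <- function(corr, bottom, cc_min = 0.8, use_abs = FALSE) {
  missing <- setdiff(bottom, rownames(corr))
  if (length(missing)) {
    stop("bottom gene(s) not in correlation matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  bottom <- sort(unique(bottom))
  if (length(bottom) < 2) {
    return(data.frame(x = character(), y = character(), r_xy = numeric(),
                      stringsAsFactors = FALSE))
  }
  sub <- corr[bottom, bottom, drop = FALSE]
  val <- if (use_abs) abs(sub) else sub
  idx <- which(upper.tri(sub) & val >= cc_min, arr.ind = TRUE)
  data.frame(x = bottom[idx[, 1]], y = bottom[idx[, 2]],
             r_xy = sub[idx], row.names = NULL, stringsAsFactors = FALSE)
}

#' First-order partial correlation
#'
#' The correlation of x and y after removing the linear effect of z:
#' `r_xy|z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#' A co-expressed pair whose partial correlation collapses when conditioning
#' on a TF implicates that TF as a common regulator.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations (vectorized).
#' @return the partial correlation(s).
#' @export
partial_corr <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1)) {
    stop("degenerate conditioning: |r_xz| or |r_yz| equals 1", call. = FALSE)
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Infer one layer of regulators by partial correlation
#'
#' For every co-expressed pair (x, y) and every candidate TF z (not itself
#' a member of the pair), computes `r_xy|z`; if `|r_xy|z| < pcc_max`
#' (default 0.3), z is taken as a common regulator and edges z -> x and
#' z -> y are emitted, annotated with the supporting pair and partial
#' correlation. Duplicate edges arising from different pairs are merged,
#' keeping the record with the smallest |pcc| (strongest conditioning
#' evidence). Degenerate (pair, TF) combinations are skipped and counted in
#' the `"n_skipped"` attribute.
#'
#' When several candidate TFs explain overlapping targets, a highly
#' correlated proxy of the true regulator (for instance its own upstream
#' regulator) also collapses the pair. With `prune_proxies = TRUE` (the
#' default) a second first-order conditioning pass keeps only the most
#' proximal regulator per target: an edge z -> x is dropped when some other
#' candidate z2 of x screens z off from x (`|r(x,z | z2)| < pcc_max`) while
#' z2's own association survives conditioning on z
#' (`|r(x,z2 | z)| >= pcc_max`). Mutually collapsing candidates are both
#' kept (the data cannot orient them).
#'
#' @param pairs data.frame from [coexpressed_pairs()].
#' @param tf_pool candidate regulator identifiers (disjoint from the pair
#'   genes; TFs already placed in a lower layer must be excluded).
#' @param corr correlation matrix covering pair genes and TFs.
#' @param pcc_max partial-correlation threshold.
#' @param prune_proxies apply the proximal-regulator pruning pass.
#' @return data.frame of edges: tf, target, via_x, via_y, r_xy, pcc.
#' @export
infer_layer_regulators <- function(pairs, tf_pool, corr, pcc_max = 0.3,
                                   prune_proxies = TRUE) {
  empty <- data.frame(tf = character(), target = character(),
                      via_x = character(), via_y = character(),
                      r_xy = numeric(), pcc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || length(tf_pool) == 0) return(empty)
  bad <- intersect(tf_pool, unique(c(pairs$x, pairs$y)))
  if (length(bad)) {
    stop("tf_pool overlaps the pair genes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x[i]; y <- pairs$y[i]; rxy <- pairs$r_xy[i]
    rxz <- corr[x, tf_pool]
    ryz <- corr[y, tf_pool]
    degen <- abs(rxz) >= 1 | abs(ryz) >= 1
    n_skipped <- n_skipped + sum(degen)
    z <- tf_pool[!degen]
    if (!length(z)) next
    pcc <- (rxy - rxz[!degen] * ryz[!degen]) /
      sqrt((1 - rxz[!degen]^2) * (1 - ryz[!degen]^2))
    hit <- abs(pcc) < pcc_max
    if (!any(hit)) next
    zh <- z[hit]; pc <- pcc[hit]
    out[[length(out) + 1L]] <- data.frame(
      tf = rep(zh, 2L), target = rep(c(x, y), each = length(zh)),
      via_x = x, via_y = y, r_xy = rxy, pcc = rep(pc, 2L),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0) {
    message(n_skipped, " degenerate (pair, TF) combination(s) skipped")
  }
  if (!length(out)) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  edges <- do.call(rbind, out)
  # merge duplicates keeping the smallest |pcc|
  edges <- edges[order(edges$tf, edges$target, abs(edges$pcc)), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("tf", "target")]), , drop = FALSE]
  if (prune_proxies && nrow(edges) > 1) {
    edges <- prune_proxy_edges(edges, corr, pcc_max)
  }
  rownames(edges) <- NULL
  attr(edges, "n_skipped") <- n_skipped
  edges
}

# Drop z -> x when another candidate z2 of x screens z off from x while z2
# itself stays associated with x given z.
prune_proxy_edges <- function(edges, corr, pcc_max) {
  drop <- logical(nrow(edges))
  for (x in unique(edges$target)) {
    idx <- which(edges$target == x)
    zs <- edges$tf[idx]
    if (length(zs) < 2) next
    for (a in seq_along(zs)) {
      z <- zs[a]
      for (z2 in zs[-a]) {
        if (abs(corr[z, z2]) >= 1) next
        r_xz_g <- partial_corr(corr[x, z], corr[x, z2], corr[z, z2])
        r_xz2_g <- partial_corr(corr[x, z2], corr[x, z], corr[z, z2])
        if (abs(r_xz_g) < pcc_max && abs(r_xz2_g) >= pcc_max) {
          drop[idx[a]] <- TRUE
          break
        }
      }
    }
  }
  edges[!drop, , drop = FALSE]
}

#' Build a multilayered regulatory network bottom-up
#'
#' Starting from the bottom layer (layer 0: pathway genes), iterates: screen
#' co-expressed pairs within the current layer (`cc_min`), find TFs in the
#' remaining pool whose conditioning collapses a pair's correlation
#' (`pcc_max`), promote those TFs to the next layer, remove them from the
#' pool, and repeat with the new layer as the bottom. Stops when no
#' regulators are found, the pool is exhausted, or `max_layers` is reached
#' (default 3, mirroring a primary-TF / secondary-TF / functional-gene
#' hierarchy). TFs that are themselves bottom-layer members stay in layer 0
#' and never act as layer-1 regulators, preserving strict layering.
#'
#' @param bottom_genes nonempty character vector of bottom-layer genes.
#' @param tf_pool candidate regulator identifiers.
#' @param expr_log log-scale expression matrix covering all identifiers.
#' @param cc_min pair-screening Pearson threshold (default 0.8).
#' @param pcc_max regulator partial-correlation threshold (default 0.3).
#' @param max_layers maximum number of layers including the bottom.
#' @param use_abs screen pairs on |r| instead of signed r.
#' @param prune_proxies see [infer_layer_regulators()].
#' @return An object of class `layered_network`: `layers` (list of
#'   identifier vectors, element 1 = layer 0), `edges` (data.frame with tf,
#'   target, via pair, r_xy, pcc, layer_from, layer_to; regulator layer
#'   index = target layer index + 1), `params`, and per-layer statistics.
#' @export
build_network <- function(bottom_genes, tf_pool, expr_log, cc_min = 0.8,
                          pcc_max = 0.3, max_layers = 3L, use_abs = FALSE,
                          prune_proxies = TRUE) {
  if (!length(bottom_genes)) stop("bottom_genes is empty", call. = FALSE)
  assert_matrix_like(expr_log, "expr_log")
  pool <- setdiff(tf_pool, bottom_genes)
  layers <- list(sort(unique(bottom_genes)))
  edges <- NULL
  current <- layers[[1]]
  k <- 0L
  while (k + 1L < max_layers && length(pool) > 0) {
    ids <- unique(c(current, pool))
    corr <- pearson_matrix(expr_log, ids)
    pairs <- coexpressed_pairs(corr, current, cc_min, use_abs)
    if (nrow(pairs) == 0) break
    new_edges <- infer_layer_regulators(pairs, pool, corr, pcc_max,
                                        prune_proxies)
    if (nrow(new_edges) == 0) break
    k <- k + 1L
    new_layer <- sort(unique(new_edges$tf))
    new_edges$layer_from <- k
    new_edges$layer_to <- k - 1L
    edges <- rbind(edges, new_edges)
    layers[[k + 1L]] <- new_layer
    pool <- setdiff(pool, new_layer)
    current <- new_layer
  }
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), target = character(),
                        via_x = character(), via_y = character(),
                        r_xy = numeric(), pcc = numeric(),
                        layer_from = integer(), layer_to = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(
    layers = layers, edges = edges,
    params = list(cc_min = cc_min, pcc_max = pcc_max,
                  max_layers = max_layers, use_abs = use_abs,
                  prune_proxies = prune_proxies),
    layer_sizes = vapply(layers, length, integer(1))
  ), class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("Layered regulatory network: %d layers, %d edges\n",
              length(x$layers), nrow(x$edges)))
  for (i in seq_along(x$layers)) {
    cat(sprintf("  layer %d: %d node(s)\n", i - 1L, length(x$layers[[i]])))
  }
  invisible(x)
}

#' Convert a layered network to an igraph object
#'
#' @param net a [build_network()] result.
#' @return directed `igraph` graph; vertices carry a `layer` attribute,
#'   edges carry `r_xy` and `pcc`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "layered_network"))
  nodes <- data.frame(
    name = unlist(net$layers),
    layer = rep(seq_along(net$layers) - 1L,
                vapply(net$layers, length, integer(1))),
    stringsAsFactors = FALSE)
  edges <- net$edges[, c("tf", "target", "r_xy", "pcc")]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Write a layered network to standard formats
#'
#' Emits an edge table TSV, a layer-membership TSV, a GraphML file, a SIF
#' file and a run-parameters JSON.
#'
#' @param net a [build_network()] result.
#' @param dir output directory, created if missing.
#' @param prefix filename prefix (default `"network"`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_network <- function(net, dir, prefix = "network") {
  stopifnot(inherits(net, "layered_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    layers = file.path(dir, paste0(prefix, "_layers.tsv")),
    graphml = file.path(dir, paste0(prefix, ".graphml")),
    sif = file.path(dir, paste0(prefix, ".sif")),
    params = file.path(dir, paste0(prefix, "_params.json"))
  )
  write_tsv(net$edges, paths["edges"])
  membership <- data.frame(
    node = unlist(net$layers),
    layer = rep(seq_along(net$layers) - 1L,
                vapply(net$layers, length, integer(1))))
  write_tsv(membership, paths["layers"])
  igraph::write_graph(as_igraph(net), paths["graphml"], format = "graphml")
  sif <- if (nrow(net$edges)) {
    paste(net$edges$tf, "regulates", net$edges$target)
  } else character()
  writeLines(sif, paths["sif"])
  jsonlite::write_json(net$params, paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
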