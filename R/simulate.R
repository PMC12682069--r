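#' Configuration for the synthetic expression simulator
#'
#' Describes a synthetic RNA-seq study with a planted three-layer regulatory
#' network (top-level TFs regulating mid-level TFs regulating pathway genes),
#' a continuous "phenotype" target gene driven by a subset of mid-level TFs,
#' condition groups carrying planted differential expression, and a Poisson
#' count observation layer over the latent log2 expression.
#'
#' The defaults mirror the scale of an 87-sample light-intensity study in
#' safflower: three condition groups, 2079 annotated TFs of which 400 are
#' never expressed (so 1679 survive the zero-expression filter), a layered
#' truth of 14 top TFs, 134 mid TFs and 131 pathway genes, and a target gene
#' driven by 5 mid-level TFs. Tests and small examples pass smaller values.
#'
#' @param n_samples total number of samples.
#' @param n_conditions number of condition groups (samples split evenly;
#'   remainders go to the earliest groups).
#' @param n_top_tfs,n_mid_tfs,n_genes node counts of the planted layers.
#' @param n_noise_tfs expressed TFs with no planted regulatory targets.
#' @param n_unexpressed_tfs TFs whose counts are identically zero, emulating
#'   annotated-but-silent regulators.
#' @param coeff_range length-2 numeric, bounds on |beta| for planted edges.
#' @param negative_fraction fraction of planted edges given a negative sign
#'   (default 0: purely activating cascades, matching positive co-expression
#'   screening downstream).
#' @param noise_sd residual SD of each structural equation (log2 scale).
#' @param de_fraction fraction of expressed non-target nodes given a planted
#'   group-mean shift.
#' @param de_log2fc_range length-2 positive numeric, bounds on the planted
#'   |log2 fold change| between the first and last condition group.
#' @param gene_length_range length-2 positive integer, bp bounds for gene
#'   lengths.
#' @param library_size_range length-2 positive integer, bounds on per-sample
#'   sequencing depth.
#' @param target_parent_count number of mid-level TFs driving the target
#'   gene; default `min(5, n_mid_tfs)`.
#' @param baseline_log2_range length-2 numeric, per-gene baseline log2
#'   abundance added to the structural signal before count generation.
#' @param dispersion optional negative-binomial dispersion (1/size); `NULL`
#'   (default) uses a Poisson observation layer.
#' @param seed integer seed; all sub-generators derive stage seeds from it.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 87L,
                              n_conditions = 3L,
                              n_top_tfs = 14L,
                              n_mid_tfs = 134L,
                              n_genes = 131L,
                              n_noise_tfs = 1531L,
                              n_unexpressed_tfs = 400L,
                              coeff_range = c(0.8, 1.2),
                              negative_fraction = 0,
                              noise_sd = 0.2,
                              de_fraction = 0.2,
                              de_log2fc_range = c(1.5, 3),
                              gene_length_range = c(500L, 5000L),
                              library_size_range = c(5e6, 2e7),
                              target_parent_count = NULL,
                              baseline_log2_range = c(3, 8),
                              dispersion = NULL,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_conditions = as.integer(n_conditions),
    n_top_tfs = as.integer(n_top_tfs),
    n_mid_tfs = as.integer(n_mid_tfs),
    n_genes = as.integer(n_genes),
    n_noise_tfs = as.integer(n_noise_tfs),
    n_unexpressed_tfs = as.integer(n_unexpressed_tfs),
    coeff_range = as.numeric(coeff_range),
    negative_fraction = as.numeric(negative_fraction),
    noise_sd = as.numeric(noise_sd),
    de_fraction = as.numeric(de_fraction),
    de_log2fc_range = as.numeric(de_log2fc_range),
    gene_length_range = as.numeric(gene_length_range),
    library_size_range = as.numeric(library_size_range),
    target_parent_count = as.integer(target_parent_count %||%
                                       min(5L, n_mid_tfs)),
    baseline_log2_range = as.numeric(baseline_log2_range),
    dispersion = dispersion,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_samples", "n_conditions", "n_top_tfs", "n_mid_tfs",
              "n_genes", "target_parent_count")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(f, " must be >= 1", call. = FALSE)
  }
  if (cfg$n_noise_tfs < 0L || cfg$n_unexpressed_tfs < 0L) {
    stop("noise/unexpressed TF counts must be >= 0", call. = FALSE)
  }
  for (f in c("coeff_range", "de_log2fc_range", "gene_length_range",
              "library_size_range", "baseline_log2_range")) {
    rng <- cfg[[f]]
    if (length(rng) != 2L || rng[1] > rng[2]) {
      stop(f, " must be an ordered pair (low <= high)", call. = FALSE)
    }
  }
  if (any(cfg$coeff_range <= 0)) stop("coeff_range must be positive", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$negative_fraction < 0 || cfg$negative_fraction > 1) {
    stop("negative_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$target_parent_count > cfg$n_mid_tfs) {
    stop("target_parent_count cannot exceed n_mid_tfs", call. = FALSE)
  }
  invisible(cfg)
}

#' Draw a planted layered regulatory network
#'
#' Samples a strictly layered DAG: every mid-level TF receives at least one
#' top-level TF parent, every pathway gene at least one mid-level TF parent,
#' and a dedicated target gene is driven by `target_parent_count` mid-level
#' TFs. Edge coefficients are drawn uniformly from `coeff_range`, with a
#' `negative_fraction` share of signs flipped.
#'
#' @param config a [simulation_config()].
#' @return An object of class `planted_network` with elements `nodes`
#'   (data.frame: id, layer), `edges` (data.frame: parent, child, beta),
#'   `target_gene` and `target_parents`.
#' @export
sample_planted_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "network"))

  top <- sprintf("TF_top_%03d", seq_len(config$n_top_tfs))
  mid <- sprintf("TF_mid_%03d", seq_len(config$n_mid_tfs))
  gen <- sprintf("GENE_%04d", seq_len(config$n_genes))
  target <- "GENE_target"

  draw_beta <- function(k) {
    b <- stats::runif(k, config$coeff_range[1], config$coeff_range[2])
    neg <- stats::runif(k) < config$negative_fraction
    b[neg] <- -b[neg]
    b
  }
  pick_parents <- function(pool) {
    k <- sample.int(min(2L, length(pool)), 1L)
    sample(pool, k)
  }

  edges <- list()
  for (m in mid) {
    par <- pick_parents(top)
    edges[[length(edges) + 1L]] <- data.frame(
      parent = par, child = m, beta = draw_beta(length(par)),
      stringsAsFactors = FALSE)
  }
  for (g in gen) {
    par <- pick_parents(mid)
    edges[[length(edges) + 1L]] <- data.frame(
      parent = par, child = g, beta = draw_beta(length(par)),
      stringsAsFactors = FALSE)
  }
  target_parents <- sample(mid, config$target_parent_count)
  edges[[length(edges) + 1L]] <- data.frame(
    parent = target_parents, child = target,
    beta = draw_beta(length(target_parents)), stringsAsFactors = FALSE)

  nodes <- data.frame(
    id = c(top, mid, gen, target),
    layer = c(rep("top_tf", length(top)), rep("mid_tf", length(mid)),
              rep("gene", length(gen) + 1L)),
    stringsAsFactors = FALSE)

  structure(list(
    nodes = nodes,
    edges = do.call(rbind, edges),
    target_gene = target,
    target_parents = sort(target_parents)
  ), class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat("Planted regulatory network\n")
  tab <- table(x$nodes$layer)
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  edges: %d\n", nrow(x$edges)))
  cat(sprintf("  target: %s <- {%s}\n", x$target_gene,
              paste(x$target_parents, collapse = ", ")))
  invisible(x)
}

# Evaluate the structural equations: top TFs standard normal, every child the
# beta-weighted sum of its parents plus Gaussian noise, all on log2 scale.
realize_structural <- function(net, config) {
  n <- config$n_samples
  ids <- net$nodes$id
  z <- matrix(0, nrow = length(ids), ncol = n, dimnames = list(ids, NULL))
  is_top <- net$nodes$layer == "top_tf"
  z[is_top, ] <- stats::rnorm(sum(is_top) * n)

  # children in layer order: mid TFs first, then genes (parents always ready)
  order_ids <- c(ids[net$nodes$layer == "mid_tf"],
                 ids[net$nodes$layer == "gene"])
  by_child <- split(net$edges, net$edges$child)
  for (id in order_ids) {
    e <- by_child[[id]]
    sig <- if (is.null(e)) 0 else crossprod(e$beta, z[e$parent, , drop = FALSE])
    val <- as.numeric(sig) + stats::rnorm(n, sd = config$noise_sd)
    # standardize each child so latent log2 amplitude stays realistic at
    # any cascade depth; correlations are invariant to per-gene scale,
    # while unstandardized deep cascades would swing expression over
    # orders of magnitude and let single genes dominate library totals
    z[id, ] <- val / stats::sd(val)
  }
  z
}

#' Simulate a synthetic expression dataset over a planted network
#'
#' Realizes the planted network's structural equations on the log2 scale
#' (top TFs standard normal, each child a beta-weighted sum of its parents
#' plus `Normal(0, noise_sd)`), adds per-gene baseline abundances and planted
#' group-mean shifts for differential expression, and draws integer counts
#' from a Poisson (or negative binomial) layer whose mean is proportional to
#' `2^latent * gene length * library-size factor`.
#'
#' Planted DE genes receive, on the latent scale, a shift that ramps linearly
#' across the ordered condition groups from 0 to the planted log2 fold
#' change, so the true log2FC between the first and last group is exact by
#' construction.
#'
#' @param net a [sample_planted_network()] result.
#' @param config the same [simulation_config()].
#' @return An object of class `synthetic_dataset`: `counts` (integer matrix),
#'   `latent` (log2-scale matrix including baselines and DE shifts),
#'   `gene_lengths` (named bp vector), `tf_list`, `groups` (data.frame
#'   sample/condition), and `truth` (the network plus a per-gene DE table).
#' @export
simulate_expression <- function(net, config) {
  stopifnot(inherits(net, "planted_network"),
            inherits(config, "simulation_config"))
  if (!setequal(net$target_parents,
                intersect(net$target_parents, net$nodes$id))) {
    stop("network and config are inconsistent", call. = FALSE)
  }

  set.seed(derive_seed(config$seed, "latent"))
  z <- realize_structural(net, config)

  noise <- if (config$n_noise_tfs > 0)
    sprintf("TF_noise_%04d", seq_len(config$n_noise_tfs)) else character()
  silent <- if (config$n_unexpressed_tfs > 0)
    sprintf("TF_silent_%04d", seq_len(config$n_unexpressed_tfs)) else character()
  if (length(noise)) {
    # a noise TF has no parents: its structural part is all residual
    zn <- matrix(stats::rnorm(length(noise) * config$n_samples,
                              sd = config$noise_sd),
                 nrow = length(noise), dimnames = list(noise, NULL))
    z <- rbind(z, zn)
  }

  samples <- sprintf("S%03d", seq_len(config$n_samples))
  colnames(z) <- samples
  sizes <- rep(config$n_samples %/% config$n_conditions, config$n_conditions)
  extra <- config$n_samples %% config$n_conditions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cond <- rep(sprintf("G%d", seq_len(config$n_conditions)), times = sizes)
  groups <- data.frame(sample = samples, condition = cond,
                       stringsAsFactors = FALSE)

  # per-gene baseline abundance (log2) on top of the structural signal
  set.seed(derive_seed(config$seed, "baseline"))
  baseline <- stats::runif(nrow(z), config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  latent <- z + baseline

  # planted DE: linear ramp of the latent mean across ordered groups
  set.seed(derive_seed(config$seed, "de"))
  eligible <- setdiff(rownames(z), net$target_gene)
  n_de <- floor(config$de_fraction * length(eligible))
  de_tab <- data.frame(gene = character(), log2fc = numeric(),
                       direction = character(), stringsAsFactors = FALSE)
  if (n_de > 0) {
    de_genes <- sample(eligible, n_de)
    lfc <- stats::runif(n_de, config$de_log2fc_range[1],
                        config$de_log2fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
    ramp <- (match(cond, unique(cond)) - 1) /
      max(1L, config$n_conditions - 1L)
    latent[de_genes, ] <- latent[de_genes, , drop = FALSE] +
      outer(lfc, ramp)
    de_tab <- data.frame(gene = de_genes, log2fc = lfc,
                         direction = ifelse(lfc > 0, "up", "down"),
                         stringsAsFactors = FALSE)
  }

  all_ids <- c(rownames(latent), silent)

  set.seed(derive_seed(config$seed, "lengths"))
  gene_lengths <- round(stats::runif(length(all_ids),
                                     config$gene_length_range[1],
                                     config$gene_length_range[2]))
  names(gene_lengths) <- all_ids

  set.seed(derive_seed(config$seed, "counts"))
  lib <- stats::runif(config$n_samples, config$library_size_range[1],
                      config$library_size_range[2])
  # Poisson mean proportional to abundance x length x depth (kb and
  # millions-of-fragments units keep counts in a realistic range)
  mu <- sweep(2^latent * gene_lengths[rownames(latent)] / 1e3, 2,
              lib / 1e6, "*")
  counts <- matrix(0L, nrow = length(all_ids), ncol = config$n_samples,
                   dimnames = list(all_ids, samples))
  drawn <- if (is.null(config$dispersion)) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts[rownames(latent), ] <- drawn

  tf_list <- c(net$nodes$id[net$nodes$layer %in% c("top_tf", "mid_tf")],
               noise, silent)

  structure(list(
    counts = counts,
    latent = latent,
    gene_lengths = gene_lengths,
    tf_list = tf_list,
    groups = groups,
    truth = list(network = net, de = de_tab)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic expression dataset\n")
  cat(sprintf("  counts: %d genes x %d samples (%d TFs, %d condition groups)\n",
              nrow(x$counts), ncol(x$counts), length(x$tf_list),
              length(unique(x$groups$condition))))
  cat(sprintf("  planted edges: %d; planted DE genes: %d\n",
              nrow(x$truth$network$edges), nrow(x$truth$de)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the counts matrix, gene lengths, TF list and group map as TSV/text,
#' plus the full ground truth (network nodes, edges, coefficients, DE table)
#' as JSON.
#'
#' @param dataset a [simulate_expression()] result.
#' @param dir output directory, created if missing.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    tfs = file.path(dir, "tf_list.txt"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json")
  )
  matrix_to_tsv(dataset$counts, paths["counts"])
  write_tsv(data.frame(gene_id = names(dataset$gene_lengths),
                       length_bp = unname(dataset$gene_lengths)),
            paths["lengths"])
  writeLines(dataset$tf_list, paths["tfs"])
  write_tsv(dataset$groups, paths["groups"])
  net <- dataset$truth$network
  jsonlite::write_json(list(
    nodes = net$nodes, edges = net$edges,
    target_gene = net$target_gene, target_parents = net$target_parents,
    de = dataset$truth$de
  ), paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
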