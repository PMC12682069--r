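#' FPKM normalization of a counts matrix
#'
#' Fragments per kilobase of exon model per million mapped fragments:
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])`, where
#' `total[s]` is the column total of the input matrix (standing in for the
#' per-sample mapped-fragment total, which is unavailable downstream of
#' quantification). The resulting per-sample columns are invariant under
#' uniform scaling of that sample's counts.
#'
#' @param counts nonnegative integer matrix, genes x samples, with dimnames.
#' @param lengths named numeric vector of gene lengths in bp; must cover
#'   every row of `counts` with positive values.
#' @return FPKM matrix with the same dimnames; normalization parameters are
#'   attached as the `"provenance"` attribute.
#' @export
fpkm <- function(counts, lengths) {
  assert_matrix_like(counts, "counts")
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("no length for gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  bad <- names(len)[!is.finite(len) | len <= 0]
  if (length(bad)) {
    stop("non-positive length for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(utils::head(zero, 5), collapse = ", "), call. = FALSE)
  }
  out <- counts * 1e9 / outer(len, totals)
  attr(out, "provenance") <- list(method = "fpkm", scale = 1e9,
                                  totals = totals)
  out
}

#' Drop genes with zero total expression
#'
#' Removes rows whose sum is exactly zero, preserving the order of the
#' remaining rows, and reports how many were dropped.
#'
#' @param expr numeric expression matrix (FPKM or counts), genes x samples.
#' @return The filtered matrix; the number of dropped rows is attached as
#'   attribute `"n_dropped"`.
#' @export
drop_unexpressed <- function(expr) {
  assert_matrix_like(expr, "expr")
  keep <- rowSums(expr) != 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) with zero total expression dropped (",
            sum(keep), " retained)")
  }
  out <- expr[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Log2 transform with pseudocount
#'
#' @param expr nonnegative numeric matrix.
#' @param pseudocount positive offset added before taking log2 (default 1).
#' @return `log2(expr + pseudocount)` elementwise.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  log2(expr + pseudocount)
}

# Vectorized two-sided Welch t-test over matrix rows; cross-checked against
# stats::t.test in the unit tests.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # both groups constant: equal means -> no evidence; unequal -> certainty
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(mb[degenerate] == ma[degenerate], 1, 0)
  list(diff = mb - ma, p = p)
}

#' Pairwise differential-expression screen
#'
#' Compares two sample groups gene-by-gene on the `log2(FPKM + pseudocount)`
#' scale: the fold change is the difference of group means (B minus A) and
#' the p-value comes from a two-sided Welch t-test. A gene is called `up`
#' when `log2fc > fc_min` and `p < alpha`, `down` when `log2fc < -fc_min`
#' and `p < alpha`, otherwise `ns`. Defaults implement the screening rule
#' P < 0.05 and |log2FC| > 1.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param group_a,group_b disjoint character vectors of sample names, each
#'   of size >= 2.
#' @param alpha significance threshold on the (raw) p-value.
#' @param fc_min minimum |log2 fold change|.
#' @param pseudocount offset for the log transform.
#' @param adjust if `TRUE`, apply Benjamini-Hochberg correction before the
#'   significance call (off by default: the screening rule uses raw P).
#' @param comparison label stored with each record.
#' @return data.frame with columns gene, log2fc, p_value, direction,
#'   comparison.
#' @export
de_test <- function(expr, group_a, group_b, alpha = 0.05, fc_min = 1,
                    pseudocount = 1, adjust = FALSE,
                    comparison = "B_vs_A") {
  assert_matrix_like(expr, "expr")
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  l <- log_transform(expr, pseudocount)
  w <- welch_rows(l[, group_a, drop = FALSE], l[, group_b, drop = FALSE])
  p_used <- if (adjust) stats::p.adjust(w$p, "BH") else w$p
  direction <- rep("ns", nrow(expr))
  direction[w$diff > fc_min & p_used < alpha] <- "up"
  direction[w$diff < -fc_min & p_used < alpha] <- "down"
  data.frame(gene = rownames(expr), log2fc = w$diff, p_value = w$p,
             direction = direction, comparison = comparison,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of differentially expressed genes across comparisons
#'
#' A gene belongs to the DEG union when it is significant (direction `up` or
#' `down`) in at least one pairwise comparison; every per-comparison record
#' of a union member is kept.
#'
#' @param results list of [de_test()] data.frames.
#' @return list with `genes` (sorted character vector) and `records`
#'   (data.frame of all significant records of union members).
#' @export
deg_union <- function(results) {
  if (!length(results)) stop("need at least one comparison", call. = FALSE)
  all_rec <- do.call(rbind, results)
  sig <- all_rec[all_rec$direction != "ns", , drop = FALSE]
  list(genes = sort(unique(sig$gene)),
       records = sig[order(sig$gene, sig$comparison), , drop = FALSE])
}
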