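# Internal helpers shared across modules.

# Deterministic child seed from a base seed and a stage tag, kept inside the
# 32-bit integer range so set.seed() never overflows. A fixed tag per stage
# means e.g. adding samples never perturbs the network draw.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) * 10007 + h * 31) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix_like <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry row and column names", call. = FALSE)
  }
  invisible(x)
}

# Two-sided p-value for a Pearson correlation via the exact t-transform.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  p <- rep(1, length(r))
  ok <- df > 0 & abs(r) < 1
  tt <- abs(r[ok]) * sqrt(df / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[df > 0 & abs(r) >= 1] <- 0
  p
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

matrix_to_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
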