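# Consensus selection of feature TFs: a Boruta shadow-feature procedure over
# random-forest regression, repeated-split RF consensus, SVM recursive
# feature elimination, and the three-way intersection with the
# gene-significance screen.

#' Boruta configuration
#'
#' @param n_iter maximum number of shadow iterations (default 300).
#' @param alpha significance level of the sequential binomial test
#'   (default 0.01).
#' @param bonferroni apply Bonferroni correction across features
#'   (default `TRUE`).
#' @param ntree trees per random forest (default 500).
#' @param mtry features tried per split; `NULL` uses the regression default
#'   (a third of the real+shadow columns).
#' @param importance `"permutation"` (default; unscaled out-of-bag mean
#'   decrease in MSE) or `"impurity"` (mean decrease in node impurity).
#'   Out-of-bag permutation importance nulls out much of the apparent
#'   signal of features whose correlation with the response is in-sample
#'   chance, which impurity importance rewards; the raw (unscaled) measure
#'   separates weak true predictors from the shadow maximum better than
#'   the z-scored variant, whose per-tree variance normalization inflates
#'   rarely used features.
#' @param shadow_floor minimum size of the shadow pool (default 40).
#'   Shadows are permuted copies of the active features; once rejections
#'   shrink the active set, additional permuted copies are drawn so the
#'   pool never falls below `shadow_floor`. A pool that shrank freely would
#'   leave borderline features an ever-lower maximum to beat, inflating
#'   false confirmations late in the run.
#' @return list of class `boruta_config`.
#' @export
boruta_config <- function(n_iter = 300L, alpha = 0.01, bonferroni = TRUE,
                          ntree = 500L, mtry = NULL,
                          importance = c("permutation", "impurity"),
                          shadow_floor = 40L) {
  stopifnot(n_iter >= 1, alpha > 0, alpha < 1, shadow_floor >= 1)
  structure(list(n_iter = as.integer(n_iter), alpha = alpha,
                 bonferroni = isTRUE(bonferroni), ntree = as.integer(ntree),
                 mtry = mtry, importance = match.arg(importance),
                 shadow_floor = as.integer(shadow_floor)),
            class = "boruta_config")
}

#' Boruta shadow-feature selection over random-forest regression
#'
#' Each iteration appends permuted "shadow" copies of the active features
#' (the pool never falling below `shadow_floor`), fits a random-forest
#' regressor, and scores a hit for every feature whose importance
#' (out-of-bag permutation importance by default) exceeds the maximum
#' shadow importance. Undecided features are tested after each iteration
#' with a
#' two-sided binomial test of their cumulative hit count against
#' `Binomial(i, 0.5)` (Bonferroni-corrected across the initial feature
#' count): significantly more hits than chance confirms a feature,
#' significantly fewer rejects it (rejected features leave the model).
#' Whatever is still undecided after `n_iter` iterations stays tentative.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y numeric response vector.
#' @param cfg a [boruta_config()].
#' @param seed integer seed (decisions are deterministic given it).
#' @return list with `decision` (named factor-like character vector:
#'   confirmed/tentative/rejected), `hits`, `n_iter_used`, and
#'   `mean_importance`.
#' @export
boruta <- function(X, y, cfg = boruta_config(), seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("response y is constant", call. = FALSE)
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped: ",
            paste(utils::head(colnames(X)[const], 5), collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  features <- colnames(X)
  p0 <- length(features)
  decision <- stats::setNames(rep("tentative", p0), features)
  hits <- stats::setNames(integer(p0), features)
  imp_sum <- stats::setNames(numeric(p0), features)
  thr <- cfg$alpha / if (cfg$bonferroni) p0 else 1

  set.seed(derive_seed(seed, "boruta"))
  used <- 0L
  for (i in seq_len(cfg$n_iter)) {
    active <- features[decision != "rejected"]
    if (!any(decision == "tentative")) break
    used <- i
    Xa <- X[, active, drop = FALSE]
    # tile permuted copies of the active features until the pool reaches
    # shadow_floor; the null bar must not collapse as rejections shrink
    # the active set
    n_copies <- max(1L, ceiling(cfg$shadow_floor / ncol(Xa)))
    shadow <- do.call(cbind, lapply(seq_len(n_copies), function(ci) {
      s <- apply(Xa, 2, sample)
      colnames(s) <- paste0(".shadow", ci, ".", colnames(Xa))
      s
    }))
    perm <- cfg$importance == "permutation"
    fit <- ranger::ranger(
      x = cbind(Xa, shadow), y = y, num.trees = cfg$ntree,
      mtry = cfg$mtry %||% max(1, floor((ncol(Xa) + ncol(shadow)) / 3)),
      importance = if (perm) "permutation" else "impurity",
      scale.permutation.importance = FALSE,
      num.threads = 1, seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$variable.importance
    smax <- max(imp[colnames(shadow)])
    real_imp <- imp[active]
    imp_sum[active] <- imp_sum[active] + real_imp
    hit <- active[real_imp > smax]
    hits[hit] <- hits[hit] + 1L

    und <- features[decision == "tentative"]
    h <- hits[und]
    p_hi <- stats::pbinom(h - 1L, i, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(h, i, 0.5)
    p2 <- pmin(1, 2 * pmin(p_hi, p_lo))
    decision[und[p2 <= thr & h > i / 2]] <- "confirmed"
    decision[und[p2 <= thr & h < i / 2]] <- "rejected"
  }

  if (any(const)) {
    dropped <- stats::setNames(rep("rejected", sum(const)),
                               names(const)[const])
    decision <- c(decision, dropped)
  }
  list(decision = decision,
       confirmed = sort(names(decision)[decision == "confirmed"]),
       hits = hits, n_iter_used = used,
       mean_importance = ifelse(used > 0, imp_sum / used, imp_sum))
}

# Repeated k-fold CV tuning of mtry, minimizing mean squared error.
tune_mtry <- function(X, y, grid, folds, repeats, ntree) {
  n <- nrow(X)
  mse <- stats::setNames(numeric(length(grid)), grid)
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (sum(!tr) < 2) stop("fold size < 2", call. = FALSE)
      for (gi in seq_along(grid)) {
        fit <- randomForest::randomForest(
          x = X[tr, , drop = FALSE], y = y[tr],
          mtry = grid[gi], ntree = ntree)
        pred <- stats::predict(fit, X[!tr, , drop = FALSE])
        mse[gi] <- mse[gi] + mean((pred - y[!tr])^2)
      }
    }
  }
  grid[which.min(mse)]
}

#' Repeated-split random-forest consensus selection
#'
#' Repeats `n_runs` times: split the samples into a training and test set
#' (default 75/25), tune the forest's features-per-split parameter by
#' repeated k-fold cross-validation minimizing mean squared error, run
#' [boruta()] on the training split, fit a forest on the confirmed features
#' and record the held-out R-squared. The consensus set is the intersection
#' of the confirmed sets across runs.
#'
#' @param X samples x features matrix with column names.
#' @param y numeric response.
#' @param n_runs number of independent splits (default 10).
#' @param train_frac training fraction (default 0.75).
#' @param cv_folds,cv_repeats folds and repeats of the mtry tuning CV
#'   (defaults 10 and 5).
#' @param mtry_grid candidate mtry values; default `p/3`, `sqrt(p)`, `p/2`.
#' @param boruta_cfg a [boruta_config()].
#' @param include_tentative count tentative features as selected
#'   (default `FALSE`).
#' @param seed integer seed.
#' @return list with `rf_set` (intersection across runs) and `runs`
#'   (per-run confirmed sets, tuned mtry, test R-squared).
#' @export
rf_consensus <- function(X, y, n_runs = 10L, train_frac = 0.75,
                         cv_folds = 10L, cv_repeats = 5L,
                         mtry_grid = NULL, boruta_cfg = boruta_config(),
                         include_tentative = FALSE, seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  n <- nrow(X)
  n_train <- round(train_frac * n)
  if (n_train < cv_folds * 2 || n - n_train < 2) {
    stop("not enough samples for the requested split and folds", call. = FALSE)
  }
  p <- ncol(X)
  grid <- mtry_grid %||% sort(unique(pmax(1L, floor(c(p / 3, sqrt(p), p / 2)))))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rs <- derive_seed(seed, paste0("rf_run_", r))
    set.seed(rs)
    tr_idx <- sample.int(n, n_train)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xte <- X[-tr_idx, , drop = FALSE]; yte <- y[-tr_idx]
    mtry <- tune_mtry(Xtr, ytr, grid, cv_folds, cv_repeats, boruta_cfg$ntree)
    cfg_r <- boruta_cfg
    cfg_r$mtry <- NULL  # boruta uses its own wide default over real+shadow
    bres <- boruta(Xtr, ytr, cfg_r, seed = rs)
    sel <- bres$confirmed
    if (include_tentative) {
      sel <- sort(c(sel, names(bres$decision)[bres$decision == "tentative"]))
    }
    r2 <- NA_real_
    if (length(sel)) {
      set.seed(derive_seed(rs, "final_fit"))
      fit <- randomForest::randomForest(
        x = Xtr[, sel, drop = FALSE], y = ytr,
        mtry = min(mtry, length(sel)), ntree = boruta_cfg$ntree)
      pred <- stats::predict(fit, Xte[, sel, drop = FALSE])
      r2 <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    }
    runs[[r]] <- list(selected = sel, mtry = mtry, test_r2 = r2)
  }
  rf_set <- Reduce(intersect, lapply(runs, `[[`, "selected"))
  list(rf_set = sort(rf_set), runs = runs)
}

#' SVM-RFE configuration
#'
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost_grid penalty parameter candidates (default 0.1, 1).
#' @param gamma_grid RBF kernel width candidates (default 0.1, 1), expressed
#'   relative to the `1/p` library default: the effective kernel width is
#'   `gamma / p` for `p` features (see `gamma_scale`). An absolute gamma of
#'   0.1 at hundreds of standardized features collapses the RBF kernel to
#'   near-identity, so the relative scale is what keeps the stated grid
#'   meaningful across feature-set sizes.
#' @param gamma_scale if `TRUE` (default) `gamma_grid` entries are
#'   multipliers of `1/p`; if `FALSE` they are absolute kernel widths.
#' @param subset_start,subset_step candidate subset sizes run from
#'   `subset_start` to the full feature count in steps of `subset_step`
#'   (defaults 50 and 100).
#' @param k_folds cross-validation folds (default 10).
#' @param top_k size of the reported key-regulator set (default 30).
#' @param elim_frac fraction of remaining features eliminated per RFE round
#'   (default 0.1, minimum one feature).
#' @return list of class `rfe_config`.
#' @export
rfe_config <- function(kernel = c("radial", "linear"),
                       cost_grid = c(0.1, 1), gamma_grid = c(0.1, 1),
                       gamma_scale = TRUE,
                       subset_start = 50L, subset_step = 100L,
                       k_folds = 10L, top_k = 30L, elim_frac = 0.1) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1,
            subset_start >= 1)
  structure(list(kernel = match.arg(kernel), cost_grid = cost_grid,
                 gamma_grid = gamma_grid, gamma_scale = isTRUE(gamma_scale),
                 subset_start = as.integer(subset_start),
                 subset_step = as.integer(subset_step),
                 k_folds = as.integer(k_folds), top_k = as.integer(top_k),
                 elim_frac = elim_frac), class = "rfe_config")
}

svr_fit <- function(X, y, cfg, cost, gamma) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = cfg$kernel,
             cost = cost, gamma = gamma, scale = FALSE)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Per-feature importance for one fitted SVR: squared weight coefficients for
# the linear kernel; for the RBF kernel, the degradation of validation RMSE
# when that feature's validation column is permuted (kernel-agnostic).
svr_importance <- function(fit, cfg, Xtr, Xval, yval, perm) {
  feats <- colnames(Xtr)
  if (cfg$kernel == "linear") {
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    return(stats::setNames(w^2, feats))
  }
  base <- rmse(yval, stats::predict(fit, Xval))
  vapply(feats, function(f) {
    Xp <- Xval
    Xp[, f] <- Xp[perm, f]
    rmse(yval, stats::predict(fit, Xp)) - base
  }, numeric(1))
}

#' SVM recursive feature elimination with cross-validated subset selection
#'
#' Features are z-scored, hyperparameters (C, gamma) are tuned on the full
#' feature set by k-fold cross-validated RMSE, and within each fold an
#' iterative elimination run produces a full ranking: each round fits a
#' support-vector regressor on the surviving features, scores per-feature
#' importance (squared weights for the linear kernel; permutation
#' degradation of held-out RMSE for the RBF kernel) and eliminates the
#' worst `elim_frac` of the remainder (at least one). Ranks are assigned in
#' elimination order (last survivor ranks first); fold-wise ranks are
#' averaged, with ties broken lexicographically by feature name. Candidate
#' subset sizes `subset_start, subset_start + subset_step, ..., p` are
#' evaluated by cross-validated RMSE using the top-ranked features; the
#' argmin (ties to the smaller subset) is the best subset, and the `top_k`
#' features by average rank form the key-regulator set.
#'
#' @param X samples x features matrix with column names.
#' @param y numeric response.
#' @param cfg an [rfe_config()].
#' @param seed integer seed.
#' @return list with `ranking` (data.frame: feature, avg_rank, rank),
#'   `rfe_set` (top `top_k` features), `best_size`, `rmse_by_size`
#'   (data.frame: size, rmse), and `tuned` (chosen cost/gamma).
#' @export
svm_rfe <- function(X, y, cfg = rfe_config(), seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped before RFE")
    X <- X[, !const, drop = FALSE]
  }
  X <- scale(X)
  p <- ncol(X); n <- nrow(X)
  feats <- colnames(X)

  set.seed(derive_seed(seed, "rfe"))
  fold <- sample(rep_len(seq_len(cfg$k_folds), n))

  cv_rmse <- function(cols, cost, gamma) {
    errs <- vapply(seq_len(cfg$k_folds), function(f) {
      tr <- fold != f
      fit <- svr_fit(X[tr, cols, drop = FALSE], y[tr], cfg, cost, gamma)
      rmse(y[!tr], stats::predict(fit, X[!tr, cols, drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }

  # hyperparameter grid on the full feature set
  gammas <- if (cfg$gamma_scale) cfg$gamma_grid / p else cfg$gamma_grid
  grid <- expand.grid(cost = cfg$cost_grid, gamma = gammas)
  grid$rmse <- vapply(seq_len(nrow(grid)), function(i) {
    cv_rmse(feats, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  best <- grid[which.min(grid$rmse), ]

  # per-fold recursive elimination
  rank_mat <- matrix(NA_real_, nrow = p, ncol = cfg$k_folds,
                     dimnames = list(feats, NULL))
  for (f in seq_len(cfg$k_folds)) {
    tr <- fold != f
    perm <- sample.int(sum(!tr))
    remaining <- feats
    next_rank <- p
    while (length(remaining) > 1) {
      fit <- svr_fit(X[tr, remaining, drop = FALSE], y[tr], cfg,
                     best$cost, best$gamma)
      imp <- svr_importance(fit, cfg, X[tr, remaining, drop = FALSE],
                            X[!tr, remaining, drop = FALSE], y[!tr], perm)
      m <- max(1L, floor(cfg$elim_frac * length(remaining)))
      ord <- remaining[order(imp, remaining)]
      drop <- ord[seq_len(m)]
      # worst importance gets the worst remaining rank
      rank_mat[drop, f] <- seq(next_rank, by = -1, length.out = m)
      next_rank <- next_rank - m
      remaining <- setdiff(remaining, drop)
    }
    rank_mat[remaining, f] <- 1
  }
  avg_rank <- rowMeans(rank_mat)
  ord <- order(avg_rank, feats)
  ranking <- data.frame(feature = feats[ord], avg_rank = avg_rank[ord],
                        rank = seq_len(p), row.names = NULL,
                        stringsAsFactors = FALSE)

  sizes <- unique(c(seq(min(cfg$subset_start, p), p, by = cfg$subset_step), p))
  rmse_by_size <- data.frame(size = sizes, rmse = vapply(sizes, function(s) {
    cv_rmse(ranking$feature[seq_len(s)], best$cost, best$gamma)
  }, numeric(1)))
  best_size <- with(rmse_by_size, min(size[rmse == min(rmse)]))

  top_k <- cfg$top_k
  if (top_k > p) {
    warning("top_k exceeds the feature count; returning all features")
    top_k <- p
  }
  list(ranking = ranking,
       rfe_set = ranking$feature[seq_len(top_k)],
       best_size = best_size, rmse_by_size = rmse_by_size,
       tuned = list(cost = best$cost, gamma = best$gamma,
                    cv_rmse = best$rmse))
}

#' Three-way consensus of feature-selection methods
#'
#' Intersects the gene-significance set, the RF/Boruta consensus set and the
#' SVM-RFE set, annotating each consensus member with its supporting
#' statistics where the corresponding tables are supplied.
#'
#' @param gs_set,rf_set,rfe_set character vectors over one feature universe.
#' @param gs_table optional [gene_significance()] table.
#' @param boruta_decision optional named decision vector from [boruta()].
#' @param rfe_ranking optional ranking data.frame from [svm_rfe()].
#' @return list with `consensus` (sorted character vector) and `table`
#'   (per-feature membership and annotations).
#' @export
consensus_features <- function(gs_set, rf_set, rfe_set, gs_table = NULL,
                               boruta_decision = NULL, rfe_ranking = NULL) {
  consensus <- sort(Reduce(intersect, list(gs_set, rf_set, rfe_set)))
  universe <- sort(unique(c(gs_set, rf_set, rfe_set)))
  tab <- data.frame(feature = universe,
                    in_gs = universe %in% gs_set,
                    in_rf = universe %in% rf_set,
                    in_rfe = universe %in% rfe_set,
                    consensus = universe %in% consensus,
                    stringsAsFactors = FALSE)
  if (!is.null(gs_table)) {
    tab$GS <- gs_table$GS[match(tab$feature, gs_table$gene)]
    tab$p_gs <- gs_table$p_value[match(tab$feature, gs_table$gene)]
  }
  if (!is.null(boruta_decision)) {
    tab$boruta <- unname(boruta_decision[tab$feature])
  }
  if (!is.null(rfe_ranking)) {
    tab$avg_rank <- rfe_ranking$avg_rank[match(tab$feature,
                                               rfe_ranking$feature)]
  }
  list(consensus = consensus, table = tab)
}
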