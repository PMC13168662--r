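#' Cross-validation configuration
#'
#' @param outer_folds,inner_folds fold counts for the outer evaluation loop
#'   and the nested penalty-selection loop (default tenfold for both).
#' @param n_penalties per-modality penalty-grid size for the nested search
#'   (the grid is log-spaced from the training [penalty_max()] down over
#'   three decades).
#' @param stratified stratify folds by class (recommended: carriers are ~5%
#'   of the training population, so unstratified folds risk carrier-free
#'   folds).
#' @param seed integer seed controlling fold assignment.
#' @param l2 softmax ridge penalty.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 10L, n_penalties = 8L,
                      stratified = TRUE, seed = 1L, l2 = 1e-6) {
  if (outer_folds < 2 || inner_folds < 2) stop_validation("cv_config: folds must be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_penalties = as.integer(n_penalties),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed), l2 = l2),
            class = "cv_config")
}

#' Assign samples to cross-validation folds
#'
#' Deterministic given the seed. Stratified assignment shuffles each class
#' separately and deals fold ids in rotation, so class counts per fold are
#' balanced within one. If a class has fewer members than folds,
#' stratification degrades gracefully (some folds simply lack that class)
#' with a warning.
#'
#' @param labels 0/1 labels (used only when `stratified`).
#' @param k number of folds (`2 <= k <= n`).
#' @param stratified balance classes across folds.
#' @param seed integer seed.
#' @return Integer fold assignment in `1..k`.
#' @export
make_folds <- function(labels, k, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (k > n) stop_validation("make_folds: k exceeds the number of samples")
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < k)
          warning(sprintf("class %s has fewer members (%d) than folds (%d); stratification degrades",
                          cls, length(idx), k))
        folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

# Impute + normalize a train/test split of raw (possibly missing) matrices,
# fitting everything on the training rows only. Returns normalized train and
# test matrices.
.prepare_split <- function(mat, train_idx, test_idx, modality) {
  tr <- feature_table(mat[train_idx, , drop = FALSE], modality)
  te <- feature_table(mat[test_idx, , drop = FALSE], modality)
  imp <- impute_missing(tr)
  norm <- fit_normalization(imp$table)
  te_imp <- impute_missing(te, imp$record)$table
  list(train = apply_normalization(imp$table, norm)$values,
       test = apply_normalization(te_imp, norm)$values)
}

# Inner-CV grid search over (beta1, beta2) pairs. Grids are fixed from the
# training set's penalty_max per modality; each inner fold refits
# imputation, normalization, both lasso paths and the softmax on the inner
# training portion only. Selection maximizes mean inner-fold out-of-sample
# AUC of the fused pipeline; pairs are scanned from sparsest to densest and
# only strict improvements are kept, so exact ties go to larger penalties.
.grid_search_penalties <- function(mirna, meta, y, inner_folds, n_penalties,
                                   seed, l2, beta_min_ratio = 1e-3) {
  imp1 <- impute_missing(feature_table(mirna, "miRNA"))$table
  imp2 <- impute_missing(feature_table(meta, "metadata"))$table
  n1 <- fit_normalization(imp1)
  n2 <- fit_normalization(imp2)
  g1 <- penalty_grid(penalty_max(apply_normalization(imp1, n1)$values, y), n_penalties, beta_min_ratio)
  g2 <- penalty_grid(penalty_max(apply_normalization(imp2, n2)$values, y), n_penalties, beta_min_ratio)
  folds <- make_folds(y, inner_folds, stratified = TRUE, seed = seed)
  G1 <- length(g1)
  G2 <- length(g2)
  auc_sum <- matrix(0, G1, G2)
  auc_n <- matrix(0L, G1, G2)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    s1 <- .prepare_split(mirna, tr, te, "miRNA")
    s2 <- .prepare_split(meta, tr, te, "metadata")
    V1 <- cd_lasso_path(s1$train, y[tr], g1, 1e-8, 100000L, numeric(0))
    V2 <- cd_lasso_path(s2$train, y[tr], g2, 1e-8, 100000L, numeric(0))
    P1tr <- s1$train %*% V1
    P2tr <- s2$train %*% V2
    P1te <- s1$test %*% V1
    P2te <- s2$test %*% V2
    for (a in seq_len(G1)) for (b in seq_len(G2)) {
      proj_tr <- cbind(P1tr[, a], P2tr[, b])
      sm <- train_softmax(proj_tr, y[tr], l2 = l2)
      prob <- predict_proba(cbind(P1te[, a], P2te[, b]), sm$w1, sm$b1)
      auc_sum[a, b] <- auc_sum[a, b] + auc_mw(prob, y[te])
      auc_n[a, b] <- auc_n[a, b] + 1L
    }
  }
  if (all(auc_n == 0)) stop_validation("nested selection: every inner fold was degenerate")
  mean_auc <- auc_sum / pmax(auc_n, 1L)
  mean_auc[auc_n == 0] <- -Inf
  best <- c(1L, 1L)
  best_auc <- -Inf
  for (a in seq_len(G1)) for (b in seq_len(G2)) {
    if (mean_auc[a, b] > best_auc + 1e-12) {
      best_auc <- mean_auc[a, b]
      best <- c(a, b)
    }
  }
  list(beta1 = g1[best[1]], beta2 = g2[best[2]], mean_auc = best_auc,
       grid1 = g1, grid2 = g2)
}

#' Nested penalty selection on a training cohort
#'
#' Grid search over per-modality penalty paths by inner cross-validation of
#' the full fused pipeline (imputation, normalization, lasso, softmax all
#' refit per inner fold); the pair maximizing mean inner-fold out-of-sample
#' AUC is returned, with exact ties resolved toward larger (sparser)
#' penalties.
#'
#' @param cohort a labeled training [cohort()].
#' @param config a [cv_config()].
#' @return List with `beta1`, `beta2`, the achieved `mean_auc`, and the grids.
#' @export
nested_select_penalties <- function(cohort, config = cv_config()) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$labels)) stop_validation("nested_select_penalties: cohort has no labels")
  if (length(unique(cohort$labels)) < 2)
    stop_validation("nested_select_penalties: training fold must contain both classes")
  .grid_search_penalties(cohort$mirna$values, cohort$metadata$values,
                         cohort$labels, config$inner_folds, config$n_penalties,
                         config$seed, config$l2)
}

#' Leakage-free nested cross-validation of the fusion pipeline
#'
#' For each outer fold, imputation, normalization, the two lasso fits, the
#' softmax, and the score scaling are all fit on the training portion only
#' (with the penalties chosen by nested inner cross-validation on that same
#' portion) and applied to the held-out portion. The out-of-fold predictions
#' for all folds are concatenated and evaluated once against the full label
#' vector — the pooled scheme, which differs from averaging per-fold AUCs.
#'
#' @param cohort a labeled [cohort()].
#' @param config a [cv_config()].
#' @param k1,k2,prescreen optional support limits for the k-constrained
#'   variant; when a limit is set for a modality the inner search is skipped
#'   for it and the densest path fit within the limit is used.
#' @return An object of class `cv_result`: per-sample out-of-fold
#'   `probability` and `score`, `fold` assignment, per-fold chosen penalties,
#'   the pooled `roc` (a `roc_result`), and the pooled Youden threshold.
#' @export
cross_validate <- function(cohort, config = cv_config(), k1 = NULL, k2 = NULL,
                           prescreen = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$labels
  if (is.null(y)) stop_validation("cross_validate: cohort has no labels")
  n <- length(y)
  folds <- make_folds(y, config$outer_folds, config$stratified, config$seed)
  prob <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  fold_betas <- data.frame(fold = sort(unique(folds)), beta1 = NA_real_, beta2 = NA_real_)
  constrained <- !is.null(k1) || !is.null(k2)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f)
    te <- which(folds == f)
    s1 <- .prepare_split(cohort$mirna$values, tr, te, "miRNA")
    s2 <- .prepare_split(cohort$metadata$values, tr, te, "metadata")
    if (constrained) {
      # a NULL limit means "unconstrained": the path-end fit is used
      fit1 <- support_constrained_fit(s1$train, y[tr],
                                      if (is.null(k1)) ncol(s1$train) else k1,
                                      prescreen = prescreen,
                                      n_points = config$n_penalties * 3L)
      fit2 <- support_constrained_fit(s2$train, y[tr],
                                      if (is.null(k2)) ncol(s2$train) else k2,
                                      prescreen = prescreen,
                                      n_points = config$n_penalties * 3L)
    } else {
      sel <- .grid_search_penalties(cohort$mirna$values[tr, , drop = FALSE],
                                    cohort$metadata$values[tr, , drop = FALSE],
                                    y[tr], config$inner_folds, config$n_penalties,
                                    config$seed + f, config$l2)
      fit1 <- solve_lasso(s1$train, y[tr], sel$beta1)
      fit2 <- solve_lasso(s2$train, y[tr], sel$beta2)
    }
    fold_betas$beta1[fold_betas$fold == f] <- fit1$beta
    fold_betas$beta2[fold_betas$fold == f] <- fit2$beta
    proj_tr <- cbind(drop(s1$train %*% fit1$v), drop(s2$train %*% fit2$v))
    sm <- train_softmax(proj_tr, y[tr], l2 = config$l2)
    raw_tr <- drop(proj_tr %*% sm$w1) + sm$b1
    smin <- min(raw_tr)
    smax <- max(raw_tr)
    if (!(smax > smin)) smax <- smin + 1
    proj_te <- cbind(drop(s1$test %*% fit1$v), drop(s2$test %*% fit2$v))
    prob[te] <- predict_proba(proj_te, sm$w1, sm$b1)
    score[te] <- brca_score(proj_te, sm$w1, sm$b1, smin, smax, clip = TRUE)
  }
  roc <- roc_auc(prob, y)
  structure(list(probability = prob, score = score, fold = folds,
                 labels = y, fold_betas = fold_betas, roc = roc,
                 youden = roc$youden, config = config,
                 k1 = k1, k2 = k2),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, pooled AUC = %.4f (95%% CI %.4f-%.4f), Youden t = %.4g>\n",
              length(unique(x$fold)), x$roc$auc, x$roc$ci[1], x$roc$ci[2], x$youden))
  invisible(x)
}
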