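#' Project a cohort to the fused two-dimensional space
#'
#' Column 1 is the normalized miRNA matrix times its sparse coefficient
#' vector, column 2 the normalized metadata matrix times its vector:
#' `X = [X1 v1, X2 v2]`.
#'
#' @param cohort an imputed [cohort()].
#' @param v1,v2 named coefficient vectors over the miRNA / metadata features.
#' @param norm_params list with `normalization_params` elements `mirna` and
#'   `metadata` (fitted on the training data).
#' @return A samples x 2 numeric matrix with columns `mirna`, `metadata`.
#' @export
project <- function(cohort, v1, v2, norm_params) {
  stopifnot(inherits(cohort, "cohort"))
  x1 <- apply_normalization(cohort$mirna, norm_params$mirna)$values
  x2 <- apply_normalization(cohort$metadata, norm_params$metadata)$values
  if (!all(names(v1) %in% colnames(x1)) || !all(names(v2) %in% colnames(x2)))
    stop_validation("coefficient vectors name features absent from the cohort")
  proj <- cbind(mirna = drop(x1[, names(v1), drop = FALSE] %*% v1),
                metadata = drop(x2[, names(v2), drop = FALSE] %*% v2))
  rownames(proj) <- cohort$sample_ids
  proj
}

#' Train the antisymmetric two-class softmax
#'
#' The two-class softmax `P(y = j | x) = exp(x'w_j + b_j) / sum_i exp(x'w_i +
#' b_i)` is parameterized antisymmetrically with `w_0 = -w_1`, `b_0 = -b_1`,
#' which makes it a logistic regression with logit `2 (x'w_1 + b_1)`.
#' Training minimizes the cross-entropy plus a tiny L2 penalty (so a finite
#' optimum exists even when the 2-D projection is linearly separable) by
#' Newton's method from a zero start; the fit is deterministic.
#'
#' @param projected samples x 2 matrix from [project()].
#' @param y 0/1 labels (both classes required).
#' @param l2 ridge penalty on `(w_1, b_1)` (default `1e-6`).
#' @param seed unused (the optimizer is deterministic); accepted so callers
#'   can thread a seed through the whole pipeline uniformly.
#' @return List with `w1` (length-2) and `b1` (scalar).
#' @export
train_softmax <- function(projected, y, l2 = 1e-6, seed = NULL) {
  Z <- cbind(as.matrix(projected), 1)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop_validation("train_softmax: both classes must be present")
  theta <- numeric(3)
  for (it in 1:200) {
    eta <- drop(Z %*% theta)
    p <- plogis(2 * eta)
    grad <- drop(crossprod(Z, 2 * (p - y))) + 2 * l2 * theta
    w <- 4 * p * (1 - p)
    H <- crossprod(Z, Z * w) + diag(2 * l2 + 1e-12, 3)
    step <- solve(H, grad)
    theta <- theta - step
    if (max(abs(step)) < 1e-12) break
  }
  list(w1 = unname(theta[1:2]), b1 = unname(theta[3]))
}

#' Carrier probability from the softmax
#'
#' Evaluates `P(y = 1 | x) = e^{x'w1 + b1} / (e^{x'w1 + b1} + e^{-(x'w1 +
#' b1)})`, computed overflow-safely as the logistic function of twice the raw
#' score.
#'
#' @inheritParams train_softmax
#' @param w1,b1 softmax weights and bias for class 1.
#' @return Probability vector in `[0, 1]`.
#' @export
predict_proba <- function(projected, w1, b1) {
  plogis(2 * (drop(as.matrix(projected) %*% w1) + b1))
}

#' BRCAness score
#'
#' The raw score `b_s = x'w1 + b1` translated and scaled to `[0, 1]`:
#' `(raw - score_min) / (score_max - score_min)`, where the anchors are the
#' raw-score extremes of the training set. External samples falling outside
#' the training range are clipped into `[0, 1]` when `clip = TRUE`.
#'
#' @inheritParams predict_proba
#' @param score_min,score_max training raw-score extremes (`score_max` must
#'   exceed `score_min`).
#' @param clip clip to `[0, 1]` (used for external cohorts).
#' @return Score vector.
#' @export
brca_score <- function(projected, w1, b1, score_min, score_max, clip = FALSE) {
  if (!(score_max > score_min)) stop_validation("brca_score: degenerate scaling (score_max <= score_min)")
  raw <- drop(as.matrix(projected) %*% w1) + b1
  s <- (raw - score_min) / (score_max - score_min)
  if (clip) s <- pmin(pmax(s, 0), 1)
  s
}

#' Threshold probabilities into class calls
#'
#' A sample is called a likely carrier iff its probability strictly exceeds
#' the threshold `t`.
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param t threshold in `[0, 1]`.
#' @return Integer 0/1 calls.
#' @export
classify <- function(probabilities, t) {
  if (t < 0 || t > 1) stop_validation("classify: t must be in [0, 1]")
  as.integer(probabilities > t)
}

#' Fit the full fusion model on a training cohort
#'
#' Runs the training pipeline end to end: mean imputation, per-feature
#' normalization, one lasso per modality (optionally support-constrained to
#' at most `k1` / `k2` non-zeros), the 2-D projection, the antisymmetric
#' softmax, and min-max scaling of the raw score. Every fitted parameter
#' depends only on the supplied cohort, so the returned bundle can be frozen
#' and applied to external data.
#'
#' @param cohort a labeled [cohort()].
#' @param beta1,beta2 lasso penalties for the miRNA / metadata modality
#'   (ignored for a modality with a `k` limit, where the penalty is chosen
#'   from the path).
#' @param k1,k2 optional maximum support sizes.
#' @param prescreen optional prescreen size used with `k1`/`k2` (absolute
#'   Pearson correlation ranking).
#' @param l2 softmax ridge penalty.
#' @param threshold operating probability threshold stored in the bundle
#'   (typically the Youden threshold from cross-validation).
#' @param n_points penalty-grid size for constrained fits.
#' @return An object of class `fusion_model`.
#' @export
fit_fusion_model <- function(cohort, beta1, beta2, k1 = NULL, k2 = NULL,
                             prescreen = NULL, l2 = 1e-6, threshold = 0.5,
                             n_points = 20L) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$labels)) stop_validation("fit_fusion_model: cohort has no labels")
  y <- cohort$labels
  imp1 <- impute_missing(cohort$mirna)
  imp2 <- impute_missing(cohort$metadata)
  norm <- list(mirna = fit_normalization(imp1$table),
               metadata = fit_normalization(imp2$table))
  x1 <- apply_normalization(imp1$table, norm$mirna)$values
  x2 <- apply_normalization(imp2$table, norm$metadata)$values
  fit1 <- if (is.null(k1)) solve_lasso(x1, y, beta1)
          else support_constrained_fit(x1, y, k1, prescreen = prescreen, n_points = n_points)
  fit2 <- if (is.null(k2)) solve_lasso(x2, y, beta2)
          else support_constrained_fit(x2, y, k2, prescreen = prescreen, n_points = n_points)
  proj <- cbind(mirna = drop(x1 %*% fit1$v), metadata = drop(x2 %*% fit2$v))
  sm <- train_softmax(proj, y, l2 = l2)
  raw <- drop(proj %*% sm$w1) + sm$b1
  score_min <- min(raw)
  score_max <- max(raw)
  if (!(score_max > score_min)) {
    # fully degenerate projection (e.g. k1 = k2 = 0): fall back to a unit span
    score_max <- score_min + 1
  }
  structure(list(norm = norm,
                 imputation = list(mirna = imp1$record, metadata = imp2$record),
                 v1 = fit1$v, v2 = fit2$v,
                 beta1 = fit1$beta, beta2 = fit2$beta,
                 w1 = sm$w1, b1 = sm$b1,
                 score_min = score_min, score_max = score_max,
                 threshold = threshold, l2 = l2),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("<fusion_model: |support(v1)| = %d/%d, |support(v2)| = %d/%d,\n",
                     "  w1 = (%.4f, %.4f), b1 = %.4f, threshold = %.4g>\n"),
              sum(x$v1 != 0), length(x$v1), sum(x$v2 != 0), length(x$v2),
              x$w1[1], x$w1[2], x$b1, x$threshold))
  invisible(x)
}

#' Apply a frozen fusion model to a cohort
#'
#' Imputation fills, normalization, coefficient vectors, softmax parameters,
#' score anchors and the decision threshold all come from the bundle; nothing
#' is refit. Cohorts missing any panel feature raise an error (no silent
#' zero-filling).
#'
#' @param object a `fusion_model`.
#' @param cohort a [cohort()] sharing the model's feature panel.
#' @param clip clip scores to `[0, 1]` (the external-cohort convention).
#' @param ... unused.
#' @return A data.frame with the 2-D projection, carrier probability,
#'   BRCAness score, and thresholded call per sample.
#' @export
predict.fusion_model <- function(object, cohort, clip = TRUE, ...) {
  stopifnot(inherits(cohort, "cohort"))
  missing1 <- setdiff(names(object$v1), feature_ids(cohort$mirna))
  missing2 <- setdiff(names(object$v2), feature_ids(cohort$metadata))
  if (length(missing1) || length(missing2))
    stop_validation("cohort lacks panel feature(s): %s",
                    paste(c(missing1, missing2), collapse = ", "))
  t1 <- impute_missing(cohort$mirna, object$imputation$mirna)$table
  t2 <- impute_missing(cohort$metadata, object$imputation$metadata)$table
  imputed <- cohort
  imputed$mirna <- t1
  imputed$metadata <- t2
  proj <- project(imputed, object$v1, object$v2, object$norm)
  prob <- predict_proba(proj, object$w1, object$b1)
  score <- brca_score(proj, object$w1, object$b1,
                      object$score_min, object$score_max, clip = clip)
  data.frame(sample_id = cohort$sample_ids,
             proj_mirna = proj[, "mirna"], proj_metadata = proj[, "metadata"],
             probability = prob, score = score,
             call = classify(prob, object$threshold),
             row.names = NULL)
}
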