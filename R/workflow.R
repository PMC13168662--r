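#' Train, cross-validate and package the fusion model
#'
#' The evaluation side runs leakage-free nested cross-validation
#' ([cross_validate()]) and reports the pooled ROC, the Youden threshold and
#' the confusion metrics at it. The deployable model is then refit on all
#' training data at penalties re-selected by (non-nested) tenfold
#' cross-validation on the full set, with the pooled-CV Youden threshold
#' frozen into the bundle.
#'
#' @param cohort a labeled training [cohort()].
#' @param config a [cv_config()].
#' @param k1,k2,prescreen optional support limits (k-limited variant).
#' @param out_dir optional directory; when given, the model bundle and
#'   delimited/JSON reports are written there.
#' @return List with `model` (a `fusion_model`), `cv` (a `cv_result`), and
#'   `report` (threshold + confusion metrics at the Youden operating point).
#' @export
run_train <- function(cohort, config = cv_config(), k1 = NULL, k2 = NULL,
                      prescreen = NULL, out_dir = NULL) {
  cv <- cross_validate(cohort, config, k1 = k1, k2 = k2, prescreen = prescreen)
  t_star <- cv$youden
  metrics <- confusion_metrics(classify(cv$probability, t_star), cohort$labels)
  if (is.null(k1) && is.null(k2)) {
    sel <- nested_select_penalties(cohort, config)
    model <- fit_fusion_model(cohort, sel$beta1, sel$beta2, l2 = config$l2,
                              threshold = t_star)
  } else {
    model <- fit_fusion_model(cohort, beta1 = NA, beta2 = NA, k1 = k1, k2 = k2,
                              prescreen = prescreen, l2 = config$l2,
                              threshold = t_star,
                              n_points = config$n_penalties * 3L)
  }
  report <- list(threshold = t_star, auc = cv$roc$auc, auc_ci = cv$roc$ci,
                 metrics = metrics)
  if (!is.null(out_dir)) {
    save_model(model, file.path(out_dir, "model"))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(sample_id = cohort$sample_ids, fold = cv$fold,
                         oof_probability = cv$probability, oof_score = cv$score,
                         label = cohort$labels),
              file.path(out_dir, "cv_predictions.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "cv_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, cv = cv, report = report)
}

#' k-sweep: cross-validated AUC against the miRNA support limit
#'
#' For each `k1` in `k1_range` (with the metadata limit `k2` held fixed),
#' runs pooled tenfold cross-validation of the support-constrained model and
#' reports the AUC; also refits on the full data per `k1` to export the
#' selected miRNA panel.
#'
#' @param cohort a labeled [cohort()].
#' @param k1_range integer vector of miRNA support limits.
#' @param k2 fixed metadata support limit (default 5).
#' @param config a [cv_config()].
#' @param prescreen prescreen size applied before the constrained fits
#'   (default 20, absolute Pearson correlation with the label).
#' @return List with `table` (data.frame k1, auc, ci_lo, ci_hi) and
#'   `features` (per-k1 selected miRNA ids from the full-data fit).
#' @export
run_ksweep <- function(cohort, k1_range, k2 = 5L, config = cv_config(),
                       prescreen = 20L) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  features <- list()
  for (k1 in k1_range) {
    cv <- cross_validate(cohort, config, k1 = k1, k2 = k2, prescreen = prescreen)
    rows[[length(rows) + 1]] <- data.frame(k1 = k1, auc = cv$roc$auc,
                                           ci_lo = cv$roc$ci[1], ci_hi = cv$roc$ci[2])
    full <- fit_fusion_model(cohort, beta1 = NA, beta2 = NA, k1 = k1, k2 = k2,
                             prescreen = prescreen,
                             n_points = config$n_penalties * 3L)
    features[[as.character(k1)]] <- names(full$v1)[full$v1 != 0]
  }
  list(table = do.call(rbind, rows), features = features)
}

#' Apply a frozen model to an external cohort
#'
#' Scores the external cohort with the trained bundle (frozen imputation,
#' normalization, coefficients, softmax, score anchors and threshold),
#' evaluates the thresholded calls and ROC against the 5-year cancer
#' outcome, and builds the binned relative-risk curve with its log-linear
#' fit. Cohorts lacking any panel feature are a hard error.
#'
#' @param model a `fusion_model`.
#' @param external a [cohort()] with `cancer_outcome`.
#' @return List with `predictions`, `metrics` (confusion at the training
#'   threshold), `roc`, `risk_curve`, and `risk_fit`.
#' @export
run_external <- function(model, external) {
  stopifnot(inherits(model, "fusion_model"), inherits(external, "cohort"))
  if (is.null(external$cancer_outcome))
    stop_validation("run_external: external cohort has no cancer_outcome")
  pred <- predict(model, external, clip = TRUE)
  metrics <- confusion_metrics(pred$call, external$cancer_outcome)
  roc <- roc_auc(pred$probability, external$cancer_outcome)
  # the risk curve needs a populated baseline bin; report what is computable
  # and warn rather than fail when the score distribution leaves it empty
  curve <- tryCatch(relative_risk_curve(pred$score, external$cancer_outcome),
                    error = function(e) {
                      warning("relative-risk curve unavailable: ", conditionMessage(e))
                      NULL
                    })
  fit <- if (is.null(curve)) NULL else fit_log_linear(curve)
  list(predictions = pred, metrics = metrics, roc = roc,
       risk_curve = curve, risk_fit = fit)
}

#' Save / load a fusion model bundle
#'
#' The bundle is a directory of plain-text files: per-modality coefficient
#' tables (feature id, lasso weight, imputation fill), normalization tables,
#' and a JSON file of the scalar parameters.
#'
#' @param model a `fusion_model`.
#' @param dir bundle directory.
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   reconstructed `fusion_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "fusion_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(v, rec, norm, file) {
    write.csv(data.frame(feature_id = names(v), weight = unname(v),
                         fill = unname(rec$fill[names(v)]),
                         center = unname(norm$center[names(v)]),
                         scale = unname(norm$scale[names(v)])),
              file.path(dir, file), row.names = FALSE)
  }
  wr(model$v1, model$imputation$mirna, model$norm$mirna, "mirna_weights.csv")
  wr(model$v2, model$imputation$metadata, model$norm$metadata, "metadata_weights.csv")
  jsonlite::write_json(list(w1 = model$w1, b1 = model$b1,
                            score_min = model$score_min, score_max = model$score_max,
                            threshold = model$threshold,
                            beta1 = model$beta1, beta2 = model$beta2,
                            l2 = model$l2),
                       file.path(dir, "scalars.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  rd <- function(file) read.csv(file.path(dir, file))
  m1 <- rd("mirna_weights.csv")
  m2 <- rd("metadata_weights.csv")
  sc <- jsonlite::read_json(file.path(dir, "scalars.json"), simplifyVector = TRUE)
  mk <- function(df) list(
    v = stats::setNames(df$weight, df$feature_id),
    rec = structure(list(fill = stats::setNames(df$fill, df$feature_id),
                         n_imputed = stats::setNames(rep(0L, nrow(df)), df$feature_id)),
                    class = "imputation_record"),
    norm = structure(list(center = stats::setNames(df$center, df$feature_id),
                          scale = stats::setNames(df$scale, df$feature_id)),
                     class = "normalization_params"))
  a <- mk(m1)
  b <- mk(m2)
  structure(list(norm = list(mirna = a$norm, metadata = b$norm),
                 imputation = list(mirna = a$rec, metadata = b$rec),
                 v1 = a$v, v2 = b$v,
                 beta1 = sc$beta1, beta2 = sc$beta2,
                 w1 = as.numeric(sc$w1), b1 = sc$b1,
                 score_min = sc$score_min, score_max = sc$score_max,
                 threshold = sc$threshold, l2 = sc$l2),
            class = "fusion_model")
}
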