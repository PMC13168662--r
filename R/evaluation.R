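#' ROC curve, AUC and DeLong confidence interval
#'
#' The AUC is the tie-corrected Mann-Whitney statistic (ties count 1/2),
#' identical to the trapezoidal area over all distinct score thresholds.
#' Candidate thresholds are the midpoints between adjacent distinct scores
#' plus `-Inf`/`+Inf` sentinels; a sample is called positive when its score
#' strictly exceeds the threshold. The 95% CI uses the DeLong variance
#' estimate (normal interval, clipped to `[0, 1]`).
#'
#' @param scores numeric scores (probabilities or BRCAness scores; AUC is
#'   invariant under strictly increasing transforms).
#' @param labels 0/1 labels with both classes present.
#' @param ci_level confidence level for the AUC interval.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `ci`, and the Youden threshold
#'   `youden`.
#' @export
roc_auc <- function(scores, labels, ci_level = 0.95) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_validation("roc_auc: length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_validation("roc_auc: both classes must be present")
  auc <- auc_mw(scores, labels)
  uq <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(uq) > 1) (uq[-1] + uq[-length(uq)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) sum(scores > t & labels == 1) / n1, numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores <= t & labels == 0) / n0, numeric(1))
  ci <- auc_ci(scores, labels, level = ci_level)
  res <- structure(list(thresholds = thresholds, sensitivity = sens,
                        specificity = spec, auc = auc, ci = ci),
                   class = "roc_result")
  res$youden <- youden_threshold(res)
  res
}

# Tie-corrected Mann-Whitney AUC via midranks.
auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties (count 1/2)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @param level confidence level.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_validation("auc_ci: both classes must be present")
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, conf.level = level,
                                                 method = "delong")))
  c(lo = max(0, ci[1]), hi = min(1, ci[3]))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f (95%% CI %.4f-%.4f), Youden t = %.4g>\n",
              x$auc, x$ci[1], x$ci[2], x$youden))
  invisible(x)
}

#' Youden-index threshold
#'
#' Returns the threshold maximizing sensitivity + specificity - 1 over the
#' ROC's candidate thresholds; ties are broken toward the smallest threshold.
#'
#' @param roc a `roc_result`.
#' @return The maximizing threshold.
#' @export
youden_threshold <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  # thresholds ascend, so which.max lands on the smallest maximizer
  roc$thresholds[which.max(j)]
}

#' Confusion-matrix metrics at a fixed operating point
#'
#' Standard count-based definitions. Ratios with empty denominators (e.g.
#' PPV when nothing is called positive) are returned as `NA` with a
#' corresponding `*_defined` flag rather than dividing by zero.
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 true labels of equal length.
#' @return A list of counts (`tp`, `fp`, `tn`, `fn`), proportions
#'   (`sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`,
#'   `positive_rate`) and definedness flags.
#' @export
confusion_metrics <- function(calls, labels) {
  if (length(calls) != length(labels)) stop_validation("confusion_metrics: length mismatch")
  calls <- as.integer(calls)
  labels <- as.integer(labels)
  if (!all(c(calls, labels) %in% c(0L, 1L))) stop_validation("confusion_metrics: entries must be 0/1")
  tp <- sum(calls == 1 & labels == 1)
  fp <- sum(calls == 1 & labels == 0)
  tn <- sum(calls == 0 & labels == 0)
  fn <- sum(calls == 0 & labels == 1)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = (tp + tn) / length(calls),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       positive_rate = (tp + fp) / length(calls),
       ppv_defined = (tp + fp) > 0,
       npv_defined = (tn + fn) > 0,
       sensitivity_defined = (tp + fn) > 0,
       specificity_defined = (tn + fp) > 0)
}

#' Subgroup-stratified evaluation at a single global threshold
#'
#' Computes confusion metrics per subgroup level at one fixed probability
#' threshold, plus a per-level ROC where both classes are present. Levels
#' lacking a class report the defined subset of metrics with their flags;
#' empty levels are skipped with a warning.
#'
#' @param scores numeric scores/probabilities.
#' @param labels 0/1 labels.
#' @param subgroup categorical vector of the same length.
#' @param t global probability threshold.
#' @return Named list per level with elements `n`, `metrics`, and `roc`
#'   (`NULL` when a class is absent).
#' @export
subgroup_eval <- function(scores, labels, subgroup, t) {
  labels <- as.integer(labels)
  levels_ <- unique(as.character(subgroup))
  out <- list()
  for (lev in levels_) {
    idx <- which(as.character(subgroup) == lev)
    if (length(idx) == 0) {
      warning(sprintf("subgroup level '%s' is empty; skipped", lev))
      next
    }
    m <- confusion_metrics(classify(scores[idx], t), labels[idx])
    roc <- if (length(unique(labels[idx])) == 2) roc_auc(scores[idx], labels[idx]) else NULL
    out[[lev]] <- list(n = length(idx), metrics = m, roc = roc)
  }
  out
}

#' Two-proportion Z-test
#'
#' The pooled-variance two-proportion Z-test without continuity correction,
#' the variant used for the cohort characteristics tables:
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (x1 + x2) / (n1 + n2)` and two-sided p-value `2 (1 - Phi(|z|))`.
#' When the pooled proportion is 0 or 1 the variance vanishes; the test then
#' reports `p = 1` with a `zero_variance` flag.
#'
#' @param x1,x2 success counts.
#' @param n1,n2 trial counts (positive).
#' @return List with `z`, `p`, and `zero_variance`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop_validation("two_proportion_z: n must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop_validation("two_proportion_z: counts must satisfy 0 <= x <= n")
  phat <- (x1 + x2) / (n1 + n2)
  if (phat == 0 || phat == 1)
    return(list(z = 0, p = 1, zero_variance = TRUE))
  z <- (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), zero_variance = FALSE)
}

#' Compare BRCAness scores between two groups
#'
#' Per-group mean and SD, fold change (ratio of means, group 2 over group 1),
#' and a two-sided Welch t-test p-value.
#'
#' @param scores numeric scores.
#' @param group_labels two-level grouping vector.
#' @return List with `groups` (data.frame of n/mean/sd per level), `fold_change`,
#'   and `p`.
#' @export
group_score_comparison <- function(scores, group_labels) {
  g <- as.character(group_labels)
  levs <- unique(g)
  if (length(levs) != 2) stop_validation("group_score_comparison: exactly two groups required")
  s1 <- scores[g == levs[1]]
  s2 <- scores[g == levs[2]]
  if (length(s1) < 2 || length(s2) < 2)
    stop_validation("group_score_comparison: each group needs >= 2 samples")
  p <- if (sd(s1) == 0 && sd(s2) == 0 && mean(s1) == mean(s2)) 1
       else t.test(s2, s1)$p.value
  list(groups = data.frame(group = levs,
                           n = c(length(s1), length(s2)),
                           mean = c(mean(s1), mean(s2)),
                           sd = c(sd(s1), sd(s2))),
       fold_change = mean(s2) / mean(s1),
       p = p)
}
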