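test_that("AUC equals brute-force concordant-pair counting", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)  # all tied
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    expect_equal(roc_auc(sc, lb)$auc, auc_bruteforce(sc, lb))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms and agrees with pROC", {
  set.seed(23)
  sc <- runif(40)
  lb <- rbinom(40, 1, 0.5)
  if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
  a <- roc_auc(sc, lb)$auc
  expect_equal(roc_auc(qlogis(sc), lb)$auc, a)
  expect_equal(roc_auc(sc^3, lb)$auc, a)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(lb, sc, direction = "<",
                                                 quiet = TRUE))))
})

test_that("DeLong CI behaves: degenerate at separation, near bootstrap, narrows with n", {
  expect_equal(unname(auc_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))), c(1, 1))
  set.seed(31)
  sc <- c(rnorm(10, 1), rnorm(10))
  lb <- rep(c(1, 0), each = 10)
  ci <- auc_ci(sc, lb)
  # stratified bootstrap percentile oracle
  boot <- replicate(10000, {
    i1 <- sample(which(lb == 1), replace = TRUE)
    i0 <- sample(which(lb == 0), replace = TRUE)
    brcaness:::auc_mw(c(sc[i1], sc[i0]), c(lb[i1], lb[i0]))
  })
  bci <- quantile(boot, c(0.025, 0.975))
  expect_lt(max(abs(ci - bci)), 0.05)
  # same AUC at 4x the sample size gives a narrower interval
  ci_big <- auc_ci(rep(sc, 4), rep(lb, 4))
  expect_lt(diff(ci_big), diff(unname(ci)))
})

test_that("Youden threshold maximizes sensitivity + specificity, smallest on ties", {
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(youden_threshold(r), 0.5)  # midpoint of the separating gap
  # identical scores: J = 0 everywhere, tie resolves to the smallest (-Inf)
  r2 <- roc_auc(rep(0.5, 8), rep(c(0, 1), 4))
  expect_equal(youden_threshold(r2), -Inf)
  # exhaustive-scan oracle on random instances
  set.seed(41)
  for (rep in 1:10) {
    sc <- round(runif(30), 2)
    lb <- rbinom(30, 1, 0.4)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    r3 <- roc_auc(sc, lb)
    t3 <- youden_threshold(r3)
    j <- function(t) mean(sc[lb == 1] > t) + mean(sc[lb == 0] <= t) - 1
    grid <- c(-Inf, sort(unique(sc)), Inf)  # every achievable operating point
    expect_equal(j(t3), max(vapply(grid, j, numeric(1))), tolerance = 1e-12)
  }
})

test_that("confusion metrics use count-based definitions with undefined flags", {
  m <- confusion_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))
  m0 <- confusion_metrics(rep(0, 5), c(1, 0, 0, 1, 0))
  expect_equal(m0$specificity, 1)
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$ppv) && !m0$ppv_defined)
  # constructed table: TP=96 FN=4 TN=1696 FP=35
  calls <- c(rep(1, 96), rep(0, 4), rep(0, 1696), rep(1, 35))
  labels <- c(rep(1, 100), rep(0, 1731))
  m1 <- confusion_metrics(calls, labels)
  expect_equal(m1$sensitivity, 0.96)
  expect_equal(m1$specificity, 1696 / 1731, tolerance = 1e-12)
  expect_equal(m1$ppv, 96 / 131, tolerance = 1e-12)
  expect_equal(m1$npv, 1696 / 1700, tolerance = 1e-12)
  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), "length")
})

test_that("subgroup evaluation applies one global threshold per level", {
  set.seed(51)
  sc <- runif(60)
  lb <- rbinom(60, 1, sc)  # informative scores
  if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
  whole <- subgroup_eval(sc, lb, rep("all", 60), t = 0.5)
  expect_equal(whole$all$metrics, confusion_metrics(classify(sc, 0.5), lb))
  expect_equal(whole$all$roc$auc, roc_auc(sc, lb)$auc)
  # a level with no positives still reports specificity, flags sensitivity
  grp <- ifelse(lb == 1, "pos_only", "neg_only")
  res <- subgroup_eval(sc, lb, grp, t = 0.5)
  expect_null(res$neg_only$roc)
  expect_false(res$neg_only$metrics$sensitivity_defined)
  expect_true(res$neg_only$metrics$specificity_defined)
})

test_that("pooled two-proportion Z-test reproduces standard results", {
  # equal proportions give z = 0, p = 1
  r <- two_proportion_z(20, 100, 10, 50)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # agreement with prop.test's pooled chi-square (z^2 = X^2, same p)
  set.seed(61)
  for (rep in 1:10) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.5)
    r <- two_proportion_z(x1, n1, x2, n2)
    pt <- prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
    expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(r$p, pt$p.value, tolerance = 1e-10)
  }
  # degenerate pooled proportion flags zero variance
  expect_true(two_proportion_z(0, 10, 0, 20)$zero_variance)
  expect_equal(two_proportion_z(10, 10, 20, 20)$p, 1)
  expect_error(two_proportion_z(11, 10, 0, 5), "0 <= x <= n")
})

test_that("group score comparison reports means, fold change and Welch p", {
  g1 <- c(0.4, 0.45, 0.5, 0.45)
  g2 <- c(0.5, 0.55, 0.6, 0.55)
  r <- group_score_comparison(c(g1, g2), rep(c("a", "b"), each = 4))
  expect_equal(r$fold_change, mean(g2) / mean(g1))
  expect_equal(r$p, t.test(g2, g1)$p.value)
  same <- group_score_comparison(rep(c(0.2, 0.4), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p, 1)
  expect_error(group_score_comparison(1:3, c("a", "a", "b")), ">= 2 samples")
  # permutation of labels on null data gives roughly uniform p-values
  set.seed(71)
  ps <- replicate(200, {
    sc <- rnorm(40)
    group_score_comparison(sc, sample(rep(c("a", "b"), 20)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})
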