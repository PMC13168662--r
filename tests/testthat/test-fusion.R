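test_that("projection is the per-modality normalized matrix-vector product", {
  m <- matrix(c(1, 2, 3, 4, 2, 0, 1, 3, 5, 1, 2, 2), 4, 3)
  d <- matrix(c(0, 1, 1, 0, 1, 1, 0, 0), 4, 2)
  co <- toy_cohort(m, d)
  norm <- list(mirna = fit_normalization(co$mirna),
               metadata = fit_normalization(co$metadata))
  v1 <- c("miR-001" = 2, "miR-002" = 0, "miR-003" = -1)
  v2 <- c(meta1 = 1, meta2 = 0.5)
  proj <- project(co, v1, v2, norm)
  x1 <- apply_normalization(co$mirna, norm$mirna)$values
  x2 <- apply_normalization(co$metadata, norm$metadata)$values
  expect_equal(unname(proj[, "mirna"]), unname(drop(x1 %*% v1)))
  expect_equal(unname(proj[, "metadata"]), unname(drop(x2 %*% v2)))
  # zero coefficients give a zero column; a unit vector extracts one feature
  expect_equal(unname(project(co, v1 * 0, v2 * 0, norm)), matrix(0, 4, 2),
               ignore_attr = TRUE)
  e2 <- c(meta1 = 0, meta2 = 1)
  expect_equal(unname(project(co, v1, e2, norm)[, "metadata"]), unname(x2[, "meta2"]))
})

test_that("softmax training respects symmetry, separability, and label antisymmetry", {
  # mirror-symmetric data: x and -x with swapped labels force b1 = 0
  x <- matrix(c(1, 0.5, -1, -0.5, 0.3, -0.2, -0.3, 0.2), 4, 2)
  y <- c(1, 1, 0, 0)
  sm <- train_softmax(x, y)
  expect_lt(abs(sm$b1), 1e-6)
  # linearly separable data: finite weights, perfect training accuracy
  set.seed(5)
  xs <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  ys <- rep(c(1, 0), each = 20)
  sm2 <- train_softmax(xs, ys, l2 = 1e-6)
  expect_true(all(is.finite(c(sm2$w1, sm2$b1))))
  expect_equal(classify(predict_proba(xs, sm2$w1, sm2$b1), 0.5), ys)
  # flipping labels negates the parameters
  sm3 <- train_softmax(xs, 1 - ys, l2 = 1e-6)
  expect_equal(sm3$w1, -sm2$w1, tolerance = 1e-5)
  expect_equal(sm3$b1, -sm2$b1, tolerance = 1e-5)
  expect_error(train_softmax(xs, rep(1, 40)), "both classes")
})

test_that("softmax fit matches an independent convex-optimizer oracle", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, plogis(x[, 1] - 0.5 * x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  l2 <- 1e-4
  sm <- train_softmax(x, y, l2 = l2)
  nll <- function(th) {
    eta <- drop(cbind(x, 1) %*% th)
    -sum(y * plogis(2 * eta, log.p = TRUE) +
           (1 - y) * plogis(-2 * eta, log.p = TRUE)) + l2 * sum(th^2)
  }
  o <- optim(c(0, 0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(c(sm$w1, sm$b1), o$par, tolerance = 1e-4)
  expect_lte(nll(c(sm$w1, sm$b1)), o$value + 1e-8)
})

test_that("probabilities follow the antisymmetric softmax, overflow-safe", {
  # the published full-data weights evaluated at the 2-D origin
  w1 <- c(5.6357, 7.4701)
  b1 <- -3.1716
  p0 <- predict_proba(matrix(0, 1, 2), w1, b1)
  expect_equal(p0, 1 / (1 + exp(6.3432)), tolerance = 1e-12)
  # raw score 0 is probability 1/2; saturation does not overflow
  expect_equal(predict_proba(matrix(c(0, 0), 1, 2), c(1, 1), 0), 0.5)
  expect_equal(predict_proba(matrix(c(1e6, 1e6), 1, 2), c(1, 1), 0), 1)
  expect_equal(predict_proba(matrix(c(-1e6, 0), 1, 2), c(1, 0), 0), 0)
})

test_that("BRCAness score is the min-max scaled raw score, clipped externally", {
  proj <- matrix(c(0, 1, 2, 0, 0, 0), 3, 2)
  w1 <- c(1, 0)
  sc <- brca_score(proj, w1, 0, score_min = 0, score_max = 2)
  expect_equal(sc, c(0, 0.5, 1))
  ext <- matrix(c(5, 0), 1, 2)
  expect_equal(brca_score(ext, w1, 0, 0, 2, clip = TRUE), 1)
  expect_equal(brca_score(ext, w1, 0, 0, 2, clip = FALSE), 2.5)
  expect_error(brca_score(proj, w1, 0, 1, 1), "degenerate")
  # monotone in probability: same ordering as predict_proba
  set.seed(3)
  pr <- matrix(rnorm(20), 10, 2)
  p <- predict_proba(pr, c(0.7, -0.4), 0.2)
  s <- brca_score(pr, c(0.7, -0.4), 0.2, -3, 3)
  expect_identical(order(p), order(s))
})

test_that("classification uses a strict threshold", {
  expect_identical(classify(c(0.03, 0.04, 0.05), 0.04), c(0L, 0L, 1L))
  expect_identical(classify(c(0, 0.2, 1), 0), c(0L, 1L, 1L))
  expect_identical(classify(c(0.2, 1), 1), c(0L, 0L))
  expect_error(classify(0.5, 1.2), "\\[0, 1\\]")
})

test_that("fitting the fusion model end-to-end is deterministic and leak-free by construction", {
  co <- random_cohort(80, shift = 1.5, seed = 13)
  m1 <- fit_fusion_model(co, beta1 = 2, beta2 = 2)
  m2 <- fit_fusion_model(co, beta1 = 2, beta2 = 2)
  expect_identical(m1, m2)
  pred <- predict(m1, co, clip = FALSE)
  expect_equal(range(pred$score), c(0, 1))  # training extremes anchor the scale
  # a cohort lacking a panel miRNA is a hard error
  drop1 <- cohort(feature_table(co$mirna$values[, -1], "miRNA"), co$metadata,
                  labels = co$labels)
  expect_error(predict(m1, drop1), "miR-001")
})
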