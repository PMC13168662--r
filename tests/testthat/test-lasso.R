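test_that("soft threshold matches its closed form", {
  expect_equal(soft_threshold(2.5, 1), 1.5)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 0.5), -2.5)
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("penalty_max is the zero-solution boundary (dense grid oracle)", {
  X <- diag(2)
  Y <- c(1, 0)
  pm <- penalty_max(X, Y)
  expect_equal(pm, 2)
  # oracle: scan a dense beta grid; solutions are zero iff beta >= pm
  for (b in seq(0.05, 4, by = 0.05)) {
    v <- solve_lasso(X, Y, b)$v
    if (b >= pm) expect_equal(unname(v), c(0, 0))
    else expect_gt(sum(abs(v)), 0)
  }
  expect_equal(penalty_max(X, c(0, 0)), 0)
  expect_equal(penalty_max(X, 3 * Y), 3 * pm)  # homogeneity in Y
  expect_error(penalty_max(matrix(numeric(0), 0, 0), numeric(0)), "empty")
})

test_that("orthonormal designs recover the soft-threshold closed form", {
  X <- diag(2)
  f <- solve_lasso(X, c(1, 0.2), 0.5)
  expect_equal(unname(f$v), c(0.75, 0))
  expect_identical(f$support, "V1")
  # closed form on random orthonormal designs: v_j = S(X_j'Y, beta/2)
  for (seed in 1:5) {
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
    Y <- rnorm(8)
    beta <- runif(1, 0.1, 2)
    f <- solve_lasso(Q, Y, beta)
    expect_equal(unname(f$v), unname(soft_threshold(drop(crossprod(Q, Y)), beta / 2)),
                 tolerance = 1e-7)
  }
})

test_that("beta = 0 reduces to least squares (normal-equations oracle)", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  Y <- rnorm(10)
  f <- solve_lasso(X, Y, 0)
  expect_equal(unname(f$v), drop(solve(crossprod(X), crossprod(X, Y))),
               tolerance = 1e-6)
})

test_that("objective matches the quadratic-programming oracle on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    X <- matrix(rnorm(80), 10, 8)
    Y <- rbinom(10, 1, 0.5)
    beta <- runif(1, 0.2, 3)
    f <- solve_lasso(X, Y, beta)
    o <- lasso_qp_oracle(X, Y, beta)
    expect_lt(abs(f$objective - o$objective), 1e-6)
    expect_lte(f$objective, sum(Y^2) + 1e-12)  # no worse than the zero vector
    expect_lt(brcaness:::kkt_residual(X, Y, f), 1e-5)
  }
})

test_that("solutions are invariant to feature permutation", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  Y <- rbinom(12, 1, 0.5)
  f <- solve_lasso(X, Y, 1.2)
  perm <- c(3, 1, 5, 2, 4)
  fp <- solve_lasso(X[, perm], Y, 1.2)
  expect_equal(fp$v[names(f$v)], f$v, tolerance = 1e-7)
})

test_that("L1 norm is non-increasing in beta and the path starts at zero", {
  set.seed(9)
  X <- matrix(rnorm(100), 20, 5)
  Y <- rbinom(20, 1, 0.4)
  path <- fit_path(X, Y, n_points = 12)
  expect_equal(sum(abs(path$fits[[1]]$v)), 0)  # first grid point = penalty_max
  l1 <- vapply(path$fits, function(f) sum(abs(f$v)), numeric(1))
  expect_true(all(diff(l1) >= -1e-8))          # betas decrease along the grid
  # grid-point fits agree with independent cold solves
  for (g in c(3, 7, 12)) {
    cold <- solve_lasso(X, Y, path$betas[g])
    expect_equal(path$fits[[g]]$v, cold$v, tolerance = 1e-6)
  }
  expect_length(fit_path(X, Y, n_points = 2)$fits, 2)
})

test_that("support-constrained fit finds the planted strong features", {
  set.seed(21)
  n <- 100
  strong <- matrix(rnorm(n * 3), n, 3)
  Y <- as.numeric(strong %*% c(2, -1.6, 1.2) + rnorm(n, sd = 0.2) > 0)
  X <- cbind(strong, matrix(rnorm(n * 7), n, 7))
  colnames(X) <- paste0("f", 1:10)
  X <- scale(X, scale = apply(abs(scale(X, scale = FALSE)), 2, max))
  f <- support_constrained_fit(X, Y, k = 3)
  expect_lte(length(f$support), 3)
  expect_true(all(f$support %in% c("f1", "f2", "f3")))
  # exhaustive best-subset oracle picks the same features
  expect_identical(sort(match(f$support, colnames(X))),
                   sort(best_subset_support(X, Y, 3)))
  expect_equal(sum(support_constrained_fit(X, Y, k = 0)$v), 0)
  # k = p at the path end equals the unconstrained path-end fit
  full <- support_constrained_fit(X, Y, k = 10)
  pend <- fit_path(X, Y)$fits[[20]]
  expect_equal(full$v, pend$v, tolerance = 1e-7)
  expect_error(support_constrained_fit(X, Y, k = -1), "non-negative")
})

test_that("prescreening keeps the most label-correlated features", {
  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  Y <- rbinom(n, 1, plogis(2 * X[, 4]))
  f <- support_constrained_fit(X, Y, k = 1, prescreen = 1)
  expect_identical(f$support, "f4")
  cors <- abs(cor(X, Y))
  expect_equal(which.max(cors), 4L)  # the oracle agrees on the screen winner
})
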