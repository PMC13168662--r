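# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (brute force / generic optimizers) and never call the code paths
# they check.

# A tiny fully-observed cohort with hand-controllable values.
toy_cohort <- function(mirna_vals, meta_vals, labels = NULL, ...) {
  ids <- sprintf("S%d", seq_len(nrow(mirna_vals)))
  rownames(mirna_vals) <- rownames(meta_vals) <- ids
  if (is.null(colnames(mirna_vals)))
    colnames(mirna_vals) <- sprintf("miR-%03d", seq_len(ncol(mirna_vals)))
  if (is.null(colnames(meta_vals)))
    colnames(meta_vals) <- sprintf("meta%d", seq_len(ncol(meta_vals)))
  cohort(feature_table(mirna_vals, "miRNA"),
         feature_table(meta_vals, "metadata"),
         labels = labels, ...)
}

# Random small cohort with optional class signal on the first miRNAs.
random_cohort <- function(n, p1 = 6, p2 = 3, shift = 0, seed = 1, prevalence = 0.3) {
  set.seed(seed)
  labels <- rbinom(n, 1, prevalence)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  m <- exp(matrix(rnorm(n * p1, 5), n, p1) + shift * labels)
  md <- matrix(rbinom(n * p2, 1, 0.3 + 0.2 * labels), n, p2)
  toy_cohort(m, md, labels = labels)
}

# Spec builders for the two synthetic study conditions.
null_spec <- function(n, seed) {
  synthetic_spec(n_samples = n, mirna_log_effect = 0,
                 metadata_rates = within(default_metadata_rates(),
                                         rate_carrier <- rate_noncarrier),
                 seed = seed)
}

# Brute-force AUC: concordant-pair counting over all case-control pairs,
# ties counting 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Quadratic-programming oracle for ||Xv - Y||^2 + beta ||v||_1: split
# v = a - b with a, b >= 0 and minimize the smooth bound-constrained
# quadratic with a generic box-constrained optimizer.
lasso_qp_oracle <- function(X, Y, beta) {
  p <- ncol(X)
  obj <- function(ab) {
    v <- ab[1:p] - ab[p + 1:p]
    sum((X %*% v - Y)^2) + beta * sum(ab)
  }
  gr <- function(ab) {
    v <- ab[1:p] - ab[p + 1:p]
    g <- 2 * drop(crossprod(X, X %*% v - Y))
    c(g + beta, -g + beta)
  }
  o <- stats::nlminb(rep(0, 2 * p), obj, gr, lower = 0,
                     control = list(iter.max = 5000))
  list(objective = o$objective,
       v = o$par[1:p] - o$par[p + 1:p])
}

# Exhaustive best-subset least squares: the support of the best k-subset fit.
best_subset_support <- function(X, Y, k) {
  combs <- utils::combn(ncol(X), k, simplify = FALSE)
  best <- Inf
  best_s <- integer(0)
  for (s in combs) {
    Xs <- X[, s, drop = FALSE]
    rss <- sum(stats::lm.fit(Xs, Y)$residuals^2)
    if (rss < best) { best <- rss; best_s <- s }
  }
  best_s
}
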