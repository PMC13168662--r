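test_that("spec validation enforces probabilities, finiteness and a mandatory seed", {
  expect_error(synthetic_spec(seed = 1, carrier_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(seed = 1, mirna_log_effect = Inf), "finite")
  expect_error(synthetic_spec(seed = 1, n_signal_mirna = 200), "exceeds")
  expect_error(synthetic_spec(), "seed is mandatory")
  # infeasible outcome model is rejected at spec time
  expect_error(synthetic_spec(seed = 1, external = TRUE, baseline_risk = 0.5,
                              log_rr_slope = 2), "exceeds 1")
})

test_that("same seed gives bit-identical cohorts, different seeds differ", {
  spec <- synthetic_spec(n_samples = 120, seed = 5)
  a <- generate_training_cohort(spec)
  b <- generate_training_cohort(spec)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$metadata$values, b$metadata$values)
  expect_identical(a$labels, b$labels)
  c <- generate_training_cohort(synthetic_spec(n_samples = 120, seed = 6))
  expect_false(identical(a$mirna$values, c$mirna$values))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_training_cohort(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("carrier prevalence and degenerate settings behave", {
  co0 <- generate_training_cohort(synthetic_spec(n_samples = 50,
                                                 carrier_prevalence = 0, seed = 2))
  expect_equal(sum(co0$labels), 0)
  co <- generate_training_cohort(synthetic_spec(n_samples = 2000, seed = 3))
  p <- 100 / 1831
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(co$labels) - p), 3 * se)
})

test_that("class-conditional metadata frequencies converge to the spec rates", {
  spec <- synthetic_spec(n_samples = 10000, carrier_prevalence = 0.5, seed = 11)
  co <- generate_training_cohort(spec)
  rates <- spec$metadata_rates
  for (j in c(1, 11, 13, 18)) {  # spot-check smoking, BBD, family history, osteoporosis
    v <- co$metadata$values[, rates$variable[j]]
    for (cls in 0:1) {
      obs <- v[co$labels == cls & !is.na(v)]
      want <- if (cls == 0) rates$rate_noncarrier[j] else rates$rate_carrier[j]
      se <- sqrt(want * (1 - want) / length(obs))
      expect_lt(abs(mean(obs) - want), 3.5 * se)
    }
  }
  # missingness matches the per-variable rate
  miss <- colMeans(is.na(co$metadata$values))
  expect_lt(max(abs(miss - spec$missing_rate)), 0.02)
})

test_that("the signal miRNAs carry the class shift and the rest do not", {
  spec <- synthetic_spec(n_samples = 4000, carrier_prevalence = 0.5, seed = 13)
  co <- generate_training_cohort(spec)
  lm_ <- log(co$mirna$values)
  shift <- colMeans(lm_[co$labels == 1, ]) - colMeans(lm_[co$labels == 0, ])
  expect_equal(unname(mean(shift[1:20])), 0.8, tolerance = 0.1)
  expect_lt(max(abs(shift[21:179])), 0.25)
})

test_that("external cohorts couple outcome risk to the latent score", {
  spec <- synthetic_spec(n_samples = 1044, external = TRUE, seed = 17)
  ex <- generate_external_cohort(spec)
  expect_equal(length(ex$cancer_outcome), 1044)
  # case fraction calibrated to 259/1044
  expect_lt(abs(mean(ex$cancer_outcome) - 259 / 1044), 3.5 * sqrt(0.25 / 1044))
  # days-to-diagnosis only for cases, within the 5-year window
  expect_true(all(is.na(ex$days_to_diagnosis[ex$cancer_outcome == 0])))
  d <- ex$days_to_diagnosis[ex$cancer_outcome == 1]
  expect_true(all(d >= 1 & d <= 1814))
  # higher latent score means higher observed risk
  hi <- mean(ex$cancer_outcome[ex$latent_score > 0.5])
  lo <- mean(ex$cancer_outcome[ex$latent_score < 0.2])
  expect_gt(hi, lo)
  # slope 0 decouples them
  ex0 <- generate_external_cohort(synthetic_spec(n_samples = 2000, external = TRUE,
                                                 log_rr_slope = 0, seed = 19))
  cu <- relative_risk_curve(ex0$latent_score, ex0$cancer_outcome)
  f <- fit_log_linear(cu)
  expect_lt(abs(f$slope), 3 * f$slope_se + 0.3)
})

test_that("characteristics_table reproduces printed-count p-values and handles missingness", {
  # construct a cohort whose metadata exactly matches published two-group counts
  build <- function(x0, n0, x1, n1, n_total0 = 1731, n_total1 = 100) {
    c(rep(1, x0), rep(0, n0 - x0), rep(NA, n_total0 - n0),
      rep(1, x1), rep(0, n1 - x1), rep(NA, n_total1 - n1))
  }
  md <- cbind(
    oral_contraceptive_use = build(648, 1731, 55, 100),
    osteoporosis = build(193, 1731, 19, 100),
    benign_breast_disease = build(370, 1717, 37, 99)
  )
  n <- nrow(md)
  rownames(md) <- sprintf("S%d", 1:n)
  mi <- matrix(1, n, 1, dimnames = list(rownames(md), "miR-001"))
  co <- cohort(feature_table(mi, "miRNA"), feature_table(md, "metadata"),
               labels = rep(c(0L, 1L), c(1731, 100)))
  tab <- characteristics_table(co, by = "labels")
  # agreement with the published values to their printed precision
  expect_lt(abs(tab$p[tab$variable == "oral_contraceptive_use"] - 0.0004), 5e-5)
  expect_lt(abs(tab$p[tab$variable == "osteoporosis"] - 0.0171), 5e-5)
  expect_lt(abs(tab$p[tab$variable == "benign_breast_disease"] - 0.0002), 5e-5)
  # observed denominators exclude missing cells
  expect_equal(tab$n_observed,
               c(1831, 1831, 1816))
  expect_equal(tab$n_group0[tab$variable == "benign_breast_disease"], 1717)
  # identical groups give p = 1
  same <- cbind(flag = rep(c(1, 0), 50))
  rownames(same) <- sprintf("T%d", 1:100)
  mi2 <- matrix(1, 100, 1, dimnames = list(rownames(same), "miR-001"))
  co2 <- cohort(feature_table(mi2, "miRNA"), feature_table(same, "metadata"),
                labels = rep(c(0L, 1L), each = 50))
  expect_equal(characteristics_table(co2)$p, 1)
})
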