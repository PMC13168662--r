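#' Default class-conditional metadata rates
#'
#' The 19 binary clinical variables used by the model (family and medical
#' history flags; the Table-1-style panel minus personal cancer history,
#' oral contraceptive use, and hysterectomy, which are excluded for reverse
#' causality) with their non-carrier and carrier prevalences and the number
#' of subjects with the variable recorded out of 1831, from which the
#' per-variable missingness rate is derived.
#'
#' @return A data.frame with columns `variable`, `rate_noncarrier`,
#'   `rate_carrier`, `n_observed`.
#' @export
default_metadata_rates <- function() {
  data.frame(
    variable = c("smoking_history", "obesity", "height_above_avg", "parity",
                 "abortions", "ectopic_pregnancy", "hrt_use", "tubal_ligation",
                 "benign_gyn_disease", "endometriosis", "benign_breast_disease",
                 "ovarian_cancer_family", "breast_cancer_family",
                 "coronary_artery_disease", "gallbladder_disease",
                 "colon_polyps", "hypertension", "osteoporosis", "diabetes"),
    rate_noncarrier = c(0.349, 0.323, 0.408, 0.661, 0.230, 0.024, 0.137,
                        0.140, 0.200, 0.115, 0.215, 0.018, 0.092, 0.046,
                        0.160, 0.198, 0.333, 0.111, 0.102),
    rate_carrier = c(0.320, 0.300, 0.380, 0.684, 0.247, 0.043, 0.157, 0.100,
                     0.220, 0.150, 0.374, 0.110, 0.360, 0.040, 0.160, 0.220,
                     0.290, 0.190, 0.090),
    n_observed = c(1829, 1831, 1829, 1770, 1426, 1700, 1690, 1819, 1831,
                   1802, 1816, 1831, 1831, 1831, 1831, 1831, 1831, 1831, 1831)
  )
}

#' Specification for a synthetic cohort
#'
#' Describes the generative model for either a biobank-like training cohort
#' (carrier labels at ~5.5% prevalence, log-normal MFI with a class shift on
#' a signal subset of miRNAs, class-conditional Bernoulli metadata with
#' per-variable missingness) or a PLCO-like external cohort (a latent score
#' in `[0, 1]` drives both a continuous feature shift and an exponentially
#' increasing 5-year cancer probability).
#'
#' @param n_samples cohort size (training default 1831, external 1044).
#' @param carrier_prevalence Bernoulli rate of carrier labels (default
#'   100/1831).
#' @param n_mirna miRNA panel size (default 179).
#' @param n_signal_mirna number of class-shifted miRNAs (default 20, the
#'   size of the limited miRNA panel).
#' @param mirna_log_effect carrier mean shift on the log-MFI scale, in units
#'   of `mirna_noise_sd` (default 0.8 SD).
#' @param mirna_noise_sd per-feature log-scale SD of MFI (default 1).
#' @param metadata_rates data.frame as [default_metadata_rates()].
#' @param missing_rate per-variable missingness probabilities (default
#'   derived from `metadata_rates$n_observed`).
#' @param external generate a PLCO-like cohort with cancer outcomes.
#' @param baseline_risk 5-year cancer probability at latent score 0; `NULL`
#'   (default) calibrates it so the expected case fraction matches
#'   `case_fraction`.
#' @param log_rr_slope slope of the log relative risk in the latent score
#'   (default 2).
#' @param case_fraction target case fraction of the external cohort (default
#'   259/1044).
#' @param seed mandatory integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 1831L,
                           carrier_prevalence = 100 / 1831,
                           n_mirna = 179L,
                           n_signal_mirna = 20L,
                           mirna_log_effect = 0.8,
                           mirna_noise_sd = 1,
                           metadata_rates = default_metadata_rates(),
                           missing_rate = NULL,
                           external = FALSE,
                           baseline_risk = NULL,
                           log_rr_slope = 2,
                           case_fraction = 259 / 1044,
                           seed) {
  if (missing(seed)) stop_validation("synthetic_spec: seed is mandatory")
  if (carrier_prevalence < 0 || carrier_prevalence > 1)
    stop_validation("synthetic_spec: carrier_prevalence must lie in [0, 1]")
  if (case_fraction < 0 || case_fraction > 1)
    stop_validation("synthetic_spec: case_fraction must lie in [0, 1]")
  if (!all(is.finite(c(mirna_log_effect, mirna_noise_sd, log_rr_slope))))
    stop_validation("synthetic_spec: effect parameters must be finite")
  if (n_signal_mirna > n_mirna)
    stop_validation("synthetic_spec: n_signal_mirna exceeds n_mirna")
  rates <- as.data.frame(metadata_rates)
  if (any(rates$rate_noncarrier < 0 | rates$rate_noncarrier > 1 |
          rates$rate_carrier < 0 | rates$rate_carrier > 1))
    stop_validation("synthetic_spec: metadata rates must lie in [0, 1]")
  if (is.null(missing_rate))
    missing_rate <- 1 - rates$n_observed / max(rates$n_observed)
  if (!is.null(baseline_risk) && baseline_risk * exp(log_rr_slope) > 1)
    stop_validation("synthetic_spec: risk exceeds 1 at the top of the latent score range")
  structure(list(n_samples = as.integer(n_samples),
                 carrier_prevalence = carrier_prevalence,
                 n_mirna = as.integer(n_mirna),
                 n_signal_mirna = as.integer(n_signal_mirna),
                 mirna_log_effect = mirna_log_effect,
                 mirna_noise_sd = mirna_noise_sd,
                 metadata_rates = rates,
                 missing_rate = missing_rate,
                 external = isTRUE(external),
                 baseline_risk = baseline_risk,
                 log_rr_slope = log_rr_slope,
                 case_fraction = case_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

mirna_panel_ids <- function(n) sprintf("miR-%03d", seq_len(n))

# Baseline per-feature log-MFI levels (MFI spans roughly 55 to 8000 units).
# These emulate the assay panel itself, so they are a fixed property of the
# panel size, shared by every generated cohort: a model trained on one cohort
# must see the same per-feature baselines in an external cohort, as it would
# with the real assay.
.mirna_baseline <- function(spec) {
  with_seed(20121831L, runif(spec$n_mirna, 4, 9))
}

# Draw the feature side shared by both cohort styles. `shift_frac` in [0,1]
# per sample scales the signal-miRNA log shift and interpolates the metadata
# rates between the non-carrier and carrier columns.
.draw_features <- function(spec, shift_frac) {
  n <- length(shift_frac)
  mu <- .mirna_baseline(spec)
  shift_total <- spec$mirna_log_effect * spec$mirna_noise_sd
  signal <- seq_len(spec$n_signal_mirna)
  logm <- matrix(rnorm(n * spec$n_mirna, sd = spec$mirna_noise_sd),
                 n, spec$n_mirna)
  logm <- sweep(logm, 2, mu, "+")
  if (length(signal) > 0)
    logm[, signal] <- logm[, signal] + shift_frac * shift_total
  mirna_vals <- exp(logm)
  ids <- sprintf("S%05d", seq_len(n))
  dimnames(mirna_vals) <- list(ids, mirna_panel_ids(spec$n_mirna))
  rates <- spec$metadata_rates
  meta_vals <- matrix(NA_real_, n, nrow(rates),
                      dimnames = list(ids, rates$variable))
  for (j in seq_len(nrow(rates))) {
    pj <- rates$rate_noncarrier[j] +
      shift_frac * (rates$rate_carrier[j] - rates$rate_noncarrier[j])
    meta_vals[, j] <- rbinom(n, 1, pj)
    miss <- runif(n) < spec$missing_rate[j]
    meta_vals[miss, j] <- NA_real_
  }
  list(mirna = feature_table(mirna_vals, "miRNA"),
       metadata = feature_table(meta_vals, "metadata"),
       ids = ids)
}

.draw_subgroups <- function(n) {
  data.frame(
    race = sample(c("white_nonhispanic", "all_other"), n, replace = TRUE,
                  prob = c(0.80, 0.20)),
    age_decade = sample(c("<50", "50-59", "60-69", "70+"), n, replace = TRUE,
                        prob = c(0.25, 0.30, 0.25, 0.20)),
    cancer_history = rbinom(n, 1, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Generate a biobank-like training cohort
#'
#' Carrier labels are Bernoulli at the spec prevalence; miRNA values are
#' log-normal MFI with an additive log-scale shift on the signal subset for
#' carriers; metadata are class-conditional Bernoulli draws with per-variable
#' missingness; subgroup annotations are drawn independently of the signal.
#' Identical seeds give bit-identical cohorts.
#'
#' @param spec a [synthetic_spec()] with `external = FALSE`.
#' @return A labeled [cohort()].
#' @export
generate_training_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$external) stop_validation("generate_training_cohort: spec has external = TRUE")
  with_seed(spec$seed, {
    labels <- rbinom(spec$n_samples, 1, spec$carrier_prevalence)
    feats <- .draw_features(spec, as.numeric(labels))
    cohort(feats$mirna, feats$metadata, labels = labels,
           subgroups = .draw_subgroups(spec$n_samples))
  })
}

#' Generate a PLCO-like external validation cohort
#'
#' Each sample carries a latent score `s ~ Beta(2, 4)` in `[0, 1]` (right-
#' skewed, so most subjects sit below 0.7 as in the screening population).
#' The score drives a proportional log-MFI shift on the signal miRNAs and an
#' interpolation of the metadata rates, and the 5-year ovarian cancer outcome
#' is Bernoulli with probability `baseline_risk * exp(log_rr_slope * s)`;
#' when `baseline_risk` is `NULL` it is calibrated so the expected case
#' fraction matches the spec. Cases receive `days_to_diagnosis` uniform on
#' 1..1814. If a frozen `fusion_model` is supplied as `model_truth`, its own
#' (clipped) BRCAness score of the generated features replaces the latent
#' score in the outcome model, tying the risk to the deployed model exactly.
#'
#' @param spec a [synthetic_spec()] with `external = TRUE`.
#' @param model_truth optional `fusion_model` supplying the latent score.
#' @return A [cohort()] with `cancer_outcome`, `days_to_diagnosis`, and
#'   `latent_score`.
#' @export
generate_external_cohort <- function(spec, model_truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$external) stop_validation("generate_external_cohort: spec has external = FALSE")
  with_seed(spec$seed, {
    s <- rbeta(spec$n_samples, 2, 4)
    feats <- .draw_features(spec, s)
    if (!is.null(model_truth)) {
      stopifnot(inherits(model_truth, "fusion_model"))
      tmp <- cohort(feats$mirna, feats$metadata)
      s <- predict(model_truth, tmp, clip = TRUE)$score
    }
    base <- spec$baseline_risk
    if (is.null(base)) base <- spec$case_fraction / mean(exp(spec$log_rr_slope * s))
    risk <- base * exp(spec$log_rr_slope * s)
    if (any(risk > 1))
      stop_validation("external outcome model: risk exceeds 1 for %d sample(s); lower baseline_risk or log_rr_slope",
                      sum(risk > 1))
    outcome <- rbinom(spec$n_samples, 1, risk)
    days <- rep(NA_integer_, spec$n_samples)
    days[outcome == 1] <- sample.int(1814L, sum(outcome), replace = TRUE)
    cohort(feats$mirna, feats$metadata,
           cancer_outcome = outcome, days_to_diagnosis = days,
           subgroups = .draw_subgroups(spec$n_samples),
           latent_score = s)
  })
}

#' Cohort characteristics table with two-proportion Z-tests
#'
#' Reproduces the characteristics-table layout: for every metadata variable,
#' the count and proportion positive in each group (with observed, non-missing
#' denominators) and the pooled two-proportion Z-test p-value for the
#' group difference.
#'
#' @param cohort a [cohort()] with `labels` or `cancer_outcome`.
#' @param by which grouping to use: `"labels"` (carrier status) or
#'   `"cancer_outcome"`.
#' @return A data.frame with one row per metadata variable.
#' @export
characteristics_table <- function(cohort, by = c("labels", "cancer_outcome")) {
  stopifnot(inherits(cohort, "cohort"))
  by <- match.arg(by)
  grp <- cohort[[by]]
  if (is.null(grp)) stop_validation("characteristics_table: cohort has no %s", by)
  vals <- cohort$metadata$values
  rows <- lapply(colnames(vals), function(v) {
    obs <- !is.na(vals[, v])
    g0 <- obs & grp == 0L
    g1 <- obs & grp == 1L
    x0 <- sum(vals[g0, v])
    x1 <- sum(vals[g1, v])
    zt <- if (sum(g0) >= 1 && sum(g1) >= 1) two_proportion_z(x0, sum(g0), x1, sum(g1))
          else list(z = NA_real_, p = NA_real_)
    data.frame(variable = v, n_observed = sum(obs),
               count_group0 = x0, n_group0 = sum(g0),
               prop_group0 = if (sum(g0) > 0) x0 / sum(g0) else NA_real_,
               count_group1 = x1, n_group1 = sum(g1),
               prop_group1 = if (sum(g1) > 0) x1 / sum(g1) else NA_real_,
               z = zt$z, p = zt$p)
  })
  do.call(rbind, rows)
}
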