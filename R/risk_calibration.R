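#' Overlapping score-bin membership
#'
#' The relative-risk curve uses 21 bins of width 0.2 with centers on the grid
#' 0.00, 0.05, ..., 1.00, intersected with `[0, 1]`. Edges are half-open
#' `[lo, hi)` except that bins whose upper edge is exactly 1.0 are closed at
#' the top, so a score of 1 is not orphaned. The first bin (center 0) is
#' `[0, 0.1)`.
#'
#' @param score numeric score(s) in `[0, 1]`.
#' @param center a center from the 21-point grid.
#' @return Logical membership vector.
#' @export
bin_membership <- function(score, center) {
  lo <- max(center - 0.1, 0)
  hi <- min(center + 0.1, 1)
  score >= lo & (score < hi | (hi == 1 & score <= 1))
}

risk_bin_centers <- function() seq(0, 1, by = 0.05)

#' Binned relative-risk curve
#'
#' For each of the 21 overlapping bins, the absolute risk is
#' `R_a = cases in bin / samples in bin`; the baseline `R_b` is the absolute
#' risk of the first bin (scores in `[0, 0.1)`), and the relative risk is
#' `R_a / R_b`, so the first bin's relative risk is 1 by construction. Bins
#' with no samples or no cases are excluded from the subsequent log-linear
#' fit (their log relative risk is undefined) and tagged with the reason.
#'
#' @param scores BRCAness scores in `[0, 1]`.
#' @param outcomes 0/1 cancer outcomes.
#' @return An object of class `risk_curve`: data.frame `bins` (center, n,
#'   cases, risk, rr, included, reason) plus `baseline_risk`.
#' @export
relative_risk_curve <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) stop_validation("relative_risk_curve: length mismatch")
  if (any(scores < 0 | scores > 1)) stop_validation("relative_risk_curve: scores must lie in [0, 1]")
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L))) stop_validation("relative_risk_curve: outcomes must be 0/1")
  centers <- risk_bin_centers()
  n <- cases <- integer(length(centers))
  for (i in seq_along(centers)) {
    memb <- bin_membership(scores, centers[i])
    n[i] <- sum(memb)
    cases[i] <- sum(outcomes[memb])
  }
  if (n[1] == 0) stop_validation("baseline undefined: the first bin [0, 0.1) contains no samples")
  if (cases[1] == 0) stop_validation("baseline undefined: the first bin [0, 0.1) contains no cases")
  baseline <- cases[1] / n[1]
  risk <- ifelse(n > 0, cases / n, NA_real_)
  rr <- risk / baseline
  reason <- ifelse(n == 0, "empty", ifelse(cases == 0, "zero-case", ""))
  bins <- data.frame(center = centers, n = n, cases = cases, risk = risk,
                     rr = rr, included = reason == "", reason = reason)
  structure(list(bins = bins, baseline_risk = baseline), class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("<risk_curve: baseline risk %.4f, %d/%d bins usable>\n",
              x$baseline_risk, sum(x$bins$included), nrow(x$bins)))
  invisible(x)
}

#' Log-linear fit of the relative-risk curve
#'
#' Unweighted ordinary least squares of `ln(RR)` on the bin center over the
#' included bins, with the Pearson correlation between the same two vectors,
#' its 95% CI by Fisher z-transform, and a two-sided p-value from the
#' t-distribution with (bins - 2) degrees of freedom.
#'
#' @param curve a `risk_curve` with at least 3 usable bins.
#' @return An object of class `risk_fit`: `slope`, `intercept`, `slope_se`,
#'   `r`, `r_ci`, `p`, `n_bins`, and `r_defined` (FALSE when the log relative
#'   risks have zero variance).
#' @export
fit_log_linear <- function(curve) {
  stopifnot(inherits(curve, "risk_curve"))
  b <- curve$bins[curve$bins$included, ]
  if (nrow(b) < 3) stop_validation("fit_log_linear: fewer than 3 usable bins")
  x <- b$center
  yv <- log(b$rr)
  fit <- lm(yv ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  # summary.lm warns on noiseless (perfect) fits; those are legitimate here
  slope_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (sd(yv) == 0) {
    r <- NA_real_; r_ci <- c(NA_real_, NA_real_); p <- NA_real_; r_def <- FALSE
  } else {
    ct <- suppressWarnings(cor.test(x, yv, conf.level = 0.95))
    r <- unname(ct$estimate)
    r_ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else as.numeric(ct$conf.int)
    p <- ct$p.value
    r_def <- TRUE
  }
  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 r = r, r_ci = r_ci, p = p, n_bins = nrow(b), r_defined = r_def),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("<risk_fit: log RR = %.3f + %.3f * score over %d bins; R = %.3f (95%% CI %.3f-%.3f), p = %.3g>\n",
              x$intercept, x$slope, x$n_bins, x$r, x$r_ci[1], x$r_ci[2], x$p))
  invisible(x)
}

#' Relative risk implied by the fitted curve at a score
#'
#' `exp(intercept + slope * score)`.
#'
#' @param fit a `risk_fit`.
#' @param score BRCAness score(s).
#' @return Relative risk value(s).
#' @export
risk_at_score <- function(fit, score) {
  stopifnot(inherits(fit, "risk_fit"))
  exp(fit$intercept + fit$slope * score)
}
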