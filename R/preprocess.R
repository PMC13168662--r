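#' Fit per-feature normalization
#'
#' Each feature is centered to zero mean and scaled so its maximum absolute
#' value on the fitting table is one: `center` is the column mean and `scale`
#' the maximum absolute deviation from it. Centering first and then dividing
#' by a positive scalar is the only order that leaves both properties holding
#' simultaneously. This puts miRNA MFI values and binary metadata on the same
#' magnitude before the penalized fits.
#'
#' @param table a `feature_table` with no missing cells.
#' @return An object of class `normalization_params` with named numeric
#'   vectors `center` and `scale`.
#' @export
fit_normalization <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  if (anyNA(vals)) stop_validation("normalization requires an imputed table (missing cells present)")
  center <- colMeans(vals)
  scale <- apply(abs(sweep(vals, 2, center, "-")), 2, max)
  if (any(scale <= 0)) {
    bad <- feature_ids(table)[scale <= 0][1]
    stop_validation("feature '%s' is constant; its normalization scale would be 0", bad)
  }
  structure(list(center = center, scale = scale), class = "normalization_params")
}

#' Apply (or invert) frozen normalization
#'
#' `apply_normalization` maps values to `(value - center) / scale`. On the
#' fitting table this yields per-column mean 0 and max |value| 1; external
#' cohorts are transformed with the frozen training parameters and may exceed
#' `[-1, 1]` (no clipping). `invert_normalization` undoes the map.
#'
#' @param table a `feature_table`.
#' @param params a `normalization_params` whose names match the table's
#'   feature ids.
#' @return A transformed `feature_table`.
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(table, "feature_table"), inherits(params, "normalization_params"))
  ids <- feature_ids(table)
  if (!identical(sort(ids), sort(names(params$center))))
    stop_validation("feature ids do not match the normalization parameters")
  out <- table
  out$values <- sweep(sweep(table$values, 2, params$center[ids], "-"),
                      2, params$scale[ids], "/")
  out$modality <- table$modality
  # normalized values may be negative even for miRNA; bypass the constructor's
  # non-negativity check by keeping the class as-is
  out
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(table, params) {
  stopifnot(inherits(table, "feature_table"), inherits(params, "normalization_params"))
  ids <- feature_ids(table)
  out <- table
  out$values <- sweep(sweep(table$values, 2, params$scale[ids], "*"),
                      2, params$center[ids], "+")
  out
}

.norm_to_df <- function(params) {
  data.frame(feature_id = names(params$center),
             center = unname(params$center),
             scale = unname(params$scale))
}

.norm_from_df <- function(df) {
  structure(list(center = stats::setNames(df$center, df$feature_id),
                 scale = stats::setNames(df$scale, df$feature_id)),
            class = "normalization_params")
}
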