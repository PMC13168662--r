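#' Construct a feature table
#'
#' A feature table is the basic container for one modality of a cohort: a
#' samples x features numeric matrix with unique sample and feature
#' identifiers. Missing cells are stored as `NA`; the missing mask is exposed
#' via [missing_mask()]. miRNA expression is recorded in mean fluorescence
#' intensity (MFI) units and must be non-negative where observed; metadata
#' variables are unitless (mostly binary) values.
#'
#' @param values numeric matrix with sample ids as row names and feature ids
#'   as column names. `NA` marks a missing cell.
#' @param modality one of `"miRNA"` or `"metadata"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, modality = c("miRNA", "metadata")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("feature table needs sample ids (row names) and feature ids (column names)")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate sample id: %s", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate feature id: %s", colnames(values)[duplicated(colnames(values))][1])
  if (modality == "miRNA" && any(values < 0, na.rm = TRUE))
    stop_validation("miRNA MFI values must be non-negative where observed")
  structure(list(values = values, modality = modality), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %s, %d samples x %d features, %d missing cells>\n",
              x$modality, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @rdname feature_table
#' @param table a `feature_table`.
#' @export
missing_mask <- function(table) is.na(table$values)

sample_ids <- function(table) rownames(table$values)
feature_ids <- function(table) colnames(table$values)

#' Construct a cohort
#'
#' Bundles the two modality tables with per-sample annotations, all sharing
#' one sample order. `labels` is the germline BRCA1/2 carrier indicator used
#' for training; `cancer_outcome` and `days_to_diagnosis` describe the 5-year
#' cancer window of an external validation cohort; `subgroups` holds
#' categorical annotations (race/ethnicity bucket, age decade, cancer-history
#' flag) for stratified evaluation.
#'
#' @param mirna,metadata `feature_table`s over the same samples in the same order.
#' @param labels optional 0/1 carrier labels.
#' @param cancer_outcome optional 0/1 five-year cancer outcome.
#' @param days_to_diagnosis optional positive integer days, defined only where
#'   `cancer_outcome == 1` (`NA` elsewhere).
#' @param subgroups optional data.frame of categorical columns.
#' @param latent_score optional per-sample latent score in `[0,1]` recorded by
#'   the synthetic generators (the ground-truth risk driver).
#' @return An object of class `cohort`.
#' @export
cohort <- function(mirna, metadata, labels = NULL, cancer_outcome = NULL,
                   days_to_diagnosis = NULL, subgroups = NULL,
                   latent_score = NULL) {
  stopifnot(inherits(mirna, "feature_table"), inherits(metadata, "feature_table"))
  ids <- sample_ids(mirna)
  if (!identical(ids, sample_ids(metadata)))
    stop_validation("miRNA and metadata tables disagree on sample ids/order")
  n <- length(ids)
  chk_binary <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) != n) stop_validation("%s must have one entry per sample", what)
    if (!all(v %in% c(0L, 1L))) stop_validation("%s must be 0/1", what)
    as.integer(v)
  }
  labels <- chk_binary(labels, "labels")
  cancer_outcome <- chk_binary(cancer_outcome, "cancer_outcome")
  if (!is.null(days_to_diagnosis)) {
    if (length(days_to_diagnosis) != n)
      stop_validation("days_to_diagnosis must have one entry per sample")
    if (is.null(cancer_outcome))
      stop_validation("days_to_diagnosis requires cancer_outcome")
    bad <- !is.na(days_to_diagnosis) & cancer_outcome == 0L
    if (any(bad))
      stop_validation("days_to_diagnosis present for %d non-case sample(s)", sum(bad))
    if (any(days_to_diagnosis[!is.na(days_to_diagnosis)] < 1))
      stop_validation("days_to_diagnosis must be positive")
  }
  if (!is.null(subgroups)) {
    subgroups <- as.data.frame(subgroups, stringsAsFactors = FALSE)
    if (nrow(subgroups) != n) stop_validation("subgroups must have one row per sample")
    rownames(subgroups) <- ids
  }
  structure(list(mirna = mirna, metadata = metadata, labels = labels,
                 cancer_outcome = cancer_outcome,
                 days_to_diagnosis = days_to_diagnosis,
                 subgroups = subgroups, latent_score = latent_score,
                 sample_ids = ids),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d samples, %d miRNAs, %d metadata variables%s%s>\n",
              length(x$sample_ids), ncol(x$mirna$values), ncol(x$metadata$values),
              if (!is.null(x$labels)) sprintf(", %d carriers", sum(x$labels)) else "",
              if (!is.null(x$cancer_outcome)) sprintf(", %d cancer cases", sum(x$cancer_outcome)) else ""))
  invisible(x)
}

# Delimiter by file extension: .csv -> comma, anything else (.tsv/.txt/.tab)
# -> tab.
.table_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

.read_feature_file <- function(path, modality) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  raw <- read.csv(path, sep = .table_sep(path), check.names = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop_validation("'%s' has no feature columns", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop_validation("duplicate sample id '%s' in %s",
                                          ids[duplicated(ids)][1], path)
  vals <- vapply(raw[-1], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, colnames(raw)[-1]))
  feature_table(vals, modality)
}

.read_samples_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  df <- read.csv(path, sep = .table_sep(path), check.names = FALSE,
                 na.strings = c("NA", ""))
  if (anyDuplicated(df[[1]]))
    stop_validation("duplicate sample id in %s", path)
  rownames(df) <- df[[1]]
  df
}

#' Read a cohort from a manifest
#'
#' The manifest is a YAML file whose paths are resolved relative to its own
#' location. Recognised keys: `mirna`, `metadata` (delimited feature tables,
#' header row = feature ids, first column = sample id), and optionally
#' `samples` (a per-sample annotation table) together with `label`,
#' `outcome`, `days_to_diagnosis`, `subgroups` naming columns of that table.
#' Sample order follows the miRNA table, restricted to the ids present in
#' every referenced file; unparseable numeric cells become missing.
#'
#' @param manifest_path path to the manifest file.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("cannot read '%s': no such file", manifest_path), call. = FALSE)
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  mirna <- .read_feature_file(resolve(man$mirna), "miRNA")
  metadata <- .read_feature_file(resolve(man$metadata), "metadata")
  ids <- intersect(sample_ids(mirna), sample_ids(metadata))
  samples <- NULL
  if (!is.null(man$samples)) {
    samples <- .read_samples_file(resolve(man$samples))
    ids <- intersect(ids, rownames(samples))
  }
  if (length(ids) == 0) stop_validation("no overlapping sample ids across cohort files")
  ids <- sample_ids(mirna)[sample_ids(mirna) %in% ids]  # manifest (miRNA-file) order
  mirna <- feature_table(mirna$values[ids, , drop = FALSE], "miRNA")
  metadata <- feature_table(metadata$values[ids, , drop = FALSE], "metadata")
  pull <- function(key) {
    if (is.null(man[[key]]) || is.null(samples)) return(NULL)
    if (!man[[key]] %in% colnames(samples))
      stop_validation("manifest column '%s' absent from samples table", man[[key]])
    samples[ids, man[[key]]]
  }
  subg <- NULL
  if (!is.null(man$subgroups) && !is.null(samples)) {
    miss <- setdiff(unlist(man$subgroups), colnames(samples))
    if (length(miss)) stop_validation("subgroup column(s) absent: %s", paste(miss, collapse = ", "))
    subg <- samples[ids, unlist(man$subgroups), drop = FALSE]
  }
  cohort(mirna, metadata,
         labels = pull("label"),
         cancer_outcome = pull("outcome"),
         days_to_diagnosis = pull("days_to_diagnosis"),
         subgroups = subg,
         latent_score = pull("latent_score"))
}

#' Write a cohort to delimited files plus a manifest
#'
#' Inverse of [read_cohort()]: writes `mirna.csv`, `metadata.csv`,
#' `samples.csv` and `manifest.yml` under `dir`.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tab, file) {
    df <- data.frame(sample_id = sample_ids(tab), tab$values,
                     check.names = FALSE, row.names = NULL)
    write.csv(df, file.path(dir, file), row.names = FALSE, na = "NA")
  }
  wr(x$mirna, "mirna.csv")
  wr(x$metadata, "metadata.csv")
  samples <- data.frame(sample_id = x$sample_ids, row.names = NULL)
  man <- list(mirna = "mirna.csv", metadata = "metadata.csv", samples = "samples.csv")
  if (!is.null(x$labels)) { samples$label <- x$labels; man$label <- "label" }
  if (!is.null(x$cancer_outcome)) { samples$outcome <- x$cancer_outcome; man$outcome <- "outcome" }
  if (!is.null(x$days_to_diagnosis)) {
    samples$days_to_diagnosis <- x$days_to_diagnosis
    man$days_to_diagnosis <- "days_to_diagnosis"
  }
  if (!is.null(x$latent_score)) { samples$latent_score <- x$latent_score; man$latent_score <- "latent_score" }
  if (!is.null(x$subgroups)) {
    samples <- cbind(samples, x$subgroups)
    man$subgroups <- colnames(x$subgroups)
  }
  write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE, na = "NA")
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Mean-impute missing cells of a feature table
#'
#' With `record = NULL` the per-feature fill value is the mean of the observed
#' cells (the training-set statistic) and the fitted record is returned so it
#' can be frozen into a model bundle. Supplying a record (external cohort)
#' applies its fill values unchanged. Observed cells are never altered and the
#' operation is idempotent.
#'
#' @param table a `feature_table`.
#' @param record an `imputation_record` from a previous call, or `NULL` to fit.
#' @return A list with elements `table` (no missing cells) and `record`.
#' @export
impute_missing <- function(table, record = NULL) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  if (is.null(record)) {
    fill <- colMeans(vals, na.rm = TRUE)
    if (any(!is.finite(fill))) {
      bad <- feature_ids(table)[!is.finite(fill)][1]
      stop_validation("feature '%s' is fully missing; cannot fit imputation", bad)
    }
  } else {
    stopifnot(inherits(record, "imputation_record"))
    if (!all(feature_ids(table) %in% names(record$fill)))
      stop_validation("imputation record lacks fill values for some features")
    fill <- record$fill[feature_ids(table)]
  }
  n_imputed <- colSums(is.na(vals))
  for (j in which(n_imputed > 0)) {
    miss <- is.na(vals[, j])
    vals[miss, j] <- fill[j]
  }
  out <- table
  out$values <- vals
  rec <- structure(list(fill = fill, n_imputed = n_imputed),
                   class = "imputation_record")
  list(table = out, record = rec)
}
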