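#' Feature abundance tables
#'
#' A `feature_table` is the package's basic container: a non-negative numeric
#' matrix of samples (rows) by features (columns), tagged with the kingdom of
#' the features (`bacteria`, `virus`, `metabolite` or `other`) and the scale
#' the values are on (`relative`, `absolute` or `concentration`). Rows of a
#' relative-scale table must each sum to at most 1 (closure is checked on
#' construction).
#'
#' @param values numeric matrix, samples x features, with unique row and
#'   column names and no missing entries.
#' @param kingdom one of `"bacteria"`, `"virus"`, `"metabolite"`, `"other"`.
#' @param scale one of `"relative"`, `"absolute"`, `"concentration"`.
#' @return An object of class `feature_table` (a matrix with attributes
#'   `kingdom` and `scale`).
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' feature_table(m, "bacteria", "relative")
#' @export
feature_table <- function(values,
                          kingdom = c("bacteria", "virus", "metabolite", "other"),
                          scale = c("relative", "absolute", "concentration")) {
  kingdom <- match.arg(kingdom)
  scale <- match.arg(scale)
  .assert(is.matrix(values) && is.numeric(values), "`values` must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "`values` must carry sample (row) and feature (column) names")
  .assert(!anyDuplicated(rownames(values)), "duplicate sample ids")
  .assert(!anyDuplicated(colnames(values)), "duplicate feature ids")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]), call. = FALSE)
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]), call. = FALSE)
  }
  if (scale == "relative") {
    rs <- rowSums(values)
    .assert(all(rs <= 1 + 1e-6),
            "relative-scale rows must sum to <= 1 (worst row sums to %.6f)", max(rs))
  }
  structure(values, kingdom = kingdom, scale = scale, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "kingdom"), attr(x, "scale")))
  invisible(x)
}

#' @rdname feature_table
#' @param x object to test.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

# strip class/attrs for plain matrix maths
#' @keywords internal
#' @noRd
.ft_values <- function(x) {
  if (is_feature_table(x)) {
    y <- unclass(x)
    attr(y, "kingdom") <- NULL
    attr(y, "scale") <- NULL
    y
  } else x
}

#' Read a feature table from tab-separated text
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' All cells must parse as non-negative numbers; the offending cell is named
#' in the error otherwise. Row and column order are preserved from the file.
#'
#' @param path path to a TSV file.
#' @inheritParams feature_table
#' @param missing how to treat empty/NA cells: `"error"` (default) or
#'   `"zero"` to replace them with explicit zeros.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, kingdom = "bacteria", scale = "relative",
                               missing = c("error", "zero")) {
  missing <- match.arg(missing)
  .assert(file.exists(path), "file not found: %s", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  .assert(!anyDuplicated(header), "duplicate feature ids in header: %s",
          paste(unique(header[duplicated(header)]), collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  .assert(ncol(raw) >= 2, "need a sample-id column plus at least one feature column")
  sample_ids <- raw[[1]]
  feats <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(feats), nrow(feats), ncol(feats),
                                 dimnames = list(sample_ids, header)))
  bad <- which(is.na(num) & !(feats == "" | is.na(feats) | toupper(feats) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d (sample '%s'), column '%s': '%s'",
                 bad[1, 1], sample_ids[bad[1, 1]], colnames(num)[bad[1, 2]],
                 feats[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num) && missing == "zero") num[is.na(num)] <- 0
  feature_table(num, kingdom = kingdom, scale = scale)
}

#' Write a feature table as tab-separated text
#'
#' Inverse of [read_feature_table()]: header row of feature ids, first column
#' `sample_id`.
#'
#' @param table a [feature_table] or named numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  m <- .ft_values(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample metadata for a case/control cohort
#'
#' Validates a per-sample metadata table: a binary `status` column (case = 1,
#' control = 0), optional `subtype`, numeric or binary covariates, and numeric
#' phenotype scores. Binary covariates must be coded 0/1.
#'
#' @param df data.frame with a `sample_id` column and a `status` column.
#' @param covariates character vector naming covariate columns (may be empty).
#' @param phenotypes character vector naming phenotype columns (may be empty).
#' @return A validated `sample_metadata` data.frame with attributes
#'   `covariates` and `phenotypes`.
#' @export
sample_metadata <- function(df, covariates = character(), phenotypes = character()) {
  .assert(is.data.frame(df), "`df` must be a data.frame")
  .assert(all(c("sample_id", "status") %in% names(df)),
          "metadata needs `sample_id` and `status` columns")
  .assert(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  .assert(.is_binary(df$status), "`status` must be coded 0 (control) / 1 (case)")
  missing_cols <- setdiff(c(covariates, phenotypes), names(df))
  .assert(length(missing_cols) == 0, "metadata lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  for (cv in covariates) {
    .assert(is.numeric(df[[cv]]), "covariate `%s` must be numeric (0/1 for binary)", cv)
    .assert(!anyNA(df[[cv]]), "covariate `%s` has missing values; imputation is not supported", cv)
  }
  rownames(df) <- df$sample_id
  structure(df, covariates = covariates, phenotypes = phenotypes,
            class = c("sample_metadata", "data.frame"))
}

#' Read sample metadata from tab-separated text
#'
#' @param path TSV with header; must include `sample_id` and `status` columns.
#' @inheritParams sample_metadata
#' @export
read_sample_metadata <- function(path, covariates = character(), phenotypes = character()) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_metadata(df, covariates = covariates, phenotypes = phenotypes)
}

#' Write sample metadata as tab-separated text
#' @param meta a `sample_metadata` or data.frame.
#' @param path output file path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a metadata table to a feature table's samples; every sample must
# resolve to exactly one metadata row
#' @keywords internal
#' @noRd
.align_meta <- function(table, meta) {
  ids <- rownames(.ft_values(table))
  missing <- setdiff(ids, meta$sample_id)
  .assert(length(missing) == 0, "samples missing from metadata: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  meta[match(ids, meta$sample_id), , drop = FALSE]
}
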