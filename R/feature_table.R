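# Feature table container: one row per sample, 86 (or fewer, after
# selection) named indicator columns plus identity and label columns.

#' Construct a feature table
#'
#' @param features numeric matrix or data.frame of indicators (columns named).
#' @param cultivar character/factor cultivar label per row.
#' @param germination optional germination stage per row
#'   (`early`/`mesophytic`/`late`, or `NA`).
#' @param sample_id optional sample identifiers.
#' @return a `feature_table` (a data.frame with columns `sample_id`,
#'   `cultivar`, `germination`, then the indicators; the indicator names are
#'   kept in `attr(, "feature_names")`).
#' @export
feature_table <- function(features, cultivar, germination = NA, sample_id = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_len(n))
  stopifnot(length(cultivar) == n)
  germination <- rep_len(as.character(germination), n)
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          cultivar = as.character(cultivar),
                          germination = germination,
                          stringsAsFactors = FALSE),
               features)
  attr(out, "feature_names") <- colnames(features)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d indicators, %d cultivar(s)\n",
              nrow(x), length(feature_names(x)), length(unique(x$cultivar))))
  invisible(x)
}

#' Indicator column names of a feature table
#' @param table a `feature_table`.
#' @return character vector of indicator names.
#' @export
feature_names <- function(table) {
  fn <- attr(table, "feature_names")
  fn %||% setdiff(colnames(table), c("sample_id", "cultivar", "germination"))
}

#' Numeric indicator matrix of a feature table
#' @param table a `feature_table`.
#' @param variables optional subset of indicator names.
#' @return numeric matrix (samples x indicators).
#' @export
feature_matrix <- function(table, variables = NULL) {
  fn <- feature_names(table)
  if (!is.null(variables)) {
    missing <- setdiff(variables, fn)
    if (length(missing))
      stopf("variables not in table: %s", paste(missing, collapse = ", "))
    fn <- variables
  }
  as.matrix(as.data.frame(table)[, fn, drop = FALSE])
}

#' Subset the indicator columns of a feature table
#' @param table a `feature_table`.
#' @param variables indicator names to keep.
#' @return a `feature_table` restricted to `variables`.
#' @export
select_features <- function(table, variables) {
  m <- feature_matrix(table, variables)
  feature_table(m, table$cultivar, table$germination, table$sample_id)
}

#' Write / read a feature table as CSV
#'
#' The on-disk format is `sample_id, cultivar, germination`, then the named
#' indicator columns.
#' @param table a `feature_table`.
#' @param path CSV path.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fn <- setdiff(colnames(df), c("sample_id", "cultivar", "germination"))
  feature_table(df[, fn, drop = FALSE], df$cultivar,
                df$germination %||% NA, df$sample_id)
}
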