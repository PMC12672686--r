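#' Table I/O
#'
#' Event, truth and enumeration tables are written as CSV or Parquet, chosen
#' by file extension (Parquet requires the arrow package).
#'
#' @name io
NULL

#' Write a table to CSV or Parquet
#' @param x data.frame.
#' @param path destination (`.csv` or `.parquet`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for Parquet output")
    arrow::write_parquet(x, path)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for Parquet input")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}
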