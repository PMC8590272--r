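#' Read a clustered binary dataset from CSV
#'
#' Reads and validates a dataset in the package schema: columns
#' `cluster_id`, `x1`, `x2`, `xh`, `y` (an optional `u_h` column of true
#' random effects is kept when present). Validation errors name the
#' offending columns or rows.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble in the [simulate_clustered()] schema.
#' @export
read_clustered <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cluster_id", "x1", "x2", "xh", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("Malformed dataset `", path, "`: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("x1", "x2")) {
    if (!is.numeric(data[[col]])) {
      stop("Malformed dataset: column `", col, "` is not numeric.",
           call. = FALSE)
    }
  }
  bad_y <- which(!data$y %in% c(0, 1))
  if (length(bad_y)) {
    stop("Malformed dataset: `y` not in {0,1} at row(s) ",
         paste(utils::head(bad_y, 5), collapse = ", "), call. = FALSE)
  }
  bad_xh <- which(!data$xh %in% c(0, 1))
  if (length(bad_xh)) {
    stop("Malformed dataset: `xh` not in {0,1} at row(s) ",
         paste(utils::head(bad_xh, 5), collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(required, "u_h"), names(data))
  data[keep]
}

#' Write a clustered binary dataset to CSV
#'
#' Writes the standard schema (`cluster_id,x1,x2,xh,y`), UTF-8 with a
#' header row and "." as the decimal mark. The true random effects are
#' dropped unless `keep_truth = TRUE`.
#'
#' @param data A dataset tibble in the [simulate_clustered()] schema.
#' @param path Output file path.
#' @param keep_truth Also write the `u_h` column when present.
#' @return Invisibly, `path`.
#' @export
write_clustered <- function(data, path, keep_truth = FALSE) {
  cols <- c("cluster_id", "x1", "x2", "xh", "y")
  if (keep_truth && "u_h" %in% names(data)) cols <- c(cols, "u_h")
  readr::write_csv(data[cols], path, progress = FALSE)
  invisible(path)
}
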