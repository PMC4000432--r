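#' Read a long-format subject-level CSV into cluster datasets
#'
#' Reads a comma-separated file with one row per subject, a cluster
#' identifier column and one or more outcome columns, and returns one
#' [cluster_dataset] per outcome column. Rows with a missing value in a
#' given outcome column are dropped for that outcome only (listwise
#' deletion per variable), so each variable keeps its own analysable N --
#' the reason per-variable mean cluster sizes differ in multicenter
#' reports.
#'
#' @param path path to a CSV file (comma separator, header row, decimal
#'   point, UTF-8).
#' @param cluster_col name of the column holding the cluster label.
#' @param outcome_cols character vector of outcome column names; default
#'   `NULL` means every column except `cluster_col`.
#' @param type_map optional named character vector/list mapping outcome
#'   column names to `"binary"`, `"continuous"` or `"auto"`; columns not
#'   named default to `"auto"`.
#'
#' @return A named list of [cluster_dataset] objects, one per outcome column.
#' @seealso [write_results_csv()], [estimate_all()]
#' @export
read_long_csv <- function(path, cluster_col, outcome_cols = NULL,
                          type_map = NULL) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!cluster_col %in% names(df)) {
    stop_input("cluster column '%s' not found in %s", cluster_col, path)
  }
  if (is.null(outcome_cols)) {
    outcome_cols <- setdiff(names(df), cluster_col)
  }
  missing_cols <- setdiff(outcome_cols, names(df))
  if (length(missing_cols)) {
    stop_input("outcome column(s) not found: %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!length(outcome_cols)) stop_input("no outcome columns to read")
  out <- vector("list", length(outcome_cols))
  names(out) <- outcome_cols
  for (col in outcome_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      # blanks arrive as "" when a character column; coerce, require numeric
      v[!nzchar(trimws(v))] <- NA
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        stop_input("column '%s' contains non-numeric values", col)
      }
      v <- vn
    }
    if (!is.numeric(v) && !is.logical(v)) {
      stop_input("column '%s' is not numeric", col)
    }
    keep <- !is.na(v)
    if (!any(keep)) stop_degenerate("column '%s' has no non-missing values", col)
    type <- "auto"
    if (!is.null(type_map) && col %in% names(type_map)) {
      type <- match.arg(type_map[[col]], c("auto", "binary", "continuous"))
    }
    out[[col]] <- cluster_dataset(as.numeric(v[keep]), df[[cluster_col]][keep],
                                  variable = col, type = type)
  }
  out
}

# rendering conventions of the printed tables: ICC and CI to 3 decimals with
# values below 0.001 shown as "<0.001"; prevalence/mean and Deff to 1
# decimal; mean cluster size as an integer.
render_icc <- function(x, censored = FALSE) {
  ifelse(censored | x < 0.001, "<0.001", sprintf("%.3f", x))
}

#' Write an ICC results table as CSV in the printed-table layout
#'
#' Writes the per-variable results in the layout of the published tables:
#' ICC and confidence bounds to 3 decimals (values below 0.001 rendered
#' `"<0.001"`), prevalence/mean and Deff to 1 decimal, mean cluster size as
#' an integer. [read_results_csv()] inverts the rendering, so
#' write-then-read is the identity at the rendered precision.
#'
#' @param table an `icc_table` (from [estimate_all()] or
#'   [load_emip_fixture()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  if (!inherits(table, "icc_table")) stop_input("'table' must be an icc_table")
  if (nrow(table) == 0L) stop_input("refusing to write an empty results table")
  censored <- if ("censored" %in% names(table)) table$censored else FALSE
  out <- data.frame(
    table_id = table$table_id,
    variable = table$variable,
    var_type = table$var_type,
    estimate = sprintf("%.1f", table$estimate),
    icc      = render_icc(table$icc, censored),
    ci_low   = ifelse(table$ci_low < 0.001, "<0.001", sprintf("%.3f", table$ci_low)),
    ci_high  = sprintf("%.3f", table$ci_high),
    deff     = sprintf("%.1f", table$deff),
    n_a      = as.integer(round(table$n_a)),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write results to '%s'", path)
  invisible(path)
}

#' Read back a results CSV written by [write_results_csv()]
#'
#' Parses the rendered table layout: `"<0.001"` ICC entries become numeric 0
#' with `censored = TRUE`, `"<0.001"` lower confidence bounds become 0.
#'
#' @param path path to a results CSV.
#' @return An `icc_table` with provenance `"computed"`.
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("table_id", "variable", "var_type", "estimate", "icc",
            "ci_low", "ci_high", "deff", "n_a")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input("results file lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  censored <- df$icc == "<0.001"
  df$icc <- ifelse(censored, 0, suppressWarnings(as.numeric(df$icc)))
  df$ci_low <- ifelse(df$ci_low == "<0.001", 0,
                      suppressWarnings(as.numeric(df$ci_low)))
  df$estimate <- as.numeric(df$estimate)
  df$ci_high <- as.numeric(df$ci_high)
  df$deff <- as.numeric(df$deff)
  df$n_a <- as.numeric(df$n_a)
  df$censored <- censored
  icc_table(df, provenance = "computed")
}
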