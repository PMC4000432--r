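#' Construct an ICC results table
#'
#' Container for per-variable results in the layout of the published
#' tables: one row per variable with its prevalence (in %, binary) or mean
#' (continuous), ICC point estimate with 95% confidence bounds, design
#' effect and mean cluster size. Variable names must be unique within a
#' table id.
#'
#' @param df data frame with columns `table_id`, `variable`, `var_type`,
#'   `estimate`, `icc`, `ci_low`, `ci_high`, `deff`, `n_a`, `censored`
#'   (extra columns are kept).
#' @param provenance `"computed"` (estimated from subject-level data) or
#'   `"fixture"` (transcribed from the published tables).
#' @return An object of class `icc_table` (a data frame).
#' @export
icc_table <- function(df, provenance = c("computed", "fixture")) {
  provenance <- match.arg(provenance)
  need <- c("table_id", "variable", "var_type", "estimate", "icc",
            "ci_low", "ci_high", "deff", "n_a", "censored")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input("icc_table lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$table_id, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop_input("duplicated variable name(s) within a table: %s",
               paste(unique(df$variable[duplicated(key)]), collapse = ", "))
  }
  df$censored <- as.logical(df$censored)
  structure(df, class = c("icc_table", "data.frame"), provenance = provenance)
}

# printed row counts of the bundled transcription, used as its integrity check
emip_table_rows <- c(T1 = 24L, T2 = 14L, T3 = 12L, T4 = 44L, T5 = 43L,
                     T6 = 35L, T7 = 27L, T8 = 15L, T9 = 18L, T10 = 29L)

#' Load the bundled EMIP per-variable ICC tables
#'
#' Returns the machine-readable transcription of the 261 per-variable rows
#' published by the Brazilian Multicenter Study on Preterm Birth (EMIP): 20
#' referral hospitals (clusters), 5,296 births, tables T1--T10 covering
#' maternal characteristics, socio-demographics, pregnancy and labor
#' process variables, newborn outcomes, and preterm-birth management.
#'
#' Rows printed as ICC `"<0.001"` are stored as numeric 0 with
#' `censored = TRUE`; their exact (sub-0.001) values cannot change any
#' median or threshold proportion reported by [summarize_icc()]. Rows that
#' belong to a labelled sub-block of a printed table carry the block label
#' as a `"Block: item"` prefix so that variable names are unique within
#' each table. Prevalences printed `"<0.1"` are stored as 0.
#'
#' @return An `icc_table` with 261 rows and provenance `"fixture"`.
#' @examples
#' emip <- load_emip_fixture()
#' subset(emip, variable == "Skin color (white)")
#' summarize_icc(emip)
#' @export
load_emip_fixture <- function() {
  path <- system.file("extdata", "emip_tables.csv", package = "clustericc",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop_fixture("bundled fixture emip_tables.csv not found")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) != sum(emip_table_rows)) {
    stop_fixture("fixture corrupt: expected %d rows, found %d",
                 sum(emip_table_rows), nrow(df))
  }
  counts <- table(df$table_id)
  for (tid in names(emip_table_rows)) {
    n <- if (tid %in% names(counts)) counts[[tid]] else 0L
    if (n != emip_table_rows[[tid]]) {
      stop_fixture("fixture corrupt: table %s has %d rows, expected %d",
                   tid, n, emip_table_rows[[tid]])
    }
  }
  bad <- with(df, icc < 0 | icc > 1 | ci_low > ci_high | deff < 0 |
                (censored == 1 & icc != 0))
  if (any(bad)) {
    stop_fixture("fixture corrupt: inconsistent row(s): %s",
                 paste(df$variable[bad], collapse = ", "))
  }
  icc_table(df, provenance = "fixture")
}

#' @export
print.icc_table <- function(x, n = 10L, ...) {
  cat(sprintf("<icc_table> %d variables (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "computed"))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
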