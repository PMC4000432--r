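#' Subject-level observations for one variable, grouped by cluster
#'
#' A `cluster_dataset` is the sole input of all estimators in this package:
#' one outcome value per subject plus the label of the cluster (primary
#' sampling unit, e.g. a hospital) the subject belongs to. Binary variables
#' must be coded 0/1; multi-category variables are analysed as one 0/1
#' indicator per level.
#'
#' @param value numeric vector of outcome values; all values must be finite
#'   (drop missing values before construction, or use [read_long_csv()]
#'   which performs per-variable listwise deletion).
#' @param cluster vector of cluster labels, same length as `value`;
#'   coerced to character. Labels must be non-empty.
#' @param variable name of the variable (used in messages and results).
#' @param type `"binary"`, `"continuous"`, or `"auto"` (default), which
#'   classifies the variable as binary iff all values lie in \{0, 1\}.
#'
#' @return An object of class `cluster_dataset`: a list with elements
#'   `variable`, `var_type`, `value`, `cluster` (factor), `a` (number of
#'   clusters), `N` (total observations) and `n_i` (per-cluster counts).
#'
#' @details At least two clusters are required (`a >= 2`): with a single
#'   cluster there is no between-cluster variance to estimate.
#'
#' @examples
#' d <- cluster_dataset(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' d$a
#' @export
cluster_dataset <- function(value, cluster, variable = "y",
                            type = c("auto", "binary", "continuous")) {
  type <- match.arg(type)
  if (!is.numeric(value)) {
    stop_input("'%s': outcome values must be numeric", variable)
  }
  value <- as.numeric(value)
  if (length(value) != length(cluster)) {
    stop_input("'%s': value and cluster lengths differ (%d vs %d)",
               variable, length(value), length(cluster))
  }
  if (length(value) == 0L) {
    stop_degenerate("'%s': no observations", variable)
  }
  if (!all(is.finite(value))) {
    stop_input("'%s': all outcome values must be finite (remove missing values first)",
               variable)
  }
  cluster <- as.character(cluster)
  if (anyNA(cluster) || any(!nzchar(cluster))) {
    stop_input("'%s': cluster labels must be non-empty", variable)
  }
  cluster <- factor(cluster)
  var_type <- switch(type,
    auto = if (all(value %in% c(0, 1))) "binary" else "continuous",
    type)
  if (var_type == "binary" && !all(value %in% c(0, 1))) {
    stop_input("'%s': binary variables must be coded 0/1", variable)
  }
  a <- nlevels(cluster)
  if (a < 2L) {
    stop_degenerate(
      "'%s': at least 2 clusters with data are required, found %d",
      variable, a)
  }
  structure(
    list(variable = variable, var_type = var_type,
         value = value, cluster = cluster,
         a = a, N = length(value),
         n_i = tabulate(cluster, nbins = a)),
    class = "cluster_dataset")
}

#' @export
print.cluster_dataset <- function(x, ...) {
  cat(sprintf("<cluster_dataset> '%s' (%s): N = %d subjects in a = %d clusters\n",
              x$variable, x$var_type, x$N, x$a))
  cat(sprintf("  cluster sizes: min %d, mean %.1f, max %d\n",
              min(x$n_i), mean(x$n_i), max(x$n_i)))
  if (x$var_type == "binary") {
    cat(sprintf("  prevalence: %.1f%%\n", 100 * mean(x$value)))
  } else {
    cat(sprintf("  mean: %.2f  sd: %.2f\n", mean(x$value), stats::sd(x$value)))
  }
  invisible(x)
}
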