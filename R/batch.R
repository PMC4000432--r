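#' Estimate ICC, confidence interval and design effect for many variables
#'
#' Runs the full per-variable pipeline over a collection of cluster
#' datasets: prevalence (%) or mean, ANOVA ICC (Kish formula) with its
#' confidence interval, exact design-effect ratio, and mean cluster size
#' `n_a = N / a` (non-missing N over clusters contributing at least one
#' observation). Variables whose estimation fails (zero variance, all
#' singletons, ...) are kept in the output with the failure reason in the
#' `failure` column -- never silently dropped.
#'
#' @param datasets a list of [cluster_dataset] objects (e.g. from
#'   [read_long_csv()] or [simulate_emip_like_study()]).
#' @param alpha two-sided type-I error for the confidence intervals.
#' @param ci_method passed to [icc_confidence_interval()].
#' @param table_id optional table label(s) recycled across rows.
#' @return An `icc_table` (provenance `"computed"`) with one row per input
#'   variable; extra columns `se`, `rho_raw` and `failure`.
#' @examples
#' \donttest{
#' study <- simulate_emip_like_study(seed = 1)
#' tab <- estimate_all(study)
#' head(tab)
#' }
#' @export
estimate_all <- function(datasets, alpha = 0.05,
                         ci_method = c("fpivot", "wald"), table_id = NA) {
  ci_method <- match.arg(ci_method)
  if (inherits(datasets, "cluster_dataset")) datasets <- list(datasets)
  if (!is.list(datasets) || length(datasets) == 0L) {
    stop_input("'datasets' must be a non-empty list of cluster_dataset objects")
  }
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (!inherits(d, "cluster_dataset")) {
      stop_input("element %d is not a cluster_dataset", i)
    }
    base <- data.frame(
      table_id = NA_character_, variable = d$variable, var_type = d$var_type,
      estimate = if (d$var_type == "binary") 100 * mean(d$value) else mean(d$value),
      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      deff = NA_real_, n_a = d$N / d$a, censored = NA,
      se = NA_real_, rho_raw = NA_real_, failure = NA_character_,
      stringsAsFactors = FALSE)
    tryCatch({
      est <- icc_anova(d, alpha = alpha, method = "kish", ci_method = ci_method)
      de <- deff_ratio(d)
      base$icc <- est$rho
      base$ci_low <- est$ci_low
      base$ci_high <- est$ci_high
      base$se <- est$se
      base$rho_raw <- est$rho_raw
      base$deff <- de$deff_ratio
      base$censored <- est$rho < 0.001
      base
    }, clustericc_error = function(e) {
      base$failure <- conditionMessage(e)
      base
    })
  })
  out <- do.call(rbind, rows)
  out$table_id <- rep_len(as.character(table_id), nrow(out))
  icc_table(out, provenance = "computed")
}

#' Aggregate statistics of an ICC results table
#'
#' Computes the aggregate statistics a multicenter ICC report prints over
#' its per-variable tables: median/min/max ICC, the percentage of
#' variables with ICC strictly below each threshold, median/min/max design
#' effect, and per-group medians. Censored ICCs (printed `"<0.001"`) enter
#' as 0; rows with a `failure` are excluded (and counted).
#'
#' Conventions matched to the printed reports: the median of an even
#' number of values is the midpoint of the two central values; threshold
#' comparisons are strict (`<`); percentages are rounded half-up to one
#' decimal.
#'
#' @param table an `icc_table`.
#' @param thresholds numeric vector of ICC thresholds (default `c(0.1, 0.3)`).
#' @param groups optional grouping for the per-group medians: either a
#'   named vector/list mapping variable names to group labels, or the name
#'   of a column of `table` (default `"table_id"` when present). Every
#'   mapped variable must exist in the table.
#' @return An object of class `icc_summary`: `n_variables`, `n_failed`,
#'   `icc_median`, `icc_min`, `icc_max`, `prop_below` (named percentage
#'   vector), `deff_median`, `deff_min`, `deff_max`, `group_icc_medians`,
#'   `group_deff_medians`.
#' @examples
#' summarize_icc(load_emip_fixture())
#' @export
summarize_icc <- function(table, thresholds = c(0.1, 0.3),
                          groups = "table_id") {
  if (!inherits(table, "icc_table")) stop_input("'table' must be an icc_table")
  if (nrow(table) == 0L) stop_input("cannot summarize an empty table")
  df <- as.data.frame(table)
  failed <- if ("failure" %in% names(df)) !is.na(df$failure) else rep(FALSE, nrow(df))
  df <- df[!failed, , drop = FALSE]
  if (nrow(df) == 0L) stop_degenerate("every variable failed estimation")
  icc <- ifelse(df$censored, 0, df$icc)
  if (length(thresholds)) {
    thresholds <- sort(thresholds)
    prop_below <- vapply(thresholds,
                         function(t) round_half_up(100 * mean(icc < t), 1),
                         numeric(1))
    names(prop_below) <- format(thresholds)
  } else prop_below <- numeric(0)

  grp <- NULL
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1 && is.null(names(groups))) {
      if (groups %in% names(df)) grp <- as.character(df[[groups]])
    } else {
      groups <- unlist(groups)
      unknown <- setdiff(names(groups), df$variable)
      if (length(unknown)) {
        stop_input("group map names unknown variable(s): %s",
                   paste(unknown, collapse = ", "))
      }
      grp <- as.character(groups[match(df$variable, names(groups))])
    }
  }
  group_icc_medians <- group_deff_medians <- NULL
  if (!is.null(grp) && any(!is.na(grp))) {
    keep <- !is.na(grp)
    group_icc_medians <- tapply(icc[keep], grp[keep], stats::median)
    group_deff_medians <- tapply(df$deff[keep], grp[keep], stats::median)
  }
  structure(
    list(n_variables = nrow(df), n_failed = sum(failed),
         icc_median = stats::median(icc), icc_min = min(icc), icc_max = max(icc),
         prop_below = prop_below,
         deff_median = stats::median(df$deff),
         deff_min = min(df$deff), deff_max = max(df$deff),
         group_icc_medians = group_icc_medians,
         group_deff_medians = group_deff_medians),
    class = "icc_summary")
}

#' @export
print.icc_summary <- function(x, ...) {
  cat(sprintf("<icc_summary> %d variables%s\n", x$n_variables,
              if (x$n_failed) sprintf(" (+%d failed)", x$n_failed) else ""))
  cat(sprintf("  ICC: median %.3f, range %s-%.3f\n",
              x$icc_median, render_icc(x$icc_min), x$icc_max))
  for (t in names(x$prop_below)) {
    cat(sprintf("  ICC < %s in %.1f%% of variables\n", t, x$prop_below[[t]]))
  }
  cat(sprintf("  Deff: median %.1f, range %.1f-%.1f\n",
              x$deff_median, x$deff_min, x$deff_max))
  if (!is.null(x$group_icc_medians)) {
    cat("  per-group median ICC (Deff):\n")
    for (g in names(x$group_icc_medians)) {
      cat(sprintf("    %-10s %.3f (%.2f)\n", g,
                  x$group_icc_medians[[g]], x$group_deff_medians[[g]]))
    }
  }
  invisible(x)
}

#' Compare a computed ICC table against the bundled reference
#'
#' Regression harness: matches rows by variable name (and table id when
#' both sides carry one), reports per-variable absolute differences in ICC
#' and Deff, and flags rows exceeding a tolerance.
#'
#' @param computed,fixture two `icc_table`s over the same variables.
#' @param tolerance maximum tolerated absolute difference (applied to both
#'   ICC and Deff); `Inf` flags nothing.
#' @return An object of class `fixture_comparison`: a data frame of
#'   per-variable differences (`icc_diff`, `deff_diff`, `flagged`) with
#'   the tolerance as an attribute.
#' @examples
#' emip <- load_emip_fixture()
#' cmp <- compare_to_fixture(emip, emip, tolerance = 0)
#' sum(cmp$flagged)  # 0
#' @export
compare_to_fixture <- function(computed, fixture, tolerance = 0.005) {
  if (!inherits(computed, "icc_table") || !inherits(fixture, "icc_table")) {
    stop_input("both arguments must be icc_table objects")
  }
  use_tid <- all(!is.na(computed$table_id)) && all(!is.na(fixture$table_id))
  key <- function(t) {
    if (use_tid) paste(t$table_id, t$variable, sep = "\r") else t$variable
  }
  kc <- key(computed); kf <- key(fixture)
  only_c <- setdiff(kc, kf); only_f <- setdiff(kf, kc)
  if (length(only_c) || length(only_f)) {
    stop_input("variable names do not match; only in computed: {%s}; only in fixture: {%s}",
               paste(gsub("\r", "/", only_c), collapse = ", "),
               paste(gsub("\r", "/", only_f), collapse = ", "))
  }
  idx <- match(kc, kf)
  out <- data.frame(
    variable = computed$variable,
    icc_computed = computed$icc, icc_reference = fixture$icc[idx],
    icc_diff = abs(computed$icc - fixture$icc[idx]),
    deff_computed = computed$deff, deff_reference = fixture$deff[idx],
    deff_diff = abs(computed$deff - fixture$deff[idx]),
    stringsAsFactors = FALSE)
  out$flagged <- (out$icc_diff > tolerance) | (out$deff_diff > tolerance)
  out$flagged[is.na(out$flagged)] <- TRUE
  structure(out, class = c("fixture_comparison", "data.frame"),
            tolerance = tolerance)
}

#' @export
print.fixture_comparison <- function(x, ...) {
  nf <- sum(x$flagged)
  cat(sprintf("<fixture_comparison> %d variables, %d exceeding tolerance %g\n",
              nrow(x), nf, attr(x, "tolerance")))
  if (nf) {
    print.data.frame(as.data.frame(x)[x$flagged,
      c("variable", "icc_diff", "deff_diff")], row.names = FALSE)
  }
  invisible(x)
}
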