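#' Design effect as a variance ratio
#'
#' The design effect of a cluster sample is
#' \deqn{Deff = \frac{var_{actual}(r)}{var_{SRS}(r)},}
#' the variance of the estimated mean (or proportion) `r` under the actual
#' single-stage cluster design divided by its variance under simple random
#' sampling of the same total size. Here `var_actual` is the with-replacement
#' single-stage PSU approximation \eqn{s^2_a / a} -- the variance among
#' cluster means divided by the number of clusters -- and `var_srs` is the
#' element variance (denominator `N - 1`) divided by `N`.
#'
#' Unlike the approximation [deff_approx()], the ratio may fall below 1
#' when cluster means vary less than simple random sampling predicts
#' (negative intracluster correlation); the published multicenter tables
#' contain such rows (Deff 0.6--0.9).
#'
#' @param data a [cluster_dataset].
#' @param weighted if `TRUE`, use the size-weighted (linearized PSU
#'   totals) estimator \eqn{\frac{a}{a-1} \sum_i (t_i - n_i r)^2 / N^2}
#'   instead of the unweighted variance of cluster means. Default `FALSE`.
#' @return An object of class `deff_result`: `deff_ratio`, `deff_approx`
#'   (computed as `1 + (m - 1) * icc` at the data's ANOVA ICC), `var_actual`,
#'   `var_srs`, `m` (mean cluster size `N/a`) and `icc`.
#' @examples
#' set.seed(42)
#' d <- simulate_binary(simulation_spec(a = 20, size = 100, var_type = "binary",
#'                                      icc = 0.05, prevalence = 0.3, seed = 42))
#' deff_ratio(d)
#' @export
deff_ratio <- function(data, weighted = FALSE) {
  if (!inherits(data, "cluster_dataset")) {
    stop_input("'data' must be a cluster_dataset")
  }
  y <- data$value
  a <- data$a
  N <- data$N
  n_i <- data$n_i
  v_elem <- stats::var(y)
  if (!is.finite(v_elem) || v_elem <= 0) {
    stop_degenerate("'%s': zero element-level variance", data$variable)
  }
  r <- mean(y)
  cl_means <- as.vector(rowsum(y, data$cluster) / n_i)
  var_actual <- if (weighted) {
    t_i <- cl_means * n_i
    a / (a - 1) * sum((t_i - n_i * r)^2) / N^2
  } else {
    stats::var(cl_means) / a
  }
  var_srs <- v_elem / N
  m <- N / a
  # the ratio itself is defined even where the ANOVA ICC is not
  # (e.g. all-singleton clusters); the approximation is then NA
  rho <- tryCatch(icc_kish(data)$rho,
                  clustericc_degenerate_error = function(e) NA_real_)
  structure(
    list(deff_ratio = var_actual / var_srs,
         deff_approx = 1 + (m - 1) * rho,
         var_actual = var_actual, var_srs = var_srs,
         m = m, icc = rho),
    class = "deff_result")
}

#' @export
print.deff_result <- function(x, ...) {
  cat(sprintf("<deff_result> Deff = %.2f (approximation 1+(m-1)ICC = %.2f)\n",
              x$deff_ratio, x$deff_approx))
  cat(sprintf("  m = %.1f, ICC = %.4f, var_actual = %.3g, var_srs = %.3g\n",
              x$m, x$icc, x$var_actual, x$var_srs))
  invisible(x)
}

#' Design-effect approximation 1 + (m - 1) ICC
#'
#' The standard planning approximation to the design effect of a
#' single-stage cluster sample with mean cluster size `m` and intracluster
#' correlation `icc`. Exactly 1 when `icc = 0` (clustering carries no
#' penalty) and `m` when `icc = 1` (each cluster is internally homogeneous,
#' so only `a` effective observations exist).
#'
#' @param icc intracluster correlation in `[0, 1]`.
#' @param m mean cluster size (>= 1; need not be an integer).
#' @return `1 + (m - 1) * icc`.
#' @examples
#' deff_approx(0.145, 265)  # 39.28
#' @export
deff_approx <- function(icc, m) {
  if (!is.numeric(icc) || any(!is.finite(icc)) || any(icc < 0) || any(icc > 1)) {
    stop_input("'icc' must be in [0, 1]")
  }
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 1)) {
    stop_input("'m' must be >= 1")
  }
  1 + (m - 1) * icc
}

#' Sample size for estimating a proportion under simple random sampling
#'
#' Closed-form precision-based sample size for a single proportion:
#' \deqn{n = \left\lceil \frac{z_{1-\alpha/2}^2\, p (1 - p)}{d^2} \right\rceil,}
#' where `p` is the anticipated proportion, `d` the absolute precision
#' (half-width of the confidence interval) and `alpha` the two-sided
#' type-I error. The ceiling is taken, never rounding down: a conservative
#' design convention.
#'
#' @param p anticipated proportion, in (0, 1).
#' @param d absolute precision, in (0, p).
#' @param alpha two-sided type-I error (default 0.05).
#' @return Required SRS sample size (integer).
#' @examples
#' srs_sample_size_proportion(0.5, 0.05)          # 385
#' srs_sample_size_proportion(0.065, 0.0025)      # 37355
#' @export
srs_sample_size_proportion <- function(p, d, alpha = 0.05) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    stop_input("'p' must be a single proportion in (0, 1)")
  }
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0 || d >= p) {
    stop_input("'d' must satisfy 0 < d < p")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_input("'alpha' must be in (0, 1)")
  }
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}

#' Inflate an SRS sample size for a cluster design
#'
#' Multiplies a simple-random-sampling sample size by the design effect
#' approximation `1 + (m - 1) * icc` to obtain the size a cluster design
#' needs for the same precision, and the number of clusters of mean size
#' `m` that implies.
#'
#' @param n_srs required sample size under simple random sampling (>= 1).
#' @param icc anticipated intracluster correlation, in `[0, 1]`.
#' @param m mean cluster size (>= 1).
#' @return An object of class `sample_size_spec`: `n_srs`, `icc`, `m`,
#'   `deff`, `n_cluster` (ceiling of `n_srs * deff`) and `n_clusters_needed`
#'   (ceiling of `n_cluster / m`).
#' @examples
#' inflate_sample_size(1000, icc = 0.028, m = 265)  # 8392 subjects
#' @export
inflate_sample_size <- function(n_srs, icc, m) {
  if (!is.numeric(n_srs) || length(n_srs) != 1 || !is.finite(n_srs) || n_srs < 1) {
    stop_input("'n_srs' must be >= 1")
  }
  deff <- deff_approx(icc, m)
  n_cluster <- as.integer(ceiling(n_srs * deff))
  structure(
    list(n_srs = as.integer(ceiling(n_srs)), icc = icc, m = m, deff = deff,
         n_cluster = n_cluster,
         n_clusters_needed = as.integer(ceiling(n_cluster / m))),
    class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf("<sample_size_spec> SRS n = %d, Deff = %.3f (ICC %.3f, m %.1f)\n",
              x$n_srs, x$deff, x$icc, x$m))
  cat(sprintf("  cluster-design n = %d (~%d clusters of %.0f)\n",
              x$n_cluster, x$n_clusters_needed, x$m))
  invisible(x)
}
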